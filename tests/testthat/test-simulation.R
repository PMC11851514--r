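test_that("the zero state stays at the fixed point for any protocol", {
  z <- setNames(rep(0, 14), state_names())
  tr <- simulate_protocol(make_scenario("mild", stem_injection = FALSE),
                          init = z)
  expect_true(all(tr$states == 0))
  ## with an injection, only the injected stem cells move (no IL-10 means
  ## no differentiation back into tissue)
  trs <- simulate_protocol(make_scenario("severe", stem_injection = TRUE),
                           init = z)
  expect_true(all(trs$states[, setdiff(state_names(), "S")] == 0))
  expect_true(all(trs$states[trs$times < 7, "S"] == 0))
  expect_equal(unname(trs$states[trs$times == 7, "S"]), 2e7)
})

test_that("a zero-dose bolus is a null event", {
  tout <- sort(unique(c(seq(0, 30, by = 0.25), 1 / 12, 7)))
  sc0 <- make_scenario("mild", stem_injection = FALSE,
                       overrides = list(output_times = tout))
  sc1 <- make_scenario("mild", stem_injection = TRUE,
                       overrides = list(output_times = tout, stem_dose = 0))
  tr0 <- quiet_sim(sc0)
  tr1 <- quiet_sim(sc1)
  expect_equal(tr0$times, tr1$times)
  for (v in state_names()) {
    range_v <- max(abs(tr0$states[, v]))
    expect_lt(max(abs(tr0$states[, v] - tr1$states[, v])) / range_v, 1e-5)
  }
})

test_that("stem bolus arithmetic is exact and additive", {
  y <- default_initial_state()
  y[["S"]] <- 0
  expect_equal(apply_stem_bolus(y, 2e7)[["S"]], 2e7)
  expect_equal(unclass(apply_stem_bolus(y, 0)), unclass(as_state(y)))
  ab <- apply_stem_bolus(apply_stem_bolus(y, 1.3e6), 2.7e6)
  expect_equal(ab[["S"]], apply_stem_bolus(y, 4e6)[["S"]])
  expect_error(apply_stem_bolus(y, -1), "nonnegative")
})

test_that("the day-7 injection jumps S by exactly the dose and nothing else", {
  tout <- sort(c(seq(0, 30, by = 0.25), 7 - 1e-8))
  sc <- make_scenario("mild", stem_injection = TRUE,
                      overrides = list(output_times = tout))
  tr <- quiet_sim(sc)
  ev <- tr$events[tr$events$label == "stem_cell_injection", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time, 7)
  expect_identical(ev$S_post - ev$S_pre, 2e7)
  ## approaching the event from the left, only S jumps
  i <- which(tr$times == 7)
  im <- which(tr$times == 7 - 1e-8)
  expect_equal(i, im + 1L)
  for (v in setdiff(state_names(), "S")) {
    jump <- abs(tr$states[i, v] - tr$states[im, v])
    expect_lt(jump, max(1e-6 * abs(tr$states[i, v]), 1e-6))
  }
  expect_equal(unname(tr$states[i, "S"] - tr$states[im, "S"]), 2e7,
               tolerance = 1e-9)
  ## the stored post-event row carries the injected pool
  expect_identical(unname(tr$states[i, "S"]), ev$S_post)
})

test_that("cardiomyocytes decrease monotonically during ischemia (mild)", {
  tr <- quiet_sim(make_scenario("mild", stem_injection = FALSE))
  mc <- tr$states[tr$times <= 1 / 12, "Mc"]
  expect_true(all(diff(mc) < 0))
})

test_that("extremum lookups use earliest-time tie-breaking", {
  fake <- structure(list(
    times = c(0, 1, 2, 3),
    states = matrix(c(0, 1, 2, 3,   5, 5, 5, 5), ncol = 2,
                    dimnames = list(NULL, c("Mc", "Md"))),
    events = data.frame()), class = "mi_trajectory")
  expect_equal(peak_time(fake, "Mc"), 3)    # monotone increasing -> last
  expect_equal(trough_time(fake, "Mc"), 0)  # monotone increasing -> first
  expect_equal(peak_time(fake, "Md"), 0)    # constant -> first time
  expect_equal(trough_time(fake, "Md"), 0)
  expect_error(peak_time(fake, "bogus"), "unknown state variable")
})

test_that("simulated ROS matches the closed-form relaxation when cells are frozen", {
  ## freeze the neutrophil pool: no recruitment, no apoptosis, no damage
  p <- as_parameters(list(k18 = 0, k19 = 0, mu_N = 0, gamma = 0))
  y0 <- default_initial_state()
  y0[["N"]] <- 1000
  sc <- make_scenario("mild", stem_injection = FALSE,
                      overrides = list(horizon = 2,
                                       output_times = seq(0, 2, by = 0.01)))
  tr <- quiet_sim(sc, params = p, init = y0, rtol = 1e-10,
                  atol = c(setNames(rep(1e-4, 14), state_names())))
  Rinf <- 0.3 * 1000 / 10.5
  expected <- Rinf + (210 - Rinf) * exp(-10.5 * tr$times)
  expect_rel_equal(tr$states[, "R"], expected, 1e-6)
})

test_that("halving solver tolerances leaves Mc(30 d) unchanged to 0.1%", {
  for (sev in c("mild", "severe")) {
    sc <- make_scenario(sev, stem_injection = TRUE,
                        overrides = list(output_times = c(0, 15, 30)))
    a <- quiet_sim(sc, rtol = 1e-6)
    b <- quiet_sim(sc, rtol = 5e-7, atol = .5 * postmi:::.default_atol())
    mc_a <- a$states[nrow(a$states), "Mc"]
    mc_b <- b$states[nrow(b$states), "Mc"]
    expect_lt(abs(mc_a - mc_b) / abs(mc_b), 1e-3)
  }
})

test_that("trajectories are reported on a strictly increasing grid with event annotations", {
  tr <- quiet_sim(make_scenario("severe", stem_injection = TRUE))
  expect_true(all(diff(tr$times) > 0))
  expect_equal(nrow(tr$states), length(tr$times))
  expect_setequal(tr$events$label,
                  c("oxygen_restoration", "stem_cell_injection"))
  expect_true(all(c(1 / 12, 7) %in% tr$times))
  expect_true(all(tr$states >= 0))
})
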