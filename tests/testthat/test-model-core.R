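test_that("saturating_fraction follows Michaelis-Menten algebra", {
  expect_equal(saturating_fraction(0, 5), 0)
  expect_equal(saturating_fraction(100, 100), 0.5)
  ## activation at x = c and inhibition c/(c+x) at x = c are both 1/2
  expect_equal(saturating_fraction(25, 25), 0.5)
  expect_equal(25 / (25 + 25), saturating_fraction(25, 25))
  x <- seq(0, 1e4, length.out = 200)
  expect_true(all(diff(saturating_fraction(x, 37)) >= 0))
  expect_true(all(saturating_fraction(x, 37) < 1))
  expect_error(saturating_fraction(1, 0), "must be > 0")
  expect_error(saturating_fraction(-1, 5), ">= 0")
})

test_that("ROS damage is gated below the subcritical threshold", {
  expect_equal(ros_damage_rate(50, gamma = 7, muR_X = 15e-4, cR_X = 100,
                               Rc = 210), 0)
  expect_equal(ros_damage_rate(100, gamma = 1, muR_X = 15e-4, cR_X = 100,
                               Rc = 0), 7.5e-4)
  expect_equal(ros_damage_rate(1e9, gamma = 0, muR_X = 15e-4, cR_X = 100,
                               Rc = 0), 0)
  ## nondecreasing in R above Rc, identically 0 below, bounded by gamma*muR
  R <- seq(0, 5000, length.out = 500)
  rate <- ros_damage_rate(R, gamma = 2, muR_X = 15e-4, cR_X = 100, Rc = 210)
  expect_true(all(rate[R < 210] == 0))
  expect_true(all(diff(rate[R >= 210]) >= 0))
  expect_true(all(rate <= 2 * 15e-4))
  expect_error(ros_damage_rate(10, 1, 15e-4, 0, 0), "cR_X")
})

test_that("ischemic-stage derivatives match the printed source terms", {
  p <- default_parameters()
  y <- default_initial_state()
  y[c("Md", "N", "IL17", "IL1", "IL10", "M0", "S", "T", "R")] <- 0
  y[["Mc"]] <- 4e7
  d <- rhs_stage1(y, p)
  expect_equal(d[["Mc"]], -0.3 * 4e7)  # pure ischemic death at mu_Mc = 0.3

  ## necrotic debris alone sources IL1, monocytes, neutrophils, gdT cells
  y0 <- setNames(rep(0, 14), state_names())
  y0[["Md"]] <- 1000
  d <- rhs_stage1(y0, p)
  expect_equal(d[["IL1"]], 0.4)    # k3 * Md
  expect_equal(d[["M0"]], 4000)    # k6 * Md
  expect_equal(d[["N"]], 4000)     # k18 * Md
  expect_equal(d[["T"]], 4000)     # k13 * Md
  expect_equal(d[["Mc"]], 0)
})

test_that("the all-zero state is a fixed point of both stages", {
  z <- setNames(rep(0, 14), state_names())
  p <- default_parameters()
  expect_true(all(rhs_stage1(z, p) == 0))
  expect_true(all(rhs_stage2(z, p) == 0))
})

test_that("ROS balance is linear with the printed equilibrium", {
  p <- as_parameters(list(gamma = 0))
  y <- setNames(rep(0, 14), state_names())
  y[["N"]] <- 1000
  ## equilibrium R* = omega * k1 * N / d_R
  y[["R"]] <- 0.3 * 1000 / 10.5
  expect_equal(rhs_stage2(y, p)[["R"]], 0, tolerance = 1e-12)
  ## doubling omega doubles production at fixed state
  y[["R"]] <- 123.4
  d1 <- rhs_stage2(y, p)[["R"]] + 10.5 * y[["R"]]
  d2 <- rhs_stage2(y, as_parameters(list(gamma = 0, omega = 2)))[["R"]] +
    10.5 * y[["R"]]
  expect_equal(d2, 2 * d1)
})

test_that("cardiomyocyte bookkeeping holds on random states", {
  set.seed(11)
  p <- unclass(default_parameters())
  for (i in 1:200) {
    y <- rand_state()
    d1 <- rhs_stage1(y, p)
    loss <- -p[["k16"]] * y[["N"]] * y[["Mc"]] -
      p[["k2"]] * y[["M1"]] * y[["Md"]] - p[["k17"]] * y[["N"]] * y[["Md"]]
    expect_rel_equal(d1[["Mc"]] + d1[["Md"]], loss, 1e-12)
    expect_lte(d1[["Mc"]] + d1[["Md"]], 0)

    ## stage 2: ROS-killed cardiomyocytes transfer exactly to the dead
    ## pool, so Mc + Md changes only by regeneration inflow and clearance
    d2 <- rhs_stage2(y, p)
    regen <- p[["y_Mc"]] * y[["S"]] * y[["IL10"]] / (y[["IL10"]] + p[["m_Mc"]])
    expect_rel_equal(d2[["Mc"]] + d2[["Md"]], regen + loss, 1e-12)
  }
})

test_that("reperfused stage reduces to the ischemic stage when stem cells, damage and natural death are absent", {
  set.seed(12)
  p0 <- unclass(default_parameters())
  p0[["gamma"]] <- 0
  p0[["delta"]] <- 1
  shared <- c("N", "M0", "M1", "M2", "IL1", "IL10", "IL17", "C", "T")
  for (i in 1:100) {
    y <- rand_state()
    y[["S"]] <- 0
    d1 <- rhs_stage1(y, p0)
    d2 <- rhs_stage2(y, p0)
    expect_rel_equal(d2[shared], d1[shared], 1e-12)
    ## with mu_Mc = 0 the two systems coincide on all 14 components
    pz <- p0
    pz[["mu_Mc"]] <- 0
    expect_rel_equal(rhs_stage2(y, pz), rhs_stage1(y, pz), 1e-12)
  }
})

test_that("parameter validation aggregates all violations by name", {
  expect_silent(validate_parameters(default_parameters()))
  expect_error(validate_parameters(as_parameters(list(cR_Mc = 0))), "cR_Mc")
  expect_error(validate_parameters(as_parameters(list(k2 = -0.1))), "k2")
  err <- tryCatch(
    validate_parameters(as_parameters(list(k2 = -0.1, cR_Mc = 0, c3 = -5))),
    error = conditionMessage)
  expect_match(err, "k2")
  expect_match(err, "cR_Mc")
  expect_match(err, "c3")
  expect_error(as_parameters(list(k99 = 1)), "k99")
})

test_that("compiled and pure-R right-hand sides agree along a trajectory", {
  sc <- make_scenario("mild", stem_injection = TRUE,
                      overrides = list(output_times = seq(0, 30, by = 0.5)))
  trC <- quiet_sim(sc, backend = "compiled")
  trR <- quiet_sim(sc, backend = "R")
  for (v in state_names()) {
    ## agreement to 1e-5 of each variable's dynamic range (the two
    ## backends take independent adaptive step sequences)
    range_v <- max(abs(trC$states[, v]))
    expect_lt(max(abs(trC$states[, v] - trR$states[, v])) / range_v, 1e-5)
  }
})
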