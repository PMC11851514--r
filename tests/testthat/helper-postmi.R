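## random nonnegative states at physiologically plausible magnitudes
## (cell pools up to 4e7 cells/mL, cytokines tens of pg/mL, collagen 1e12)
rand_state <- function() {
  c(Mc = runif(1, 0, 4e7), Md = runif(1, 0, 1e6), IL1 = runif(1, 0, 50),
    IL10 = runif(1, 0, 50), IL17 = runif(1, 0, 50), N = runif(1, 0, 2e5),
    M0 = runif(1, 0, 2e5), M1 = runif(1, 0, 1e5), M2 = runif(1, 0, 1e5),
    C = runif(1, 0, 1e12), F = runif(1, 0, 1e8), S = runif(1, 0, 2e7),
    T = runif(1, 0, 1e5), R = runif(1, 0, 5e3))
}

## componentwise relative comparison: |a - b| <= tol * max(|a|, |b|, floor)
expect_rel_equal <- function(a, b, tol, floor = 1e-300) {
  scale <- pmax(abs(a), abs(b), floor)
  expect_lt(max(abs(a - b) / scale), tol)
}

## scalar Ishigami test function and its analytic variance decomposition
## (a = 7, b = 0.1 over [-pi, pi]^3)
ishigami <- function(x) sin(x[1]) + 7 * sin(x[2])^2 + 0.1 * x[3]^4 * sin(x[1])
ishigami_ranges <- data.frame(name = c("x1", "x2", "x3"),
                              low = -pi, high = pi)
ishigami_S1 <- c(x1 = 0.3139, x2 = 0.4424, x3 = 0)

quiet_sim <- function(...) suppressWarnings(simulate_protocol(...))
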