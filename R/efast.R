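#' eFAST search curve
#'
#' The periodic transform that drives a parameter across its uncertainty
#' range in the (extended) Fourier Amplitude Sensitivity Test:
#' `x(s) = low + (high - low) * (1/2 + arcsin(sin(freq * s + phase)) / pi)`.
#' Sweeping `s` uniformly over a full period samples `x` uniformly on
#' `[low, high]`.
#'
#' @param s Scalar phase variable(s), radians.
#' @param low,high Range bounds, `low < high`.
#' @param freq Integer driving frequency.
#' @param phase Random phase shift (radians; defaults to 0).
#' @return Parameter value(s) in `[low, high]`.
#' @export
#' @examples
#' search_curve(0, 0, 1, freq = 5)  # midpoint 0.5
search_curve <- function(s, low, high, freq, phase = 0) {
  if (any(low >= high)) stop("need low < high", call. = FALSE)
  low + (high - low) * (0.5 + asin(sin(freq * s + phase)) / pi)
}

#' Construct an eFAST sampling design
#'
#' Assigns the driving frequency and complementary frequencies, the
#' per-curve random phase shifts, and the sample grid of an eFAST design
#' over `d` parameters.  The frequency of interest is
#' `floor((Ns - 1) / (2 * M))`, the largest frequency whose first `M`
#' harmonics stay below the Nyquist limit of an `Ns`-point curve;
#' complementary frequencies are spread over `1 .. floor(w1 / (2 * M))`
#' (the standard max-spread integer scheme), which keeps their first `M`
#' harmonics strictly below the frequency of interest.
#'
#' @param names Character vector of varied parameter names (default: every
#'   parameter with a published range, see [parameter_ranges()]).
#' @param ranges `data.frame` with columns `name`, `low`, `high` (a
#'   `baseline` column is allowed and ignored here).
#' @param M Interference factor: number of harmonics attributed to the
#'   parameter of interest (default 4).
#' @param Ns Samples per search curve; odd, at least `4 * M^2 + 1`
#'   (65 for `M = 4`), the smallest size for which a valid frequency
#'   assignment exists.
#' @param NR Number of independent resampling curves (random phase shifts)
#'   per parameter (default 5).
#' @param seed RNG seed fixing the phase shifts (and hence the whole
#'   design).
#' @return A list of class `"mi_efast_design"`.
#' @export
efast_design <- function(names = NULL, ranges = parameter_ranges(),
                         M = 4, Ns = 65, NR = 5, seed = 1) {
  stopifnot(is.data.frame(ranges), all(c("name", "low", "high") %in%
                                         colnames(ranges)))
  if (is.null(names)) names <- ranges$name
  missing <- setdiff(names, ranges$name)
  if (length(missing))
    stop("no range for parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- length(names)
  if (d < 2L) stop("need at least two varied parameters", call. = FALSE)
  if (Ns %% 2L != 1L) stop("Ns must be odd", call. = FALSE)
  ns_min <- 4L * M^2 + 1L
  if (Ns < ns_min)
    stop(sprintf("Ns = %d is below the Nyquist bound; need Ns >= %d for M = %d",
                 Ns, ns_min, M), call. = FALSE)
  w1 <- (Ns - 1L) %/% (2L * M)
  m <- w1 %/% (2L * M)
  w_comp <- if (m >= d - 1L) {
    floor(seq(1, m, length.out = d - 1L))
  } else {
    ((seq_len(d - 1L) - 1L) %% m) + 1L
  }
  idx <- match(names, ranges$name)
  set.seed(seed)
  phases <- array(runif(d * NR * d, 0, 2 * pi), dim = c(d, NR, d))
  structure(list(
    names = names, low = ranges$low[idx], high = ranges$high[idx],
    M = M, Ns = Ns, NR = NR, seed = seed,
    freq_interest = w1, freq_complementary = as.integer(w_comp),
    s = 2 * pi * (seq_len(Ns) - 1L) / Ns - pi,
    phases = phases
  ), class = "mi_efast_design")
}

#' Generate the eFAST parameter samples
#'
#' For each parameter of interest `i` and resampling curve `r`, drives
#' parameter `i` at the frequency of interest and every other varied
#' parameter at its complementary frequency (all with curve-specific
#' random phase shifts), yielding `Ns` parameter sets per curve;
#' parameters outside the design stay at `baseline`.
#'
#' @param design From [efast_design()].
#' @param baseline Full parameter set supplying unvaried values (default
#'   [default_parameters()]).  Pass `NULL` to obtain bare sample matrices
#'   over the design columns only (used for analytic test functions).
#' @return A list with one element per (parameter, curve) run:
#'   `list(param, curve, X)` where `X` is an `Ns x d` matrix of varied
#'   values; when `baseline` is given, also `params`, a list of `Ns` full
#'   parameter sets.
#' @export
generate_efast_samples <- function(design, baseline = default_parameters()) {
  stopifnot(inherits(design, "mi_efast_design"))
  d <- length(design$names)
  runs <- vector("list", d * design$NR)
  k <- 0L
  for (i in seq_len(d)) {
    freqs <- integer(d)
    freqs[i] <- design$freq_interest
    freqs[-i] <- design$freq_complementary
    for (r in seq_len(design$NR)) {
      X <- matrix(NA_real_, design$Ns, d, dimnames = list(NULL, design$names))
      for (j in seq_len(d))
        X[, j] <- search_curve(design$s, design$low[j], design$high[j],
                               freqs[j], design$phases[i, r, j])
      k <- k + 1L
      run <- list(param = design$names[i], curve = r, X = X)
      if (!is.null(baseline)) {
        base <- unclass(as_parameters(baseline))
        run$params <- lapply(seq_len(design$Ns), function(s) {
          p <- base
          p[design$names] <- X[s, ]
          p
        })
      }
      runs[[k]] <- run
    }
  }
  runs
}

## Fourier-spectrum index estimator.  P_k is the power at integer
## frequency k of the Ns-point curve; the first M harmonics of the driving
## frequency give the first-order variance share, everything at or below
## floor(freq/2) (the complementary band and its harmonics) gives the
## complementary share whose complement is the total-order index.
.efast_indices_core <- function(y, freq, M, warn = TRUE) {
  Ns <- length(y)
  stopifnot(Ns %% 2L == 1L)
  if (M * freq > (Ns - 1) / 2)
    stop("harmonics exceed the Nyquist limit: need Ns >= 2*M*freq + 1",
         call. = FALSE)
  P <- (2 / Ns^2) * Mod(fft(y))^2
  spec <- P[2:((Ns + 1) / 2)]          # frequencies 1 .. (Ns-1)/2
  V <- sum(spec)
  if (V <= 0 || V < 1e-20 * (abs(mean(y)) + 1)^2) {
    if (warn) warning("constant model output: sensitivity indices set to 0")
    return(c(S1 = 0, ST = 0))
  }
  S1 <- sum(spec[seq_len(M) * freq]) / V
  Vc <- sum(spec[seq_len(max(1L, freq %/% 2L))]) / V
  c(S1 = min(max(S1, 0), 1), ST = min(max(1 - Vc, 0), 1))
}

#' First- and total-order eFAST indices from one output curve
#'
#' Given the model output over the `Ns` samples of one search curve,
#' estimates the first-order index (variance at the first `M` harmonics of
#' the driving frequency over total variance) and the total-order index
#' (one minus the variance share of the complementary frequency band).
#' Both are clipped to `[0, 1]`; a constant output yields `(0, 0)` with a
#' warning.
#'
#' @param y Numeric output series along the curve (`length(y)` odd).
#' @param freq Integer driving frequency of the parameter of interest.
#' @param M Interference factor.
#' @return Named vector `c(S1, ST)`.
#' @export
compute_efast_indices <- function(y, freq, M = 4) {
  .efast_indices_core(as.numeric(y), freq, M, warn = TRUE)
}

#' eFAST of a scalar-valued function
#'
#' Convenience driver used to validate the estimator on closed-form test
#' functions: runs the full design through `f` and aggregates indices
#' across resampling curves by their mean.
#'
#' @param f Function taking a numeric vector of length `d` (one value per
#'   design parameter, in design order) and returning a scalar.
#' @param design From [efast_design()].
#' @param workers Parallel workers for the function evaluations.
#' @return A `data.frame` of class `"mi_sensitivity"` with columns
#'   `parameter`, `S1`, `ST`, `interaction` (`= ST - S1` exactly), plus a
#'   `per_curve` attribute holding the curve-level indices.
#' @export
run_efast <- function(f, design, workers = 1L) {
  runs <- generate_efast_samples(design, baseline = NULL)
  ys <- .apply_workers(runs, function(run) apply(run$X, 1L, f), workers)
  .aggregate_efast(design, runs, ys, times = NULL, window = NULL)
}

#' Time-averaged eFAST of the cardiomyocyte output
#'
#' Global sensitivity analysis of the simulated live-cardiomyocyte density
#' `Mc`: every sampled parameter set is run through
#' [simulate_protocol()], first- and total-order indices are computed at
#' each output time, averaged over the window, and aggregated across
#' resampling curves by their mean.
#'
#' @param design From [efast_design()]; the varied set defaults to every
#'   parameter with a published range.
#' @param scenario Scenario from [make_scenario()].
#' @param params Baseline parameter set for unvaried parameters.
#' @param init Initial state.
#' @param window Averaging window (days; default the scenario horizon).
#' @param output_times Time grid at which indices are computed (default 61
#'   equispaced points over the horizon; `t = 0`, where all runs coincide,
#'   is never used).
#' @param workers Parallel workers (forked; deterministic because all
#'   randomness is fixed in the design).
#' @param rtol,atol Solver tolerances passed to [simulate_protocol()].
#' @return A `data.frame` of class `"mi_sensitivity"` (see [run_efast()]),
#'   with attributes `times`, `window`, `n_failed`.
#' @export
efast_for_model <- function(design, scenario,
                            params = default_parameters(),
                            init = default_initial_state(),
                            window = NULL, output_times = NULL,
                            workers = 1L, rtol = 1e-6,
                            atol = .default_atol()) {
  scenario <- validate_scenario(scenario)
  if (is.null(window)) window <- scenario$horizon
  if (window > scenario$horizon)
    stop("averaging window exceeds the scenario horizon", call. = FALSE)
  if (is.null(output_times))
    output_times <- seq(0, scenario$horizon, length.out = 61)
  scenario$output_times <- NULL
  sc <- scenario
  sc$output_times <- sort(unique(c(output_times, scenario$t_oxygen,
                                   if (scenario$stem_injection)
                                     scenario$t_stem)))
  keep <- sc$output_times > 0 & sc$output_times <= window

  runs <- generate_efast_samples(design, baseline = params)
  eval_run <- function(run) {
    t(vapply(run$params, function(p) {
      tryCatch({
        tr <- suppressWarnings(  # per-run clamp notes would swamp the log
          simulate_protocol(sc, params = p, init = init,
                            rtol = rtol, atol = atol))
        tr$states[keep, "Mc"]
      }, error = function(e) rep(NA_real_, sum(keep)))
    }, numeric(sum(keep))))
  }
  ys <- .apply_workers(runs, eval_run, workers)
  .aggregate_efast(design, runs, ys,
                   times = sc$output_times[keep], window = window)
}

.apply_workers <- function(xs, f, workers) {
  if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(xs, f, mc.cores = workers, mc.preschedule = TRUE)
  else
    lapply(xs, f)
}

## Aggregate per-run outputs into the sensitivity table.  `ys[[k]]` is
## either a length-Ns vector (scalar output) or an Ns x nt matrix
## (time-resolved output); runs containing failed simulations (NAs) are
## dropped from their parameter's average, and more than 1% failed
## simulations aborts the analysis.
.aggregate_efast <- function(design, runs, ys, times, window) {
  d <- length(design$names)
  per_curve <- array(NA_real_, dim = c(d, design$NR, 2),
                     dimnames = list(design$names, NULL, c("S1", "ST")))
  n_failed <- 0L
  n_total <- 0L
  for (k in seq_along(runs)) {
    run <- runs[[k]]
    y <- ys[[k]]
    if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
    n_total <- n_total + nrow(y)
    bad <- apply(y, 1L, function(v) any(!is.finite(v)))
    i <- match(run$param, design$names)
    if (any(bad)) {
      n_failed <- n_failed + sum(bad)
      next  # a broken curve cannot be Fourier-analysed; drop it
    }
    idx <- vapply(seq_len(ncol(y)), function(tt)
      .efast_indices_core(y[, tt], design$freq_interest, design$M,
                          warn = FALSE),
      numeric(2))
    per_curve[i, run$curve, ] <- rowMeans(idx)
  }
  if (n_failed > 0) {
    frac <- n_failed / n_total
    if (frac > 0.01)
      stop(sprintf("%d of %d simulations failed (%.1f%% > 1%%); aborting",
                   n_failed, n_total, 100 * frac), call. = FALSE)
    warning(sprintf("%d of %d simulations failed; affected curves dropped",
                    n_failed, n_total))
  }
  S1 <- apply(per_curve[, , "S1", drop = FALSE], 1L, mean, na.rm = TRUE)
  ST <- apply(per_curve[, , "ST", drop = FALSE], 1L, mean, na.rm = TRUE)
  out <- data.frame(parameter = design$names, S1 = unname(S1),
                    ST = unname(ST), interaction = unname(ST - S1),
                    stringsAsFactors = FALSE)
  attr(out, "per_curve") <- per_curve
  attr(out, "design") <- design[c("M", "Ns", "NR", "seed", "freq_interest")]
  attr(out, "times") <- times
  attr(out, "window") <- window
  attr(out, "n_failed") <- n_failed
  class(out) <- c("mi_sensitivity", "data.frame")
  out
}
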