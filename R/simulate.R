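## Per-variable absolute tolerances: the state spans ~9 orders of
## magnitude, so cell pools and collagen get 1 unit, cytokines and ROS
## 1e-6 pg/mL.
.default_atol <- function() {
  a <- setNames(rep(1, 14), .state_names)
  a[c("IL1", "IL10", "IL17", "R")] <- 1e-6
  a
}

.default_output_times <- function(sc) {
  c(seq(0, sc$t_oxygen, length.out = 51),
    seq(sc$t_oxygen, min(1, sc$horizon), length.out = 481),
    seq(0, sc$horizon, length.out = 1201))
}

## sorted unique grid; points closer than 1e-9 d collapse onto the
## protected (event) times so restarts hit events exactly
.dedupe_times <- function(tt, protected) {
  tt <- sort(unique(c(tt, protected)))
  drop <- logical(length(tt))
  for (i in seq_along(tt)[-1]) {
    if (tt[i] - tt[i - 1] < 1e-9) {
      if (tt[i] %in% protected && !(tt[i - 1] %in% protected))
        drop[i - 1] <- TRUE
      else drop[i] <- TRUE
    }
  }
  tt[!drop]
}

#' Add a stem-cell bolus to a state
#'
#' Increments the stem-cell pool `S` by `dose`, leaving every other
#' component unchanged.
#'
#' @param state Named state vector.
#' @param dose Injected stem-cell density (cells/mL, >= 0).
#' @return The updated state.
#' @export
apply_stem_bolus <- function(state, dose) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("dose must be a single nonnegative number", call. = FALSE)
  state <- as_state(state)
  state[["S"]] <- state[["S"]] + dose
  state
}

## one integration leg; stage is 1 (ischemic) or 2 (reperfused)
.integrate_leg <- function(y0, times, stage, pvec, rtol, atol, backend) {
  if (length(times) < 2L) return(matrix(y0, nrow = 1,
                                        dimnames = list(NULL, .state_names)))
  out <- if (backend == "compiled") {
    deSolve::lsoda(y = y0, times = times, func = paste0("postmi_derivs", stage),
                   parms = pvec, dllname = "postmi",
                   initfunc = "postmi_initmod", rtol = rtol, atol = atol)
  } else {
    f <- if (stage == 1L)
      function(t, y, p) list(.rhs1_core(y, p, ros_dynamics = p[["ros_stage1"]] != 0))
    else
      function(t, y, p) list(.rhs2_core(y, p))
    deSolve::lsoda(y = y0, times = times, func = f, parms = pvec,
                   rtol = rtol, atol = atol)
  }
  di <- attr(out, "istate")
  if (!is.null(di) && di[1] < 0) {
    last <- out[nrow(out), ]
    stiffest <- .state_names[which.max(abs(unlist(last[-1])))]
    stop(sprintf(paste0("integrator failed (istate = %d) near t = %.6g d ",
                        "in stage %d; largest component: %s"),
                 di[1], unname(last[1]), stage, stiffest), call. = FALSE)
  }
  m <- unclass(out)[, -1, drop = FALSE]
  colnames(m) <- .state_names
  m
}

.clamp_negatives <- function(m, atol) {
  neg <- m < 0
  if (any(neg)) {
    worst <- min(m[neg])
    if (worst < -max(atol))
      warning(sprintf(paste0("state components below -atol were clamped to 0 ",
                             "(most negative: %.3g)"), worst))
    else
      warning(sprintf(paste0("small negative solver excursions clamped to 0 ",
                             "(most negative: %.3g)"), worst))
    m[neg] <- 0
  }
  m
}

#' Simulate the staged treatment protocol
#'
#' Event-driven piecewise integration of the post-MI model: the ischemic
#' system runs on `[0, t_oxygen]`; oxygen restoration switches to the
#' reperfused system (activating thresholded ROS damage, stem-cell-driven
#' regeneration and the `delta`/`omega`/`gamma` multipliers); if the
#' scenario requests it, the stem-cell pool jumps by `stem_dose` at
#' `t_stem`; integration continues to the horizon.  Event times are hit
#' exactly by restarting the integrator, never by interpolation.  The
#' adaptive stiff-capable `lsoda` solver is used with per-variable
#' absolute tolerances.  Small negative solver excursions (within the
#' absolute tolerance) are clamped to zero with a warning.
#'
#' @param scenario A scenario from [make_scenario()].
#' @param params Parameter set (default [default_parameters()]).  The
#'   scenario's `mu_Mc`, `y_Mc`, `delta`, `omega`, `gamma` replace the
#'   corresponding entries.
#' @param init Initial state (default [default_initial_state()]).
#' @param rtol Relative tolerance (default 1e-6).
#' @param atol Absolute tolerance, scalar or per-variable named vector
#'   (default: 1 for cell pools and collagen, 1e-6 for cytokines and ROS).
#' @param backend `"compiled"` (C right-hand side; default) or `"R"`
#'   (pure-R right-hand side, bitwise-independent implementation used for
#'   cross-checking).
#' @return A list of class `"mi_trajectory"`: `times` (days, strictly
#'   increasing), `states` (matrix, one row per time, columns
#'   [state_names()]; at `t_stem` the post-bolus state), `events`
#'   (data.frame `time`/`label`/`S_pre`/`S_post`), and `meta` (scenario,
#'   parameter fingerprint, tolerances).
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_protocol(make_scenario("mild", stem_injection = FALSE))
#' peak_time(tr, "R") * 24  # hours
#' }
simulate_protocol <- function(scenario, params = default_parameters(),
                              init = default_initial_state(),
                              rtol = 1e-6, atol = .default_atol(),
                              backend = c("compiled", "R")) {
  backend <- match.arg(backend)
  scenario <- validate_scenario(scenario)
  params <- validate_parameters(as_parameters(params))
  init <- validate_state(init)
  if (length(atol) == 1L) atol <- setNames(rep(atol, 14), .state_names)
  atol <- atol[.state_names]

  p <- unclass(params)
  p[["mu_Mc"]] <- scenario$mu_Mc
  p[["y_Mc"]] <- scenario$y_Mc
  p[["delta"]] <- scenario$delta
  p[["omega"]] <- scenario$omega
  p[["gamma"]] <- scenario$gamma
  pvec <- c(p, ros_stage1 = as.numeric(isTRUE(scenario$ros_in_stage1)))

  tout <- scenario$output_times
  if (is.null(tout)) tout <- .default_output_times(scenario)
  tout <- .dedupe_times(tout, c(0, scenario$t_oxygen,
                                if (scenario$stem_injection) scenario$t_stem,
                                scenario$horizon))

  breaks <- c(0, scenario$t_oxygen,
              if (scenario$stem_injection) scenario$t_stem,
              scenario$horizon)
  stages <- c(1L, rep(2L, length(breaks) - 2L))

  y <- unclass(init)
  times_all <- 0
  states_all <- matrix(y, nrow = 1, dimnames = list(NULL, .state_names))
  events <- data.frame(time = numeric(0), label = character(0),
                       S_pre = numeric(0), S_post = numeric(0))

  for (leg in seq_along(stages)) {
    t0 <- breaks[leg]; t1 <- breaks[leg + 1]
    leg_times <- sort(unique(c(t0, tout[tout > t0 & tout <= t1], t1)))
    m <- .integrate_leg(y, leg_times, stages[leg], pvec, rtol, atol, backend)
    m <- .clamp_negatives(m, atol)
    y <- m[nrow(m), ]
    if (nrow(m) > 1L) {
      times_all <- c(times_all, leg_times[-1])
      states_all <- rbind(states_all, m[-1, , drop = FALSE])
    }
    ## event at the end of this leg
    if (leg == 1L) {
      events <- rbind(events, data.frame(
        time = t1, label = "oxygen_restoration",
        S_pre = unname(y[["S"]]), S_post = unname(y[["S"]])))
    } else if (scenario$stem_injection && leg == 2L) {
      s_pre <- unname(y[["S"]])
      y <- unclass(apply_stem_bolus(y, scenario$stem_dose))
      states_all[nrow(states_all), "S"] <- y[["S"]]
      events <- rbind(events, data.frame(
        time = t1, label = "stem_cell_injection",
        S_pre = s_pre, S_post = unname(y[["S"]])))
    }
  }

  structure(list(
    times = times_all,
    states = states_all,
    events = events,
    meta = list(scenario = scenario,
                parameter_fingerprint = fingerprint(p),
                rtol = rtol, atol = atol, backend = backend)
  ), class = "mi_trajectory")
}

#' @export
print.mi_trajectory <- function(x, ...) {
  cat(sprintf("<mi_trajectory> %d time points over [%g, %g] days; events: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(sprintf("%s@%gd", x$events$label, x$events$time),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mi_trajectory <- function(x, ...) {
  data.frame(t_days = x$times, x$states, check.names = FALSE)
}

.lookup_var <- function(traj, var) {
  if (!var %in% colnames(traj$states))
    stop("unknown state variable: ", var, "; expected one of ",
         paste(.state_names, collapse = ", "), call. = FALSE)
  traj$states[, var]
}

#' Time of the global extremum of a trajectory variable
#'
#' `peak_time()` returns the time (days) at which `var` attains its global
#' maximum over the sampled trajectory; `trough_time()` the global
#' minimum.  Ties are broken by the earliest time.
#'
#' @param traj A trajectory from [simulate_protocol()].
#' @param var A state-variable name (see [state_names()]).
#' @return Time in days.
#' @export
peak_time <- function(traj, var) {
  traj$times[which.max(.lookup_var(traj, var))]
}

#' @rdname peak_time
#' @export
trough_time <- function(traj, var) {
  traj$times[which.min(.lookup_var(traj, var))]
}
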