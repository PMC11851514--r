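## Severity presets: constant ischemic cardiomyocyte death rate mu_Mc and
## stem-cell-to-cardiomyocyte differentiation rate y_Mc.
.severity_presets <- list(
  mild = c(mu_Mc = 0.3, y_Mc = 0.9),
  severe = c(mu_Mc = 4.0677, y_Mc = 2.52)
)

#' Build a treatment-protocol scenario
#'
#' A scenario bundles the infarct severity, the event-driven treatment
#' protocol (oxygen restoration at `t_oxygen`, optional stem-cell bolus of
#' `stem_dose` cells/mL at `t_stem`), the three clinical multipliers, and
#' the output grid.  Severity selects the preset pair `(mu_Mc, y_Mc)`:
#' mild gives (0.3, 0.9)/day, severe (4.0677, 2.52)/day.
#'
#' @param severity `"mild"` or `"severe"`.
#' @param stem_injection Apply the stem-cell bolus at `t_stem`?
#' @param delta Neutrophil-recruitment multiplier (immune activity;
#'   1 = normal, 10 = overactive).
#' @param omega ROS-production multiplier (oxygen-restoration level;
#'   1 = normal, 10 = excessive).
#' @param gamma ROS-damage multiplier (patient risk factors; 1 = normal,
#'   10 = elevated).
#' @param overrides Named list overriding any scenario field
#'   (`t_oxygen`, `t_stem`, `stem_dose`, `horizon`, `output_times`,
#'   `ros_in_stage1`, `mu_Mc`, `y_Mc`).
#' @return A list of class `"mi_scenario"` with fields `severity`,
#'   `mu_Mc`, `y_Mc`, `t_oxygen` (days, default 1/12 = 2 h), `stem_injection`,
#'   `t_stem` (days, default 7), `stem_dose` (cells/mL, default 2e7),
#'   `horizon` (days, default 30), `delta`, `omega`, `gamma`,
#'   `output_times` (`NULL` for the default dense grid), and
#'   `ros_in_stage1` (integrate the ROS balance during ischemia, default
#'   `TRUE`).
#' @export
#' @examples
#' make_scenario("severe")$mu_Mc
make_scenario <- function(severity = c("mild", "severe"),
                          stem_injection = TRUE,
                          delta = 1, omega = 1, gamma = 1,
                          overrides = list()) {
  severity <- match.arg(severity)
  preset <- .severity_presets[[severity]]
  sc <- list(
    severity = severity,
    mu_Mc = unname(preset["mu_Mc"]),
    y_Mc = unname(preset["y_Mc"]),
    t_oxygen = 1 / 12,
    stem_injection = isTRUE(stem_injection),
    t_stem = 7,
    stem_dose = 2e7,
    horizon = 30,
    delta = delta, omega = omega, gamma = gamma,
    output_times = NULL,
    ros_in_stage1 = TRUE
  )
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(sc))
    if (length(unknown))
      stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    sc[names(overrides)] <- overrides
  }
  validate_scenario(sc)
}

#' @rdname make_scenario
#' @param sc A scenario list.
#' @export
validate_scenario <- function(sc) {
  stopifnot(is.list(sc))
  with(sc, {
    if (!is.numeric(t_oxygen) || t_oxygen <= 0)
      stop("t_oxygen must be > 0", call. = FALSE)
    if (horizon <= t_oxygen)
      stop("horizon must exceed t_oxygen", call. = FALSE)
    if (stem_injection && (t_stem <= t_oxygen || t_stem >= horizon))
      stop("need t_oxygen < t_stem < horizon when stem_injection is set",
           call. = FALSE)
    if (stem_dose < 0) stop("stem_dose must be >= 0", call. = FALSE)
    if (any(c(delta, omega, gamma) < 0))
      stop("delta, omega, gamma must be >= 0", call. = FALSE)
    if (!is.null(output_times)) {
      if (is.unsorted(output_times, strictly = TRUE))
        stop("output_times must be strictly increasing", call. = FALSE)
      if (min(output_times) < 0 || max(output_times) > horizon)
        stop("output_times must lie within [0, horizon]", call. = FALSE)
    }
  })
  class(sc) <- "mi_scenario"
  sc
}

#' The clinical multiplier experiment grid
#'
#' The four published combinations of the neutrophil-recruitment (`delta`),
#' oxygenation (`omega`) and risk-factor (`gamma`) multipliers:
#' baseline/normal levels (1,1,1), elevated risk factors (1,1,10),
#' overactive immune system (10,1,1), and excessive oxygen restoration
#' (1,10,1) -- crossed, when simulated via [run_scenario_grid()], with both
#' severities and both treatment arms.
#'
#' @return A `data.frame` of class `"mi_grid"` with columns `label`,
#'   `delta`, `omega`, `gamma`.
#' @export
scenario_grid <- function() {
  g <- data.frame(
    label = c("baseline", "elevated risk factors",
              "overactive immune system", "excessive oxygen restoration"),
    delta = c(1, 1, 10, 1),
    omega = c(1, 1, 1, 10),
    gamma = c(1, 10, 1, 1),
    stringsAsFactors = FALSE
  )
  class(g) <- c("mi_grid", "data.frame")
  g
}

#' Simulate every cell of the multiplier grid
#'
#' Runs [simulate_protocol()] for each multiplier combination of
#' [scenario_grid()], crossed with both severities and (optionally) both
#' treatment arms, and summarizes each run.
#'
#' @param params Parameter set (default [default_parameters()]).
#' @param init Initial state (default [default_initial_state()]).
#' @param severities Character vector of severities to run.
#' @param stem_arms Logical vector of treatment arms (`FALSE` = oxygen
#'   restoration only, `TRUE` = oxygen restoration + day-7 bolus).
#' @param ... Passed on to [simulate_protocol()] (e.g. tolerances).
#' @return A `data.frame` with one row per run: `label`, `severity`,
#'   `stem`, the multipliers, final cardiomyocyte density `Mc_final`
#'   (cells/mL), ROS peak `R_peak` (pg/mL) and its time `R_peak_time`
#'   (days), and the cardiomyocyte trough time `Mc_trough_time` (days).
#'   The trajectories are attached as attribute `"trajectories"`.
#' @export
run_scenario_grid <- function(params = default_parameters(),
                              init = default_initial_state(),
                              severities = c("mild", "severe"),
                              stem_arms = c(FALSE, TRUE), ...) {
  grid <- scenario_grid()
  rows <- list()
  trajs <- list()
  for (sev in severities) for (stem in stem_arms) {
    for (i in seq_len(nrow(grid))) {
      sc <- make_scenario(sev, stem_injection = stem,
                          delta = grid$delta[i], omega = grid$omega[i],
                          gamma = grid$gamma[i])
      tr <- simulate_protocol(sc, params, init, ...)
      key <- sprintf("%s|%s|%s", grid$label[i], sev,
                     if (stem) "stem" else "no-stem")
      trajs[[key]] <- tr
      rows[[key]] <- data.frame(
        label = grid$label[i], severity = sev, stem = stem,
        delta = grid$delta[i], omega = grid$omega[i], gamma = grid$gamma[i],
        Mc_final = unname(tr$states[nrow(tr$states), "Mc"]),
        R_peak = max(tr$states[, "R"]),
        R_peak_time = peak_time(tr, "R"),
        Mc_trough_time = trough_time(tr, "Mc"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "trajectories") <- trajs
  out
}
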