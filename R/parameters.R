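#' @useDynLib postmi
#' @importFrom stats fft runif setNames var ks.test punif
#' @importFrom utils modifyList read.csv write.csv packageVersion
"_PACKAGE"

## Canonical parameter ordering.  The compiled right-hand side indexes the
## parameter vector positionally, so this order is part of the ABI between
## R/parameters.R and src/rhs.c -- do not reorder.
.param_names <- c(
  paste0("k", 1:22),
  "c1", "c2", "c3",
  "c_IL10_C", "c_IL1_C", "c_IL10_F", "c_IL17_Mc",
  "c_IL1_M0", "c_IL10_M0", "c_IL17_M0", "c_IL17",
  "d_IL1", "d_IL10", "d_IL17", "d_R",
  "y_Mc", "y_F", "m_Mc", "m_F",
  "mu_Mc", "mu_M", "mu_N", "mu_S", "mu_T",
  paste0("muR_", c("Mc", "N", "M0", "M1", "M2", "S", "T")),
  paste0("cR_",  c("Mc", "N", "M0", "M1", "M2", "S", "T")),
  "omega", "gamma", "delta", "Rc"
)

## Parameters that must be strictly positive (half-saturation and
## self-inhibition constants appearing in denominators).
.positive_params <- c(
  "c1", "c2", "c3",
  "c_IL10_C", "c_IL1_C", "c_IL10_F", "c_IL17_Mc",
  "c_IL1_M0", "c_IL10_M0", "c_IL17_M0", "c_IL17",
  "m_Mc", "m_F",
  paste0("cR_", c("Mc", "N", "M0", "M1", "M2", "S", "T"))
)

#' Names of all model parameters
#'
#' Returns the canonical ordering of the model parameter vector: the rate
#' constants `k1`..`k22`, the IL-10 inhibition constants `c1`..`c3`, the
#' half-saturation constants, the cytokine/ROS decay rates, the stem-cell
#' differentiation rates, the death/emigration rates, the per-cell-type ROS
#' destruction rates `muR_*` and half-saturations `cR_*`, the treatment
#' multipliers `omega` (oxygenation), `gamma` (risk factors), `delta`
#' (neutrophil recruitment), and the subcritical ROS threshold `Rc`.
#'
#' @return Character vector of parameter names.
#' @export
parameter_names <- function() .param_names

#' Baseline model parameter set
#'
#' The published baseline values for every rate and saturation constant of
#' the post-MI remodeling model (units: rates in 1/day or mL/cells/day or
#' pg/cells/day, concentrations in pg/mL).  The seven ROS destruction rates
#' `muR_*` share one baseline (1.5e-3/day) and the seven ROS
#' half-saturations `cR_*` share another (100 pg/mL), but are stored as
#' independent fields so they can be varied separately in sensitivity
#' analysis.  The treatment multipliers default to `omega = gamma = delta =
#' 1` (normal oxygen restoration, risk profile, and immune activity) and
#' the subcritical ROS threshold defaults to `Rc = 210` pg/mL, the baseline
#' ROS level below which no reperfusion damage occurs.
#'
#' @return A named numeric vector of class `"mi_params"`.
#' @seealso [parameter_ranges()], [validate_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p[["k16"]]
default_parameters <- function() {
  p <- c(
    k1 = 0.3, k2 = 0.09, k3 = 4e-4, k4 = 5e-4, k5 = 5e-4, k6 = 4,
    k7 = 0.7, k8 = 0.3, k9 = 0.075, k10 = 26e5, k11 = 3e-4, k12 = 0.25,
    k13 = 4, k14 = 1e-5, k15 = 1e-3, k16 = 1e-7, k17 = 1e-6, k18 = 4,
    k19 = 1, k20 = 0.7, k21 = 1e-6, k22 = 1e-6,
    c1 = 25, c2 = 100, c3 = 100,
    c_IL10_C = 5, c_IL1_C = 10, c_IL10_F = 2.5, c_IL17_Mc = 10,
    c_IL1_M0 = 10, c_IL10_M0 = 5, c_IL17_M0 = 10, c_IL17 = 100,
    d_IL1 = 10.5, d_IL10 = 5, d_IL17 = 10.5, d_R = 10.5,
    y_Mc = 0.9, y_F = 0.9, m_Mc = 5, m_F = 5,
    mu_Mc = 0.3, mu_M = 0.2, mu_N = 0.3, mu_S = 2, mu_T = 2,
    muR_Mc = 15e-4, muR_N = 15e-4, muR_M0 = 15e-4, muR_M1 = 15e-4,
    muR_M2 = 15e-4, muR_S = 15e-4, muR_T = 15e-4,
    cR_Mc = 100, cR_N = 100, cR_M0 = 100, cR_M1 = 100, cR_M2 = 100,
    cR_S = 100, cR_T = 100,
    omega = 1, gamma = 1, delta = 1, Rc = 210
  )
  stopifnot(identical(names(p), .param_names))
  class(p) <- "mi_params"
  p
}

#' Published uncertainty ranges for the model parameters
#'
#' One row per parameter that carries a published uniform uncertainty
#' range, with `low <= baseline <= high` and `low < high`.  `mu_Mc` (the
#' severity-defining cardiomyocyte death rate) has no published range and
#' is excluded; the treatment multipliers `omega`/`gamma`/`delta` and the
#' threshold `Rc` are scenario settings, not uncertain rates, and are also
#' excluded.  The shared `muR_*` range ([1e-4, 15e-4]) and `cR_*` range
#' ([95, 100]) are expanded to the seven per-cell-type entries each.
#'
#' @return A `data.frame` with columns `name`, `low`, `high`, `baseline`.
#' @export
parameter_ranges <- function() {
  rng <- list(
    k1 = c(0.2, 0.4), k2 = c(1e-2, 0.1), k3 = c(1e-4, 9e-4),
    k4 = c(1e-4, 9e-4), k5 = c(1e-4, 9e-4), k6 = c(1, 10),
    k7 = c(0.1, 0.9), k8 = c(0.1, 9), k9 = c(1e-2, 0.2),
    k10 = c(1e5, 3e6), k11 = c(1e-4, 9e-4), k12 = c(0.1, 0.9),
    k13 = c(0, 4), k14 = c(9e-6, 1e-5), k15 = c(1e-4, 1e-3),
    k16 = c(1e-8, 1e-7), k17 = c(1e-7, 1e-6), k18 = c(3, 4),
    k19 = c(0.5, 1), k20 = c(0.5, 0.7), k21 = c(1e-7, 1e-6),
    k22 = c(1e-7, 1e-6),
    c1 = c(21, 25), c2 = c(95, 100), c3 = c(95, 100),
    c_IL10_C = c(3, 5), c_IL1_C = c(8, 10), c_IL10_F = c(2, 2.5),
    c_IL17_Mc = c(8, 10), c_IL1_M0 = c(8, 10), c_IL10_M0 = c(3, 5),
    c_IL17_M0 = c(8, 10), c_IL17 = c(95, 100),
    d_IL1 = c(10, 10.5), d_IL10 = c(3, 5), d_IL17 = c(10, 10.5),
    d_R = c(10, 10.5),
    y_Mc = c(0.7, 0.9), y_F = c(0.5, 0.9), m_Mc = c(3, 5), m_F = c(3, 5),
    mu_M = c(0.1, 0.2), mu_N = c(0.1, 0.3), mu_S = c(1, 2), mu_T = c(1, 2)
  )
  for (x in c("Mc", "N", "M0", "M1", "M2", "S", "T")) {
    rng[[paste0("muR_", x)]] <- c(1e-4, 15e-4)
    rng[[paste0("cR_", x)]] <- c(95, 100)
  }
  base <- default_parameters()
  out <- data.frame(
    name = names(rng),
    low = vapply(rng, `[`, numeric(1), 1L),
    high = vapply(rng, `[`, numeric(1), 2L),
    baseline = as.numeric(base[names(rng)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ## keep canonical parameter order
  out[order(match(out$name, .param_names)), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Validate a model parameter set
#'
#' Checks that the parameter vector is complete, finite, nonnegative, and
#' that every half-saturation constant is strictly positive.  All
#' violations are aggregated into a single error naming the offending
#' parameters.
#'
#' @param params Named numeric vector as returned by
#'   [default_parameters()], possibly with modified values.
#' @return `params`, unchanged (invisibly classed as `"mi_params"`), if
#'   valid.
#' @export
validate_parameters <- function(params) {
  params <- as_parameters(params)
  bad <- character(0)
  val <- unclass(params)
  nonfinite <- names(val)[!is.finite(val)]
  if (length(nonfinite))
    bad <- c(bad, paste0(nonfinite, " is not finite"))
  neg <- setdiff(names(val)[val < 0], nonfinite)
  if (length(neg))
    bad <- c(bad, paste0(neg, " must be >= 0 (got ", val[neg], ")"))
  nonpos <- setdiff(names(val)[names(val) %in% .positive_params & val <= 0],
                    nonfinite)
  if (length(nonpos))
    bad <- c(bad, paste0(nonpos, " must be > 0 (half-saturation constant)"))
  if (length(bad))
    stop("invalid parameter set:\n  ", paste(unique(bad), collapse = "\n  "),
         call. = FALSE)
  invisible(params)
}

#' Coerce a named vector or list to a full parameter set
#'
#' Missing entries are filled from [default_parameters()]; unknown names
#' are an error.
#'
#' @param x Named numeric vector or list of parameter values (possibly
#'   partial), or an existing `"mi_params"` object.
#' @return Named numeric vector of class `"mi_params"` in canonical order.
#' @export
as_parameters <- function(x) {
  if (inherits(x, "mi_params") && identical(names(unclass(x)), .param_names))
    return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(.param_names))
    names(x) <- .param_names
  unknown <- setdiff(names(x), .param_names)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- unclass(default_parameters())
  p[names(x)] <- as.numeric(x)
  class(p) <- "mi_params"
  p
}

#' @export
print.mi_params <- function(x, ...) {
  cat("<mi_params> ", length(x), " model parameters\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
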