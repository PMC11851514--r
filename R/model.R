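#' Michaelis-Menten saturating fraction
#'
#' The saturation kinetics `x / (x + c)` used throughout the model for
#' cytokine-mediated activation, and its mirror image `c / (c + x)` for
#' IL-10 self-inhibition.  Monotone nondecreasing in `x`, equal to 1/2 at
#' `x = c`, and bounded by 1.
#'
#' @param x Concentration (>= 0), vectorized.
#' @param c Half-saturation constant (> 0).
#' @return `x / (x + c)`, in `[0, 1)`.
#' @export
#' @examples
#' saturating_fraction(100, 100)  # 0.5
saturating_fraction <- function(x, c) {
  if (any(c <= 0)) stop("half-saturation constant must be > 0", call. = FALSE)
  if (any(x < 0)) stop("concentration must be >= 0", call. = FALSE)
  x / (x + c)
}

#' Thresholded ROS-mediated specific death rate
#'
#' Reperfusion damage is gated by the subcritical ROS threshold `Rc`:
#' below it, physiological ROS levels are harmless and the damage
#' multiplier is forced to zero; at or above it, the specific death rate of
#' cell type X is `gamma * muR_X * R / (R + cR_X)`, saturating at
#' `gamma * muR_X` for large R.
#'
#' @param R ROS concentration (pg/mL), vectorized.
#' @param gamma Risk-factor damage multiplier (>= 0; 1 is a normal risk
#'   profile).
#' @param muR_X Maximal ROS destruction rate of cell type X (1/day).
#' @param cR_X ROS half-saturation constant for cell type X (pg/mL, > 0).
#' @param Rc Subcritical ROS threshold (pg/mL).
#' @return Specific death rate (1/day).
#' @export
#' @examples
#' ros_damage_rate(100, gamma = 1, muR_X = 15e-4, cR_X = 100, Rc = 0)
ros_damage_rate <- function(R, gamma, muR_X, cR_X, Rc) {
  if (any(cR_X <= 0)) stop("cR_X must be > 0", call. = FALSE)
  if (any(c(R, gamma, muR_X, Rc) < 0))
    stop("R, gamma, muR_X and Rc must be >= 0", call. = FALSE)
  ifelse(R < Rc, 0, gamma * muR_X * R / (R + cR_X))
}

#' Right-hand side of the ischemic (pre-treatment) model
#'
#' Time derivative of the 14 state variables during the first stage after
#' infarction, before oxygen restoration: IL-17- and neutrophil-mediated
#' cardiomyocyte destruction plus natural ischemic death at rate `mu_Mc`,
#' necrotic-debris-driven recruitment of neutrophils, monocytes and
#' gamma-delta T cells, cytokine secretion with IL-10 inhibition,
#' macrophage polarization, collagen/fibroblast growth, and stem-cell
#' washout.  No regeneration and no ROS damage act during ischemia.  ROS
#' are produced by neutrophils at rate `k1` (with the oxygenation
#' multiplier pinned to 1 before treatment) and decay at rate `d_R`; set
#' `ros_dynamics = FALSE` to freeze R at its initial value instead.
#'
#' @param state Named state vector (see [state_names()]).
#' @param params Parameter set (see [default_parameters()]).
#' @param ros_dynamics Integrate the ROS balance during ischemia (default
#'   `TRUE`)?
#' @return Named numeric vector of derivatives (per day), canonical order.
#' @export
rhs_stage1 <- function(state, params, ros_dynamics = TRUE) {
  .rhs1_core(unclass(as_state(validate_state(state))),
             unclass(validate_parameters(as_parameters(params))),
             ros_dynamics)
}

## unvalidated core: also called by the pure-R integration backend, where
## the adaptive solver may probe marginally negative states
.rhs1_core <- function(y, p, ros_dynamics = TRUE) {
  with(c(as.list(y), as.list(p)), {
    fIL17Mc <- IL17 / (IL17 + c_IL17_Mc)
    fIL1M0 <- IL1 / (IL1 + c_IL1_M0)
    fIL10M0 <- IL10 / (IL10 + c_IL10_M0)
    fIL17M0 <- IL17 / (IL17 + c_IL17_M0)
    d <- c(
      Mc = -k15 * Mc * fIL17Mc - k16 * N * Mc - mu_Mc * Mc,
      Md = k15 * Mc * fIL17Mc + mu_Mc * Mc - k2 * M1 * Md - k17 * N * Md,
      IL1 = k3 * Md + k4 * M1 * c1 / (c1 + IL10) - d_IL1 * IL1,
      IL10 = k21 * T * c3 / (c3 + IL10) + k5 * M2 * c2 / (c2 + IL10) -
        d_IL10 * IL10,
      IL17 = k22 * T * c3 / (c3 + IL10) - d_IL17 * IL17,
      N = k18 * Md + k19 * IL17 / (IL17 + c_IL17) - mu_N * N,
      M0 = k6 * Md - k7 * M0 * fIL1M0 - k8 * M0 * fIL10M0 -
        k20 * M0 * fIL17M0 - mu_M * M0,
      M1 = k7 * M0 * fIL1M0 + k20 * M0 * fIL17M0 - k9 * M1 - mu_M * M1,
      M2 = k8 * M0 * fIL10M0 + k9 * M1 - mu_M * M2,
      C = k10 * F * IL10 / (IL10 + c_IL10_C) - k11 * C * IL1 / (IL1 + c_IL1_C),
      F = k12 * F * IL10 / (IL10 + c_IL10_F),
      S = -mu_S * S,
      T = k13 * Md - mu_T * T,
      R = if (ros_dynamics) k1 * N - d_R * R else 0
    )
    d
  })
}

#' Right-hand side of the reperfused (treatment) model
#'
#' Time derivative of the 14 state variables after oxygen restoration.
#' Relative to the ischemic stage: natural ischemic cardiomyocyte death
#' stops; IL-10-saturated stem-cell differentiation regenerates
#' cardiomyocytes (rate `y_Mc`) and fibroblasts (rate `y_F`); thresholded
#' ROS damage (see [ros_damage_rate()]) removes Mc, N, M0, M1, M2, S and T,
#' with ROS-killed cardiomyocytes transferred to the dead pool; neutrophil
#' recruitment from necrotic debris is scaled by the immune-activity
#' multiplier `delta`; and neutrophil ROS production is scaled by the
#' oxygenation multiplier `omega`.
#'
#' @inheritParams rhs_stage1
#' @return Named numeric vector of derivatives (per day), canonical order.
#' @export
rhs_stage2 <- function(state, params) {
  .rhs2_core(unclass(as_state(validate_state(state))),
             unclass(validate_parameters(as_parameters(params))))
}

.rhs2_core <- function(y, p) {
  with(c(as.list(y), as.list(p)), {
    fIL17Mc <- IL17 / (IL17 + c_IL17_Mc)
    fIL1M0 <- IL1 / (IL1 + c_IL1_M0)
    fIL10M0 <- IL10 / (IL10 + c_IL10_M0)
    fIL17M0 <- IL17 / (IL17 + c_IL17_M0)
    regenMc <- y_Mc * S * IL10 / (IL10 + m_Mc)
    regenF <- y_F * S * IL10 / (IL10 + m_F)
    ## raw thresholded damage law (negative solver probes of R gate to 0)
    rd <- function(mu, cc) if (R < Rc) 0 else gamma * mu * R / (R + cc)
    d <- c(
      Mc = regenMc - k15 * Mc * fIL17Mc - k16 * N * Mc - rd(muR_Mc, cR_Mc) * Mc,
      Md = k15 * Mc * fIL17Mc + rd(muR_Mc, cR_Mc) * Mc - k2 * M1 * Md -
        k17 * N * Md,
      IL1 = k3 * Md + k4 * M1 * c1 / (c1 + IL10) - d_IL1 * IL1,
      IL10 = k21 * T * c3 / (c3 + IL10) + k5 * M2 * c2 / (c2 + IL10) -
        d_IL10 * IL10,
      IL17 = k22 * T * c3 / (c3 + IL10) - d_IL17 * IL17,
      N = delta * k18 * Md + k19 * IL17 / (IL17 + c_IL17) - mu_N * N -
        rd(muR_N, cR_N) * N,
      M0 = k6 * Md - k7 * M0 * fIL1M0 - k8 * M0 * fIL10M0 -
        k20 * M0 * fIL17M0 - mu_M * M0 - rd(muR_M0, cR_M0) * M0,
      M1 = k7 * M0 * fIL1M0 + k20 * M0 * fIL17M0 - k9 * M1 - mu_M * M1 -
        rd(muR_M1, cR_M1) * M1,
      M2 = k8 * M0 * fIL10M0 + k9 * M1 - mu_M * M2 - rd(muR_M2, cR_M2) * M2,
      C = k10 * F * IL10 / (IL10 + c_IL10_C) - k11 * C * IL1 / (IL1 + c_IL1_C),
      F = regenF + k12 * F * IL10 / (IL10 + c_IL10_F),
      S = -regenMc - regenF - k14 * M1 * S - mu_S * S - rd(muR_S, cR_S) * S,
      T = k13 * Md - mu_T * T - rd(muR_T, cR_T) * T,
      R = omega * k1 * N - d_R * R
    )
    d
  })
}
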