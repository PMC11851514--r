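## Canonical state ordering, shared with src/rhs.c and the trajectory CSV
## header -- do not reorder.
.state_names <- c("Mc", "Md", "IL1", "IL10", "IL17", "N", "M0", "M1", "M2",
                  "C", "F", "S", "T", "R")

#' Names of the 14 model state variables
#'
#' In canonical order: live cardiomyocytes `Mc`, dead cardiomyocytes `Md`
#' (cells/mL); cytokines `IL1`, `IL10`, `IL17` (pg/mL); neutrophils `N`,
#' monocytes `M0`, classically activated macrophages `M1`, alternatively
#' activated macrophages `M2` (cells/mL); collagen `C` (pg/mL);
#' fibroblasts `F`, stem cells `S`, gamma-delta T cells `T` (cells/mL);
#' reactive oxygen species `R` (pg/mL).
#'
#' @return Character vector of length 14.
#' @export
state_names <- function() .state_names

#' Initial state at the moment of infarction
#'
#' The published initial conditions: 4e7 cells/mL of live cardiomyocytes,
#' no dead cardiomyocytes, trace cytokine levels (IL1 = 0.1, IL10 = 0.01,
#' IL17 = 0.1 pg/mL), no neutrophils, 2e3 monocytes/mL, no activated
#' macrophages, 839.5e9 pg/mL collagen, 1e8 fibroblasts/mL, 2e7 resident
#' stem cells/mL, no gamma-delta T cells, and the baseline subcritical ROS
#' level of 210 pg/mL.
#'
#' @return A named numeric vector of class `"mi_state"`.
#' @export
#' @examples
#' default_initial_state()[["Mc"]]
default_initial_state <- function() {
  y <- c(Mc = 4e7, Md = 0, IL1 = 0.1, IL10 = 0.01, IL17 = 0.1, N = 0,
         M0 = 2e3, M1 = 0, M2 = 0, C = 839.5e9, F = 1e8, S = 2e7, T = 0,
         R = 210)
  stopifnot(identical(names(y), .state_names))
  class(y) <- "mi_state"
  y
}

#' Validate a state vector
#'
#' A valid state has exactly the 14 named components in canonical order,
#' all finite and nonnegative.
#'
#' @param state Named numeric vector (order-insensitive; reordered to
#'   canonical order).
#' @return The state, canonically ordered, classed `"mi_state"`.
#' @export
validate_state <- function(state) {
  state <- as_state(state)
  v <- unclass(state)
  if (any(!is.finite(v)))
    stop("state components not finite: ",
         paste(names(v)[!is.finite(v)], collapse = ", "), call. = FALSE)
  if (any(v < 0))
    stop("negative state components: ",
         paste0(names(v)[v < 0], " = ", v[v < 0], collapse = ", "),
         call. = FALSE)
  invisible(state)
}

#' @rdname validate_state
#' @export
as_state <- function(state) {
  v <- unlist(state)
  if (is.null(names(v)) && length(v) == 14L) names(v) <- .state_names
  if (!setequal(names(v), .state_names) || length(v) != 14L)
    stop("a state vector needs exactly the components ",
         paste(.state_names, collapse = ", "), call. = FALSE)
  v <- v[.state_names]
  class(v) <- "mi_state"
  v
}
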