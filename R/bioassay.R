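# Endpoint mathematics of the three enzyme systems and the impact
# classification rule applied to residual luminescence.

#' Residual BChE activity
#'
#' Residual (relative) activity of butyrylcholinesterase,
#' `OA = A / A0 x 100%`, where `A` is the substrate-hydrolysis rate in the
#' test solution and `A0` the rate in the control. Values above 100
#' indicate activation rather than inhibition.
#'
#' @param a Hydrolysis rate in the test solution (>= 0). Vectorized.
#' @param a0 Hydrolysis rate in the control solution (> 0).
#' @return Residual activity in percent.
#' @export
residual_activity <- function(a, a0) {
  if (any(!is.finite(a)) || any(a < 0))
    stop("test rate 'a' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(a0)) || any(a0 <= 0))
    stop("control rate 'a0' must be positive", call. = FALSE)
  a / a0 * 100
}

#' Residual luminescence
#'
#' Residual luminescence of a bioluminescent enzyme system,
#' `I / I0 x 100%`, where `I` is the luminescence intensity with the test
#' solution and `I0` with the control. This is the endpoint (T2 for the
#' two-enzyme, T3 for the three-enzyme system) to which the impact
#' classification of [classify_impact()] applies.
#'
#' @param i Luminescence intensity in the test (>= 0). Vectorized.
#' @param i0 Luminescence intensity in the control (> 0).
#' @return Residual luminescence in percent.
#' @export
residual_luminescence <- function(i, i0) {
  if (any(!is.finite(i)) || any(i < 0))
    stop("test intensity 'i' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(i0)) || any(i0 <= 0))
    stop("control intensity 'i0' must be positive", call. = FALSE)
  i / i0 * 100
}

#' Impact class labels, ordered by severity
#' @return `c("no_impact", "impact", "significant_impact")`.
#' @export
impact_levels <- function() c("no_impact", "impact", "significant_impact")

#' Classify the enzymatic impact of a sample
#'
#' Three-level classification of residual luminescence: above 80% the
#' sample has no impact, below 50% a significant impact, and in between
#' an impact. The rule's published inequalities are strict on both sides,
#' leaving the boundary points 50 and 80 unassigned; here both boundaries
#' fall in the middle class (`"impact"`), the conservative,
#' continuity-preserving choice. Defined for any residual endpoint, but
#' intended for the luminescence endpoints T2 and T3; applying it to RA
#' is advisory only.
#'
#' @param residual Residual endpoint in percent (>= 0). Vectorized.
#' @return A factor with levels [impact_levels()], ordered by severity.
#' @examples
#' classify_impact(c(90.78, 78.55, 22))
#' @export
classify_impact <- function(residual) {
  if (any(!is.finite(residual)) || any(residual < 0))
    stop("residual must be finite and >= 0", call. = FALSE)
  lab <- ifelse(residual > 80, "no_impact",
                ifelse(residual >= 50, "impact", "significant_impact"))
  factor(lab, levels = impact_levels())
}

#' Assay kinetics: an optical-density time series
#'
#' Bundles the optical-density readings recorded during the Ellman BChE
#' assay (typically over 5 min at 412 nm) with their time points.
#'
#' @param times Time points in seconds; strictly increasing, length >= 2.
#' @param readings Optical-density values, same length as `times`.
#' @return An object of class `assay_kinetics`.
#' @export
assay_kinetics <- function(times, readings) {
  times <- as.numeric(times)
  readings <- as.numeric(readings)
  if (length(times) < 2L)
    stop("at least 2 time points are required", call. = FALSE)
  if (length(readings) != length(times))
    stop("times and readings must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(readings)))
    stop("readings must be finite", call. = FALSE)
  structure(list(times = times, readings = readings),
            class = "assay_kinetics")
}

#' Substrate hydrolysis rate from assay kinetics
#'
#' Estimates the BChE substrate-hydrolysis rate as the ordinary
#' least-squares slope of optical density versus time over the full
#' recorded window. OLS is the standard estimator for Ellman kinetics and
#' is exact on linear series. Computed in closed form,
#' `sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)`.
#'
#' @param k An [assay_kinetics] object, or a numeric vector of times (in
#'   which case `readings` must be supplied).
#' @param readings Optional readings vector when `k` is a times vector.
#' @return The slope, in optical-density units per second.
#' @examples
#' hydrolysis_rate(assay_kinetics(seq(0, 300, 60), 0.1 + 0.001 * seq(0, 300, 60)))
#' @export
hydrolysis_rate <- function(k, readings = NULL) {
  if (!inherits(k, "assay_kinetics")) k <- assay_kinetics(k, readings)
  t_c <- k$times - mean(k$times)
  y_c <- k$readings - mean(k$readings)
  sum(t_c * y_c) / sum(t_c^2)
}
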