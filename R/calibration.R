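# Cryodistillation fractionation correction.
#
# Soil water recovered by cryodistillation can be isotopically fractionated
# relative to the water actually held in the soil. Running waters of known
# 18O enrichment through the same extraction yields a calibration curve
# (measured ~ known); applying its inverse corrects sample measurements.

#' Fit a cryodistillation calibration curve
#'
#' Ordinary least squares of measured on known atom percent across a set of
#' extraction standards. Two forms are supported: `"linear"` (slope and
#' intercept, the default) and `"offset"` (slope fixed at 1, mean offset
#' only). One curve is fitted per extraction batch.
#'
#' @param known known 18O enrichments of the standards (atom percent).
#' @param measured enrichments measured after extraction (atom percent).
#' @param mode `"linear"` or `"offset"`.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `n_standards`, `residual_sd` and `mode`.
#' @examples
#' fit_calibration(c(1, 5, 10, 20, 40), c(1.1, 5.0, 10.2, 19.9, 39.6))
#' @export
fit_calibration <- function(known, measured, mode = c("linear", "offset")) {
  mode <- match.arg(mode)
  if (!is.numeric(known) || !is.numeric(measured)) {
    stop("known and measured must be numeric", call. = FALSE)
  }
  if (length(known) != length(measured)) {
    stop("known and measured must have equal length", call. = FALSE)
  }
  n <- length(known)
  if (n < 2L) stop("at least 2 standards are required", call. = FALSE)
  if (any(!is.finite(known)) || any(!is.finite(measured))) {
    stop("standards must be finite", call. = FALSE)
  }
  if (mode == "linear" && stats::var(known) == 0) {
    stop("known standards must not all be equal", call. = FALSE)
  }
  if (mode == "linear") {
    fit <- stats::lm(measured ~ known)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    res <- stats::residuals(fit)
  } else {
    intercept <- mean(measured - known)
    slope <- 1
    res <- measured - known - intercept
  }
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate calibration: slope is zero", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, n_standards = n,
         residual_sd = if (n > 2L) stats::sd(res) else 0, mode = mode),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> measured = %.6g * known + %.6g (%s, n = %d, residual sd = %.4g at%%)\n",
    x$slope, x$intercept, x$mode, x$n_standards, x$residual_sd))
  invisible(x)
}

#' Correct a measured enrichment for extraction fractionation
#'
#' Inverts the calibration line: corrected = (measured - intercept) / slope.
#' Corrected values falling outside `[0, 100]` atom percent are clipped to
#' the boundary and flagged via the `out_of_range` attribute (and a
#' warning), since a clipped value signals either an extreme sample or a
#' calibration problem.
#'
#' @param curve a [fit_calibration()] result.
#' @param measured measured enrichment(s), atom percent.
#' @return Corrected atom percent, with logical attribute `out_of_range`.
#' @export
apply_calibration <- function(curve, measured) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a calibration_curve", call. = FALSE)
  }
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  corrected <- (measured - curve$intercept) / curve$slope
  oor <- corrected < 0 | corrected > 100
  if (any(oor, na.rm = TRUE)) {
    warning(sprintf("%d corrected value(s) outside [0, 100] at%% were clipped",
                    sum(oor, na.rm = TRUE)), call. = FALSE)
  }
  corrected <- pmin(pmax(corrected, 0), 100)
  attr(corrected, "out_of_range") <- oor
  corrected
}
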