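# External linear calibration and normalization of adduct responses to
# deoxyguanosine content (adducts per 1e8 dG).

#' Fit an external calibration curve
#'
#' Ordinary least squares of response on concentration; optional 1/x
#' weighting.
#'
#' @param concentration,response Numeric vectors of calibration points
#'   (>= 2 distinct concentrations, responses >= 0).
#' @param weighted If `TRUE`, weight by 1/concentration (all concentrations
#'   must then be > 0). Default unweighted.
#' @param matrix_matched Flag recorded on the curve (matrix-matched
#'   external calibration).
#' @return A `calibration_curve`: `slope`, `intercept`, `r_squared`,
#'   `points`, `response_range`, `weighted`, `matrix_matched`.
#' @examples
#' fit_calibration(c(1, 2, 3), c(10, 20, 30))
#' @export
fit_calibration <- function(concentration, response, weighted = FALSE,
                            matrix_matched = FALSE) {
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 2L)
    stop("need at least 2 distinct concentrations")
  if (any(response < 0)) stop("responses must be >= 0")
  w <- if (weighted) {
    if (any(concentration <= 0)) stop("1/x weighting needs positive concentrations")
    1 / concentration
  } else NULL
  fit <- stats::lm(response ~ concentration, weights = w)
  # summary.lm warns on perfect fits; exact calibration lines are routine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    points = data.frame(concentration = concentration, response = response),
    response_range = range(response),
    weighted = weighted, matrix_matched = matrix_matched
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> response = %.6g x conc %+.6g (r^2 = %.4f)%s\n",
              x$slope, x$intercept, x$r_squared,
              if (x$matrix_matched) " [matrix-matched]" else ""))
  invisible(x)
}

#' Inverse-predict concentrations from responses
#'
#' @param curve A [fit_calibration()] curve.
#' @param response Numeric responses to invert.
#' @return Data frame `response`, `concentration`, `extrapolated`;
#'   responses outside the calibrated response range extended by 20% are
#'   flagged as extrapolated.
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope; cannot invert calibration")
  conc <- (response - curve$intercept) / curve$slope
  rr <- curve$response_range
  span <- diff(rr)
  lo <- rr[1] - 0.2 * span
  hi <- rr[2] + 0.2 * span
  data.frame(response = response, concentration = conc,
             extrapolated = response < lo | response > hi)
}

#' Normalize an adduct amount to deoxyguanosine content
#'
#' The dG aliquot is measured after dilution (100-fold by default), so the
#' measured dG amount is scaled back up before forming the ratio. The
#' result is the dimensionless adduct/dG ratio times 1e8, the conventional
#' "adducts per 10^8 dG" reporting unit.
#'
#' @param adduct_amount Adduct amount (mol, or any unit shared with dG).
#' @param dG_amount Measured dG amount in the diluted aliquot (> 0).
#' @param dilution_factor Dilution factor of the dG aliquot (>= 1,
#'   default 100).
#' @return Adducts per 1e8 dG.
#' @examples
#' normalize_to_dG(1720e-8, 1, dilution_factor = 1)  # 1720 per 1e8 dG
#' @export
normalize_to_dG <- function(adduct_amount, dG_amount,
                            dilution_factor = 100) {
  if (any(dG_amount <= 0)) stop("dG_amount must be > 0")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(adduct_amount < 0)) stop("adduct_amount must be >= 0")
  adduct_amount / (dG_amount * dilution_factor) * 1e8
}
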