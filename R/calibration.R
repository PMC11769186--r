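#' Linear pulse-oximetry calibration curve
#'
#' The standard empirical form `SaO2 = a - b * R` (SaO2 in percent, R the
#' dimensionless ratio of ratios), stored so that `b > 0` encodes the
#' negative correlation of R with oxygen saturation.
#'
#' @param intercept `a`, percent SaO2 at R = 0.
#' @param slope `b`, percent SaO2 per unit R (positive for all shipped
#'   curves).
#' @param skin_type,mode Optional labels.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(intercept, slope, skin_type = NA_character_,
                              mode = NA_character_) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(intercept = intercept, slope = slope,
                 skin_type = skin_type, mode = mode),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve [%s, %s]: SaO2 = %.4g - %.4g * R\n",
              x$skin_type, x$mode, x$intercept, x$slope))
  invisible(x)
}

#' Predict oxygen saturation from the ratio of ratios
#'
#' @param object A [calibration_curve()].
#' @param r Ratio-of-ratios value(s).
#' @param ... Unused.
#' @return Predicted SaO2 in percent.
#' @export
predict.calibration_curve <- function(object, r, ...) {
  object$intercept - object$slope * r
}

#' Fit a linear calibration curve to (saturation, R) points
#'
#' Ordinary least squares of SaO2 (percent) on the ratio of ratios, returned
#' in the field convention `SaO2 = a - b * R`.
#'
#' @param sat_percent Arterial saturations in percent (or fractions in
#'   `[0, 1]`, which are rescaled).
#' @param r Ratio-of-ratios values, at least two distinct.
#' @param skin_type,mode Labels carried onto the fitted curve.
#' @return A `calibration_curve` with attribute `residuals`.
#' @examples
#' fit_curve(c(70, 85, 100), c(1.5, 1.0, 0.5))
#' @export
fit_curve <- function(sat_percent, r, skin_type = NA_character_,
                      mode = NA_character_) {
  stopifnot(length(sat_percent) == length(r), length(r) >= 2)
  if (max(r) - min(r) < .Machine$double.eps * 100) {
    stop("degenerate fit: no spread in R values", call. = FALSE)
  }
  if (all(sat_percent <= 1)) sat_percent <- 100 * sat_percent
  fit <- stats::lm(sat_percent ~ r)
  curve <- calibration_curve(unname(stats::coef(fit)[1]),
                             -unname(stats::coef(fit)[2]),
                             skin_type, mode)
  attr(curve, "residuals") <- unname(stats::residuals(fit))
  curve
}

#' Reference calibration curves
#'
#' Loads the packaged set of simulated finger pulse-oximetry calibration
#' equations — transmittance and reflectance mode for light, moderate and
#' dark skin, plus a commercial-style transmittance curve — from a JSON
#' fixture of (intercept, slope) pairs.
#'
#' @param path JSON fixture path; defaults to the packaged set.
#' @return Named list of [calibration_curve()] objects, names
#'   `"<skin_type>_<mode>"`.
#' @examples
#' reference_curves()$light_reflectance
#' @export
reference_curves <- function(path = system.file("extdata",
                                                "reference_curves.json",
                                                package = "pulseoxmc")) {
  tab <- jsonlite::fromJSON(path)
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    calibration_curve(tab$intercept[i], tab$slope[i],
                      tab$skin_type[i], tab$mode[i])
  })
  names(curves) <- ifelse(tab$skin_type == tab$mode, tab$skin_type,
                          paste(tab$skin_type, tab$mode, sep = "_"))
  names(curves)[tab$mode == "commercial"] <- "commercial"
  curves
}

#' Invert a calibration curve
#'
#' Rearranges `SaO2 = a - b * R` to `R = (a - SaO2) / b`. The conventional
#' reference for bias analysis is the light-skin transmittance curve, which
#' closely matches the commercial calibration.
#'
#' @param sao2 Saturation(s) in percent.
#' @param curve A [calibration_curve()]; default light-skin transmittance
#'   from [reference_curves()].
#' @return Ratio-of-ratios value(s).
#' @export
invert_curve <- function(sao2, curve = reference_curves()$light_transmittance) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope != 0)
  (curve$intercept - sao2) / curve$slope
}

#' Bias between transmittance- and reflectance-mode calibration
#'
#' For each saturation on the grid, the ratio of ratios is obtained by
#' inverting the reference curve; substituting that R into the transmittance
#' and reflectance curves of one skin type gives the two predicted
#' saturations, whose difference (transmittance minus reflectance) is the
#' bias. The grid defaults to the healthy range 95-100% in 1% steps.
#'
#' @param trans,refl Transmittance- and reflectance-mode
#'   [calibration_curve()]s for one skin type.
#' @param reference Curve inverted to generate R values (default light-skin
#'   transmittance).
#' @param grid SaO2 grid in percent.
#' @return A `bias_report`: data frame `sao2, r_reference, bias_percent`
#'   with attribute `rmse` and class methods; see [bias_rmse()].
#' @examples
#' rc <- reference_curves()
#' bias_analysis(rc$light_transmittance, rc$light_reflectance)
#' @export
bias_analysis <- function(trans, refl,
                          reference = reference_curves()$light_transmittance,
                          grid = 95:100) {
  stopifnot(inherits(trans, "calibration_curve"),
            inherits(refl, "calibration_curve"),
            inherits(reference, "calibration_curve"))
  if (length(grid) < 1) stop("bias grid must be non-empty", call. = FALSE)
  r_ref <- invert_curve(grid, reference)
  bias <- predict(trans, r_ref) - predict(refl, r_ref)
  out <- data.frame(sao2 = grid, r_reference = r_ref, bias_percent = bias)
  attr(out, "rmse") <- bias_rmse(bias)
  attr(out, "skin_type") <- trans$skin_type
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Root-mean-square error of a bias vector
#'
#' @param bias Numeric vector of bias values (percent).
#' @return `sqrt(mean(bias^2))`, in percent.
#' @export
bias_rmse <- function(bias) {
  if (length(bias) == 0) stop("empty bias vector", call. = FALSE)
  sqrt(mean(bias^2))
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias_report [%s]: RMSE %.4f%%\n",
              attr(x, "skin_type"), attr(x, "rmse")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Skin-type correction factor for the ratio of ratios
#'
#' A single multiplicative factor aligning a skin type's calibration with a
#' baseline: the mean, over a saturation grid (default 70-100% in 5% steps),
#' of the ratio `R_baseline(s) / R_target(s)` with each R obtained by
#' inverting the respective curve. Applied to measured R values it shifts
#' the target curve towards the baseline.
#'
#' @param target Curve to be corrected (e.g. dark-skin reflectance).
#' @param baseline Curve corrected towards (e.g. light-skin reflectance).
#' @param grid SaO2 grid in percent.
#' @return A `correction_factor`: single positive number with attributes
#'   `skin_type` and `ratios`.
#' @examples
#' rc <- reference_curves()
#' correction_factor(rc$dark_reflectance, rc$light_reflectance)
#' @export
correction_factor <- function(target, baseline, grid = seq(70, 100, by = 5)) {
  stopifnot(inherits(target, "calibration_curve"),
            inherits(baseline, "calibration_curve"), length(grid) >= 1)
  r_target <- invert_curve(grid, target)
  if (any(r_target == 0)) {
    stop("target curve crosses R = 0 on the grid; factor undefined",
         call. = FALSE)
  }
  ratios <- invert_curve(grid, baseline) / r_target
  structure(mean(ratios), skin_type = target$skin_type, ratios = ratios,
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("correction_factor [%s]: %.4f\n",
              attr(x, "skin_type"), unclass(x)))
  invisible(x)
}

#' Apply a correction factor to calibration points
#'
#' Multiplies the ratio-of-ratios column by the factor, leaving
#' saturations unchanged.
#'
#' @param points Data frame with columns `sat_a` (or `sao2`) and `r`.
#' @param factor A [correction_factor()] or a positive number.
#' @return `points` with corrected `r`.
#' @export
apply_correction <- function(points, factor) {
  f <- as.numeric(factor)
  stopifnot(is.finite(f), f > 0, "r" %in% names(points))
  points$r <- f * points$r
  points
}
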