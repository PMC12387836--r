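#' Brunelli regression coefficients
#'
#' Coefficients of the published linear regressions for predicted percentage
#' loss of FEV1 and DLCO after anatomical lung resection:
#'
#' \deqn{FEV1\ loss\ (\%) = 21.34 - 0.47 \cdot age + 0.49 \cdot removed\% +
#'   17.91 \cdot COPD\ index}
#' \deqn{DLCO\ loss\ (\%) = 35.99 - 0.31 \cdot age - 36.47 \cdot FEV1/FVC +
#'   0.33 \cdot DLCO + 0.54 \cdot removed\%}
#'
#' where `removed%` is the percentage of removed functioning lung parenchyma
#' on the 0-100 scale, FEV1/FVC is on the 0-1 scale and DLCO is in measured
#' units (mmol/(min·kPa)). Defaults are fixed to the published values and
#' overridable only through this constructor.
#'
#' @param fev1 named numeric: `intercept`, `age`, `removed_pct`, `copd_index`.
#' @param dlco named numeric: `intercept`, `age`, `fev1_fvc`, `dlco`,
#'   `removed_pct`.
#' @return object of class `brunelli_coefficients`.
#' @export
brunelli_coefficients <- function(
    fev1 = c(intercept = 21.34, age = -0.47, removed_pct = 0.49,
             copd_index = 17.91),
    dlco = c(intercept = 35.99, age = -0.31, fev1_fvc = -36.47,
             dlco = 0.33, removed_pct = 0.54)) {
  need_f <- c("intercept", "age", "removed_pct", "copd_index")
  need_d <- c("intercept", "age", "fev1_fvc", "dlco", "removed_pct")
  if (!all(need_f %in% names(fev1)))
    stop("fev1 coefficients need names: ", paste(need_f, collapse = ", "))
  if (!all(need_d %in% names(dlco)))
    stop("dlco coefficients need names: ", paste(need_d, collapse = ", "))
  structure(list(fev1 = fev1[need_f], dlco = dlco[need_d]),
            class = "brunelli_coefficients")
}

#' COPD index (Korst)
#'
#' Composite obstruction index used as a covariate in the Brunelli FEV1
#' regression: the sum of FEV1 as a fraction of predicted and the FEV1/FVC
#' ratio. A normal subject scores near 1.8-2.0; severe obstruction pushes the
#' index down.
#'
#' @param fev1_pct_pred FEV1 as a fraction of predicted (0.92 for 92%).
#' @param fev1_fvc FEV1/FVC ratio (0-1 scale).
#' @return the index (unitless).
#' @export
copd_index <- function(fev1_pct_pred, fev1_fvc) {
  if (any(fev1_pct_pred <= 0) || any(fev1_pct_pred > 2))
    stop("'fev1_pct_pred' must be a fraction of predicted in (0, 2]")
  if (any(fev1_fvc <= 0) || any(fev1_fvc > 2))
    stop("'fev1_fvc' must be a ratio in (0, 2]")
  fev1_pct_pred + fev1_fvc
}

#' The 5%-per-segment rule
#'
#' Classical segment-counting estimate of postoperative function: each of the
#' ~20 bronchopulmonary segments is assumed to contribute 5% of total lung
#' function, so `ppo = preop * (1 - 0.05 * segments_removed)`. Applies a flat
#' 5% per segment with no renormalisation. Fractional segment counts are
#' accepted so the rule can be evaluated at cohort means.
#'
#' @param preop_value preoperative FEV1 (L) or DLCO (mmol/(min·kPa)).
#' @param segments_removed number of segments removed, >= 0 and <= 20
#'   (removing more than 20 segments would imply negative function).
#' @return predicted postoperative value, same units as `preop_value`.
#' @export
five_percent_rule <- function(preop_value, segments_removed) {
  if (any(segments_removed < 0)) stop("'segments_removed' must be >= 0")
  if (any(segments_removed > 20))
    stop("'segments_removed' must be <= 20 (function cannot go negative)")
  preop_value * (1 - 0.05 * segments_removed)
}

check_removed_pct <- function(removed_functioning_pct) {
  if (any(removed_functioning_pct < 0 | removed_functioning_pct > 100))
    stop("'removed_functioning_pct' must lie in [0, 100]")
  if (any(removed_functioning_pct > 0 & removed_functioning_pct < 1))
    stop("'removed_functioning_pct' looks like a 0-1 fraction; ",
         "supply it on the 0-100 percent scale (16.42 means 16.42%)")
  invisible(TRUE)
}

#' Predicted percentage FEV1 loss (Brunelli regression)
#'
#' Linear evaluation of the published FEV1-loss regression. The result may be
#' negative (a predicted functional gain) and is returned unclamped; clamping
#' happens only when a loss is converted to an absolute value via
#' [apply_loss()].
#'
#' @param age years, > 0.
#' @param removed_functioning_pct percent of removed functioning lung
#'   parenchyma on the 0-100 scale (16.42 means 16.42%).
#' @param copd_index see [copd_index()].
#' @param coefficients a [brunelli_coefficients()] object.
#' @return predicted loss as a percentage of the preoperative FEV1.
#' @export
brunelli_fev1_loss <- function(age, removed_functioning_pct, copd_index,
                               coefficients = brunelli_coefficients()) {
  if (any(age <= 0)) stop("'age' must be positive")
  check_removed_pct(removed_functioning_pct)
  b <- coefficients$fev1
  b[["intercept"]] + b[["age"]] * age +
    b[["removed_pct"]] * removed_functioning_pct +
    b[["copd_index"]] * copd_index
}

#' Predicted percentage DLCO loss (Brunelli regression)
#'
#' @inheritParams brunelli_fev1_loss
#' @param fev1_fvc FEV1/FVC ratio on the 0-1 scale (a value > 1.5 is rejected
#'   as a percent-scale input).
#' @param dlco preoperative DLCO in measured units, mmol/(min·kPa) — not
#'   percent of predicted.
#' @return predicted loss as a percentage of the preoperative DLCO
#'   (unclamped; may be negative).
#' @export
brunelli_dlco_loss <- function(age, fev1_fvc, dlco, removed_functioning_pct,
                               coefficients = brunelli_coefficients()) {
  if (any(age <= 0)) stop("'age' must be positive")
  if (any(fev1_fvc <= 0)) stop("'fev1_fvc' must be positive")
  if (any(fev1_fvc > 1.5))
    stop("'fev1_fvc' looks like a percent-scale input; supply the 0-1 ratio")
  check_removed_pct(removed_functioning_pct)
  b <- coefficients$dlco
  b[["intercept"]] + b[["age"]] * age + b[["fev1_fvc"]] * fev1_fvc +
    b[["dlco"]] * dlco + b[["removed_pct"]] * removed_functioning_pct
}

#' Convert a percentage loss to an absolute postoperative value
#'
#' `ppo = preop * (1 - loss/100)`, clamped at zero with a warning when the
#' loss exceeds 100%. Negative losses (predicted gains) pass through.
#'
#' @param preop_value preoperative value, >= 0.
#' @param loss_pct predicted loss in percent of the preoperative value.
#' @return predicted postoperative value, same units.
#' @export
apply_loss <- function(preop_value, loss_pct) {
  if (any(preop_value < 0)) stop("'preop_value' must be >= 0")
  out <- preop_value * (1 - loss_pct / 100)
  if (any(out < 0)) {
    warning("predicted loss exceeds 100%; postoperative value clamped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Volumetric prediction of postoperative function
#'
#' CT-volumetric model: the predicted postoperative value scales with the
#' fraction of functional (well-aerated) parenchyma left in place,
#' `ppo = preop * (1 - removed_functional_fraction)`. The fraction is the
#' `removed_functional_fraction` of a [simulate_resection()] result.
#'
#' @param preop_value preoperative value, >= 0.
#' @param removed_functional_fraction fraction of whole-lung well-aerated
#'   volume removed, in `[0, 1]`.
#' @return predicted postoperative value, same units.
#' @export
volumetric_ppo <- function(preop_value, removed_functional_fraction) {
  if (any(removed_functional_fraction < 0 | removed_functional_fraction > 1))
    stop("'removed_functional_fraction' must lie in [0, 1]")
  if (any(preop_value < 0)) stop("'preop_value' must be >= 0")
  preop_value * (1 - removed_functional_fraction)
}

#' Predicted postoperative function under all models
#'
#' Convenience wrapper computing ppoFEV1 under the 5% rule, the Brunelli
#' regression and the volumetric model, and ppoDLCO under the 5% rule and the
#' Brunelli regression, for one patient (or vectors of patients).
#'
#' @param preop_fev1 preoperative FEV1 (L).
#' @param preop_dlco preoperative DLCO (mmol/(min·kPa)).
#' @param age years.
#' @param fev1_pct_pred FEV1 as a fraction of predicted (0-2 scale).
#' @param fev1_fvc FEV1/FVC ratio (0-1 scale).
#' @param segments_removed segment count for the 5% rule.
#' @param removed_functional_fraction removed functioning parenchyma as a 0-1
#'   fraction (from [simulate_resection()]); multiplied by 100 for the
#'   Brunelli regressions.
#' @param coefficients a [brunelli_coefficients()].
#' @return object of class `ppo_prediction`: a data.frame with columns
#'   `ppo_fev1_5pct`, `ppo_fev1_brunelli`, `ppo_fev1_volumetric`,
#'   `ppo_dlco_5pct`, `ppo_dlco_brunelli`, `fev1_loss_brunelli_pct`,
#'   `dlco_loss_brunelli_pct` (losses recorded pre-clamp).
#' @export
predict_ppo <- function(preop_fev1, preop_dlco, age, fev1_pct_pred, fev1_fvc,
                        segments_removed, removed_functional_fraction,
                        coefficients = brunelli_coefficients()) {
  ci <- copd_index(fev1_pct_pred, fev1_fvc)
  removed_pct <- 100 * removed_functional_fraction
  fev1_loss <- brunelli_fev1_loss(age, removed_pct, ci, coefficients)
  dlco_loss <- brunelli_dlco_loss(age, fev1_fvc, preop_dlco, removed_pct,
                                  coefficients)
  out <- data.frame(
    ppo_fev1_5pct = five_percent_rule(preop_fev1, segments_removed),
    ppo_fev1_brunelli = apply_loss(preop_fev1, fev1_loss),
    ppo_fev1_volumetric = volumetric_ppo(preop_fev1, removed_functional_fraction),
    ppo_dlco_5pct = five_percent_rule(preop_dlco, segments_removed),
    ppo_dlco_brunelli = apply_loss(preop_dlco, dlco_loss),
    fev1_loss_brunelli_pct = fev1_loss,
    dlco_loss_brunelli_pct = dlco_loss
  )
  class(out) <- c("ppo_prediction", "data.frame")
  out
}

#' @export
print.ppo_prediction <- function(x, digits = 2, ...) {
  cat("<ppo_prediction>", nrow(x), "patient(s)\n")
  print.data.frame(round(as.data.frame(x), digits), ...)
  invisible(x)
}
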