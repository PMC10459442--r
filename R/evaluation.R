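#' Area under the curve by the linear trapezoidal rule
#'
#' AUC from the first to the last point of the profile; no
#' extrapolation to infinity.  A log-down variant (log-linear
#' trapezoids on strictly decreasing segments) is available behind the
#' `method` flag.
#'
#' @param profile a [concentration_profile()], or a numeric vector of
#'   times when `conc` is given.
#' @param conc concentrations when `profile` is a plain time vector.
#' @param method `"linear"` (default) or `"log_down"`.
#' @return AUC in ug*day/mL.
#' @export
auc_trapezoid <- function(profile, conc = NULL,
                          method = c("linear", "log_down")) {
  method <- match.arg(method)
  if (inherits(profile, "concentration_profile")) {
    tt <- profile$times; cc <- profile$concentrations
  } else {
    tt <- profile; cc <- conc
  }
  if (length(tt) < 2) stop("AUC needs at least 2 points")
  if (anyDuplicated(tt)) stop("duplicate times")
  if (is.unsorted(tt, strictly = TRUE))
    stop("times must be strictly increasing")
  dt <- diff(tt)
  c1 <- cc[-length(cc)]; c2 <- cc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "log_down") {
    logok <- c1 > 0 & c2 > 0 & c2 < c1
    seg[logok] <- (c1[logok] - c2[logok]) /
      log(c1[logok] / c2[logok]) * dt[logok]
  }
  sum(seg)
}

#' Average fold error and average absolute fold error
#'
#' `afe` is the geometric mean of prediction/observation ratios,
#' \eqn{10^{\frac{1}{N}\sum \log_{10}(C_{pred}/C_{obs})}}; it measures
#' bias.  `aafe` uses the absolute log ratios and measures spread
#' (always >= 1).
#'
#' @param pred,obs paired positive concentrations of equal length.
#' @return dimensionless fold error.
#' @export
#' @examples
#' afe(c(2, 0.5), c(1, 1))    # 1
#' aafe(c(2, 0.5), c(1, 1))   # 2
afe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' @rdname afe
#' @export
aafe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(abs(log10(pred / obs)))
}

check_pairs <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0)
    stop("pred and obs must be non-empty and of equal length")
  if (any(pred <= 0) || any(obs <= 0))
    stop("fold errors need strictly positive concentrations")
  invisible(TRUE)
}

#' Classify a prediction-error ratio
#'
#' Regulatory-style accuracy classes for predicted/observed ratios:
#' very accurate within 0.80-1.25, acceptable within 0.50-0.80 or
#' 1.25-2.00, inaccurate outside the two-fold range.
#'
#' @param ratio positive predicted/observed ratio (vectorized).
#' @return factor with levels `very_accurate`, `acceptable`,
#'   `inaccurate`.
#' @export
classify <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  out <- ifelse(ratio >= 0.80 & ratio <= 1.25, "very_accurate",
         ifelse(ratio >= 0.50 & ratio <= 2.00, "acceptable",
                "inaccurate"))
  factor(out, levels = c("very_accurate", "acceptable", "inaccurate"))
}

#' Exposure metrics over the observation window
#' @param profile a [concentration_profile()].
#' @return list with `auc` (ug*day/mL) and `cmax` (ug/mL).
#' @export
exposure_metrics <- function(profile) {
  list(auc = auc_trapezoid(profile), cmax = max(profile$concentrations))
}

#' Evaluate a prediction against observations
#'
#' Computes the prediction errors PE = predicted/observed for AUC and
#' Cmax, the AFE and AAFE over paired concentrations, and the accuracy
#' classes.  The predicted profile must be evaluated at the observed
#' times (observations are never interpolated).
#'
#' @param pred_profile,obs_profile [concentration_profile()] objects on
#'   the same time grid.
#' @return an `evaluation_report`: list with `pe_auc`, `pe_cmax`,
#'   `afe`, `aafe`, `n`, `class_auc`, `class_cmax`.
#' @export
evaluate_prediction <- function(pred_profile, obs_profile) {
  if (length(pred_profile$times) == 0 ||
      length(obs_profile$times) == 0)
    stop("empty profiles")
  if (length(pred_profile$times) != length(obs_profile$times) ||
      any(abs(pred_profile$times - obs_profile$times) > 1e-9))
    stop("prediction must be evaluated at the observed times")
  pred <- pred_profile$concentrations
  obs <- obs_profile$concentrations
  pe_auc <- auc_trapezoid(pred_profile) / auc_trapezoid(obs_profile)
  pe_cmax <- max(pred) / max(obs)
  structure(
    list(pe_auc = pe_auc, pe_cmax = pe_cmax,
         afe = afe(pred, obs), aafe = aafe(pred, obs),
         n = length(obs),
         class_auc = classify(pe_auc), class_cmax = classify(pe_cmax)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d  PE(AUC)=%.3g [%s]  PE(Cmax)=%.3g [%s]  AFE=%.3g  AAFE=%.3g\n",
    x$n, x$pe_auc, as.character(x$class_auc), x$pe_cmax,
    as.character(x$class_cmax), x$afe, x$aafe))
  invisible(x)
}

#' Predict a scenario at the times of an observed profile
#' @param scenario a `population_scenario`.
#' @param obs_profile observed [concentration_profile()] supplying the
#'   times and regimen metadata.
#' @param ... passed to [scenario_model()].
#' @return predicted [concentration_profile()] at the observed times.
#' @export
predict_at <- function(scenario, obs_profile, ...) {
  model <- scenario_model(scenario, ...)
  sim <- simulate_regimen(model, profile_regimen(obs_profile),
                          output_times = obs_profile$times)
  p <- sim$profile
  p$study_id <- paste0("pred_", obs_profile$study_id)
  p$population <- obs_profile$population
  p
}
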