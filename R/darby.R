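#' Excess relative risk of major coronary events
#'
#' Linear no-threshold cardiac risk model: the rate of major coronary events
#' increases by 7.4% per Gy of mean heart dose,
#' `ERR = 0.074 Gy^-1 * D_mean`.
#'
#' @param mean_heart_dose Mean heart dose in Gy (>= 0, vectorised).
#' @param slope Excess relative risk per Gy (default 0.074).
#' @return Dimensionless ERR (0.074 means +7.4%).
#' @examples
#' err_mce(1)    # 0.074
#' err_mce(4.5)  # 0.333
#' @export
err_mce <- function(mean_heart_dose, slope = 0.074) {
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (any(is.na(mean_heart_dose)) || any(mean_heart_dose < 0)) {
    stop("`mean_heart_dose` must be non-negative", call. = FALSE)
  }
  slope * mean_heart_dose
}

#' Cumulative risk from a baseline risk and an ERR
#'
#' `cumulative = baseline * (1 + ERR)`. Results above 1 are clamped to 1
#' with a warning (a probability cannot exceed certainty).
#'
#' @param baseline Baseline event probability in [0, 1].
#' @param err Dimensionless excess relative risk (>= -1).
#' @return Cumulative event probability.
#' @examples
#' cumulative_risk(0.016, 0.25)  # 0.02
#' @export
cumulative_risk <- function(baseline, err) {
  if (any(baseline < 0) || any(baseline > 1)) {
    stop("`baseline` must lie in [0, 1]", call. = FALSE)
  }
  if (any(err < -1)) stop("`err` must be >= -1", call. = FALSE)
  out <- baseline * (1 + err)
  if (any(out > 1)) {
    warning("cumulative risk exceeded 1 and was clamped", call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' Back-calculate an ERR from baseline and cumulative risks
#'
#' Inverse of [cumulative_risk()]: `ERR = cumulative / baseline - 1`.
#'
#' @param baseline Baseline event probability (> 0).
#' @param cumulative Cumulative event probability (>= 0).
#' @return Dimensionless ERR.
#' @examples
#' err_from_risks(0.016, 0.020)  # 0.25
#' @export
err_from_risks <- function(baseline, cumulative) {
  if (any(baseline <= 0)) stop("`baseline` must be positive", call. = FALSE)
  if (any(cumulative < 0)) {
    stop("`cumulative` must be non-negative", call. = FALSE)
  }
  cumulative / baseline - 1
}
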