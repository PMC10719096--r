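# Risk-projection arithmetic: translating fitted coefficients into the
# per-examination percent increase and the expected number of excess
# cases among a population examined today.

#' Published anchor estimates
#'
#' The published cohort totals and fitted coefficients (ERR/100 mGy per
#' endpoint, EAR per 100,000 PY per 100 mGy, case counts, the typical
#' present-day examination dose) shipped as a reference input table. These
#' feed the self-contained projection arithmetic; they are inputs, not
#' outputs, of this package.
#'
#' @return A data.frame with columns `name`, `value`, `ci_low`, `ci_high`.
#' @export
published_estimates <- function() {
  read.csv(system.file("extdata", "published_estimates.csv",
                       package = "pedctrisk", mustWork = TRUE))
}

#' @rdname published_estimates
#' @param name Anchor name, e.g. `"err_per_100mGy_all_heme"`.
#' @param field `"value"`, `"ci_low"` or `"ci_high"`.
#' @export
published_value <- function(name, field = "value") {
  pe <- published_estimates()
  i <- match(name, pe$name)
  if (is.na(i)) stop("unknown published anchor: ", name)
  pe[[field]][i]
}

#' Relative risk at a dose under the linear ERR model
#'
#' `RR(Z) = 1 + beta Z`; with the ERR expressed per 100 mGy,
#' `RR = 1 + err * Z / 100`.
#'
#' @param err_per_100mGy ERR per 100 mGy.
#' @param dose_mGy Cumulative ABM dose in mGy.
#' @return Relative risk.
#' @export
rr_at_dose <- function(err_per_100mGy, dose_mGy) {
  rr <- 1 + err_per_100mGy * dose_mGy / 100
  if (any(rr <= 0)) stop("relative risk must be positive")
  rr
}

#' Percent increase in risk implied by the ERR at a given dose
#'
#' At the typical present-day examination dose (8 mGy to the active bone
#' marrow) an ERR of 1.96 per 100 mGy translates to a
#' `100 * 1.96 * 8 / 100 = 15.7` percent increase per examination.
#'
#' @param err_per_100mGy ERR per 100 mGy (point estimate or CI bound).
#' @param dose_mGy Dose per examination in mGy.
#' @return Percent increase (unrounded).
#' @export
err_implied_percent_increase <- function(err_per_100mGy, dose_mGy) {
  stopifnot(is.finite(err_per_100mGy), is.finite(dose_mGy))
  100 * (rr_at_dose(err_per_100mGy, dose_mGy) - 1)
}

#' Expected excess cases among an examined population
#'
#' Under the additive model, a population of `n_persons` each carrying an
#' extra `dose_mGy` from one examination accrues
#' `alpha * dose * n * (years_after_exam - lag)` excess cases: the dose
#' lag removes the first `lag` of the `years_after_exam` years from the
#' at-risk period. With the published EAR of 17.7 per 100,000 PY per
#' 100 mGy, 8 mGy, 10,000 persons and 12 years this gives about 1.4
#' cases.
#'
#' @param ear_alpha EAR in canonical units (cases per PY per mGy); use
#'   [ear_unscale()] for coefficients quoted per 1e5 PY per 100 mGy.
#' @param dose_mGy Dose per examination (mGy).
#' @param n_persons Number of persons examined.
#' @param years_after_exam Projection horizon (years since examination).
#' @param lag Dose lag (years).
#' @return Expected number of excess cases.
#' @export
predict_excess_cases <- function(ear_alpha, dose_mGy, n_persons,
                                 years_after_exam, lag = 2) {
  if (years_after_exam <= lag) {
    warning("projection horizon does not exceed the lag; no at-risk time")
    return(0)
  }
  ear_alpha * dose_mGy * n_persons * (years_after_exam - lag)
}
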