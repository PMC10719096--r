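# Dose-ensemble summaries and per-person exposure metrics.
#
# Doses are absorbed doses to the active bone marrow (ABM), in mGy. Each
# examination carries an ensemble of Monte-Carlo dose realizations (200 in
# the dosimetry system emulated here); the analysis consumes either the
# arithmetic mean (main) or the median (sensitivity) of the ensemble, or an
# exam-count metric assigning exposure 1 to every examination.

#' Summarize a dose-realization ensemble
#'
#' @param ensemble Numeric vector of ABM dose realizations (mGy), all >= 0.
#' @param method `"mean"` (arithmetic mean, the main analysis choice) or
#'   `"median"`.
#' @return A single dose in mGy.
#' @export
summarize_ensemble <- function(ensemble, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(ensemble) == 0L) stop("empty dose ensemble")
  if (any(ensemble < 0)) stop("negative dose realization")
  if (method == "mean") mean(ensemble) else median(ensemble)
}

# matrix of ensembles (exams in rows, rownames = exam_id) -> summary table
summarize_ensembles <- function(ensembles) {
  data.frame(exam_id = rownames(ensembles),
             abm_dose_mean = rowMeans(ensembles),
             abm_dose_median = apply(ensembles, 1, median),
             stringsAsFactors = FALSE)
}

# long doses.csv -> matrix with exam_id rownames
ensembles_from_long <- function(long) {
  stopifnot(all(c("exam_id", "realization_index", "abm_dose_mGy") %in%
                  names(long)))
  long <- long[order(long$exam_id, long$realization_index), ]
  ids <- unique(long$exam_id)
  k <- nrow(long) / length(ids)
  if (k != round(k)) stop("ragged dose ensembles: fixed length required")
  matrix(long$abm_dose_mGy, nrow = length(ids), ncol = k, byrow = TRUE,
         dimnames = list(ids, NULL))
}

#' Dose history of a cohort
#'
#' The per-person exposure trajectory: a step function of age built from the
#' examination ages and the chosen per-exam dose metric. With
#' `metric = "exam_count"` every examination contributes 1, so the
#' cumulative "dose" is the lagged number of examinations.
#'
#' @param cohort A `ct_cohort` whose exam table carries `abm_dose_mean` /
#'   `abm_dose_median` columns (as produced by [simulate_cohort()] or
#'   [read_cohort_tables()]).
#' @param metric `"abm_dose_mean"`, `"abm_dose_median"` or `"exam_count"`.
#' @return A data.frame (`person_id`, `age`, `dose`) sorted by person and
#'   age, with the metric recorded as an attribute.
#' @export
dose_history <- function(cohort,
                         metric = c("abm_dose_mean", "abm_dose_median",
                                    "exam_count")) {
  metric <- match.arg(metric)
  ex <- cohort$exams
  dose <- if (metric == "exam_count") rep(1, nrow(ex)) else ex[[metric]]
  if (is.null(dose)) stop("exam table lacks column ", metric)
  h <- data.table::data.table(person_id = ex$person_id,
                              age = ex$age_at_exam, dose = dose)
  data.table::setorder(h, person_id, age)
  h <- as.data.frame(h)
  attr(h, "metric") <- metric
  h
}

#' Lagged cumulative dose at an age
#'
#' Sums the dose over all examinations received at or before `age - lag`
#' (inclusive boundary: an event exactly `lag` years after an examination
#' counts that examination's dose).
#'
#' @param history A dose-history data.frame for one person or a whole cohort
#'   (columns `age`, `dose`, optionally `person_id`).
#' @param age Attained age (years).
#' @param lag Dose lag (years), default 2.
#' @return For a single-person history, a single dose; with a `person_id`
#'   column, a named vector over the persons present.
#' @export
cumulative_dose_at <- function(history, age, lag = 2) {
  stopifnot(age >= 0, lag >= 0)
  sel <- history$age <= age - lag
  if (is.null(history$person_id) || length(unique(history$person_id)) <= 1L) {
    return(sum(history$dose[sel]))
  }
  out <- setNames(numeric(length(unique(history$person_id))),
                  unique(history$person_id))
  s <- rowsum(history$dose[sel], history$person_id[sel])
  out[rownames(s)] <- s[, 1]
  out
}

#' Cumulative-dose categories
#'
#' Half-open categories `[a, b)` from sorted cutpoints, the last category
#' closed above at the cohort maximum. The default cutpoints are the
#' a-priori analysis categories (<5, 5-<10, 10-<15, 15-<25, 25-<50,
#' >=50 mGy).
#'
#' @param z Cumulative doses (mGy), >= 0.
#' @param cutpoints Increasing lower bounds, first equal to 0.
#' @return Integer category indices (1-based); see
#'   [dose_category_labels()].
#' @export
categorize_dose <- function(z, cutpoints = c(0, 5, 10, 15, 25, 50)) {
  if (any(z < 0)) stop("negative cumulative dose")
  if (is.unsorted(cutpoints, strictly = TRUE)) stop("cutpoints must increase")
  findInterval(z, cutpoints)
}

#' @rdname categorize_dose
#' @export
dose_category_labels <- function(cutpoints = c(0, 5, 10, 15, 25, 50)) {
  n <- length(cutpoints)
  c(paste0("[", cutpoints[-n], ",", cutpoints[-1], ")"),
    paste0(cutpoints[n], "+"))
}

#' Decompose lagged cumulative dose into exposure windows
#'
#' Splits the lagged cumulative dose at `age` into components by age at
#' exposure or by time since exposure, for the effect-modification
#' analyses. Windows must partition the axis; each examination falls in
#' exactly one window and the components sum exactly to
#' [cumulative_dose_at()]. For `by = "time_since_exposure"` the lag acts as
#' a floor: exposures more recent than `lag` contribute nothing.
#'
#' @param history Single-person dose history (columns `age`, `dose`).
#' @param age Attained age.
#' @param lag Dose lag (years).
#' @param windows Increasing window lower bounds; for age at exposure
#'   typically `c(0, 5, 10)` (<5, 5-<10, >=10 years), for time since
#'   exposure `c(2, 5, 10)` (2-<5, 5-<10, >=10 years).
#' @param by `"age_at_exposure"` or `"time_since_exposure"`.
#' @return Named numeric vector of window dose components (mGy).
#' @export
decompose_dose_windows <- function(history, age, lag = 2,
                                   windows = c(0, 5, 10),
                                   by = c("age_at_exposure",
                                          "time_since_exposure")) {
  by <- match.arg(by)
  if (is.unsorted(windows, strictly = TRUE))
    stop("windows must be strictly increasing (non-overlapping)")
  sel <- history$age <= age - lag
  ax <- if (by == "age_at_exposure") history$age[sel] else
    age - history$age[sel]
  idx <- findInterval(ax, windows)
  n <- length(windows)
  labs <- c(paste0("[", windows[-n], ",", windows[-1], ")"),
            paste0(windows[n], "+"))
  out <- setNames(numeric(n), labs)
  if (any(idx == 0))
    stop("exposure falls below the first window bound at ",
         paste(signif(ax[idx == 0], 4), collapse = ", "))
  s <- rowsum(history$dose[sel], idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Persons retained under percentile truncation of cumulative dose
#'
#' The sensitivity analyses exclude the individuals above the 99th, 98th or
#' 95th percentile of the end-of-follow-up cumulative dose distribution.
#' Ties at the threshold are retained (dose <= empirical percentile), which
#' makes the operation idempotent.
#'
#' @param z_end Named vector of end-of-follow-up cumulative doses
#'   (names = person ids) or an unnamed vector.
#' @param p Percentile in (0, 100].
#' @return Logical vector (same order/names) of retained persons.
#' @export
truncate_at_percentile <- function(z_end, p) {
  stopifnot(p > 0, p <= 100)
  z_end <= quantile(z_end, p / 100, names = FALSE, type = 7)
}

#' End-of-follow-up cumulative dose per included person
#'
#' Unlagged cumulative dose at exit (everything received before the end
#' of follow-up); the quantity whose empirical percentiles define the
#' truncation sensitivity analyses.
#'
#' @param cohort A `ct_cohort` with follow-up derived.
#' @param metric Per-exam dose metric.
#' @return Named numeric vector over included persons (mGy).
#' @export
end_of_followup_dose <- function(cohort,
                                 metric = "abm_dose_mean") {
  fu <- cohort$followup
  if (is.null(fu)) stop("derive follow-up first")
  h <- dose_history(cohort, metric)
  inc <- fu[fu$included, ]
  dt <- data.table::as.data.table(h)
  fi <- data.table::data.table(person_id = inc$person_id,
                               exit = inc$exit_age)
  dt <- dt[fi, on = "person_id"]
  agg <- dt[age <= exit, .(z = sum(dose)), by = person_id]
  out <- setNames(numeric(nrow(inc)), inc$person_id)
  out[agg$person_id] <- agg$z
  out
}
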