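# Orchestration of the full dose-response analysis and the sensitivity
# suite, with report tables in the layout of the published dose-response,
# effect-modification and sensitivity tables.

#' Analysis configuration
#'
#' @param endpoints Endpoint groups to analyse (each independently).
#' @param lag Dose lag in years (2 main; 1 and 5 in sensitivity).
#' @param metric Per-exam dose metric.
#' @param cutpoints Categorical dose cutpoints (mGy).
#' @param strata_vars Stratification variables.
#' @param age_windows,tse_windows Exposure-window bounds for the
#'   age-at-exposure and time-since-exposure heterogeneity tests.
#' @param ear_age_bands Attained-age bands for the person-year table.
#' @param ear_background Background-strata variables for [fit_ear()].
#' @param with_ear,with_heterogeneity Toggles for the heavier components.
#' @param sensitivity Which sensitivity variants [run_sensitivity_suite()]
#'   runs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(endpoints = c("all_heme", "lymphoid",
                                          "myeloid_AL"),
                            lag = 2, metric = "abm_dose_mean",
                            cutpoints = c(0, 5, 10, 15, 25, 50),
                            strata_vars = c("sex", "country",
                                            "birth_cohort"),
                            age_windows = c(0, 5, 10),
                            tse_windows = c(2, 5, 10),
                            ear_age_bands = seq(0, 60, 5),
                            ear_background = c("age_band", "sex"),
                            with_ear = TRUE, with_heterogeneity = TRUE,
                            sensitivity = c("lag_1", "lag_5",
                                            "median_dose",
                                            "truncate_99", "truncate_98",
                                            "truncate_95", "exclude_5y",
                                            "exclude_10y",
                                            "born_after_registry",
                                            "drop_low_reporting",
                                            "followup_cap",
                                            "require_vital_status",
                                            "leave_one_country_out")) {
  structure(list(endpoints = endpoints, lag = lag, metric = metric,
                 cutpoints = cutpoints, strata_vars = strata_vars,
                 age_windows = age_windows, tse_windows = tse_windows,
                 ear_age_bands = ear_age_bands,
                 ear_background = ear_background, with_ear = with_ear,
                 with_heterogeneity = with_heterogeneity,
                 sensitivity = sensitivity),
            class = "analysis_config")
}

#' Run the main dose-response analysis
#'
#' For every endpoint: the continuous linear ERR fit with
#' profile-likelihood CI, the categorical RR table with Wald CIs and trend
#' test, heterogeneity tests by age at exposure, time since exposure and
#' sex, and the additive EAR fit on the person-year table. Deterministic
#' given the cohort and configuration.
#'
#' @param cohort A `ct_cohort` (follow-up is derived here if absent).
#' @param config An [analysis_config()].
#' @return A results bundle (list of per-endpoint results plus metadata).
#' @export
run_main_analysis <- function(cohort, config = analysis_config()) {
  if (is.null(cohort$followup))
    cohort <- apply_inclusion_exclusion(cohort)
  res <- list()
  for (ep in config$endpoints) {
    rs <- build_risk_sets(cohort, endpoint = ep, lag = config$lag,
                          metric = config$metric,
                          strata_vars = config$strata_vars,
                          cutpoints = config$cutpoints)
    if (rs$n_cases == 0L) {
      res[[ep]] <- list(status = "no cases")
      next
    }
    r <- list(status = "ok",
              continuous = fit_linear_err(rs),
              categorical = fit_categorical_rr(rs))
    if (config$with_heterogeneity) {
      r$het_age_at_exposure <- test_heterogeneity(
        build_risk_sets(cohort, ep, config$lag, config$metric,
                        config$strata_vars,
                        windows = config$age_windows,
                        window_by = "age_at_exposure"))
      r$het_time_since_exposure <- test_heterogeneity(
        build_risk_sets(cohort, ep, config$lag, config$metric,
                        config$strata_vars,
                        windows = config$tse_windows,
                        window_by = "time_since_exposure"))
      r$het_sex <- test_heterogeneity(
        build_risk_sets(cohort, ep, config$lag, config$metric,
                        config$strata_vars, group_var = "sex"))
    }
    if (config$with_ear) {
      pyt <- tabulate_person_years(cohort, ep,
                                   age_bands = config$ear_age_bands,
                                   cutpoints = config$cutpoints,
                                   lag = config$lag,
                                   metric = config$metric,
                                   strata_vars = config$strata_vars)
      r$ear <- fit_ear(pyt, background = config$ear_background)
    }
    res[[ep]] <- r
  }
  structure(list(endpoints = res, config = config,
                 n_included = sum(cohort$followup$included),
                 person_years = person_years(cohort),
                 exclusion_log = cohort$exclusion_log),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", length(x$endpoints), "endpoint(s);",
      x$n_included, "persons;", round(x$person_years), "PY\n")
  for (ep in names(x$endpoints)) {
    cat("--", ep, "--\n")
    if (identical(x$endpoints[[ep]]$status, "ok")) {
      print(x$endpoints[[ep]]$continuous)
    } else cat("  status:", x$endpoints[[ep]]$status, "\n")
  }
  invisible(x)
}

# refit the continuous ERR after subsetting persons; helper for the
# sensitivity suite
refit_subset <- function(cohort, keep_ids, config, rules, lag = NULL,
                         metric = NULL, endpoint) {
  sub <- cohort
  sub$persons <- cohort$persons[cohort$persons$person_id %in% keep_ids, ,
                                drop = FALSE]
  sub$exams <- cohort$exams[cohort$exams$person_id %in% keep_ids, ,
                            drop = FALSE]
  sub$outcomes <- cohort$outcomes[cohort$outcomes$person_id %in%
                                    keep_ids, , drop = FALSE]
  sub$followup <- sub$exclusion_log <- NULL
  sub <- apply_inclusion_exclusion(sub, rules)
  rs <- build_risk_sets(sub, endpoint = endpoint,
                        lag = lag %||% config$lag,
                        metric = metric %||% config$metric,
                        strata_vars = config$strata_vars)
  fit_linear_err(rs)
}

#' Run the sensitivity suite
#'
#' One row per variant: alternative dose lags (1, 5 years), the median
#' dose-realization summary, percentile truncation of the cumulative dose
#' distribution (99/98/95), longer exclusion windows after the first CT
#' (5, 10 years), dropping persons born before cancer registration
#' started, dropping low-reporting hospitals, capping follow-up shortly
#' after the country-specific maximum age at exposure, requiring known
#' vital status, and leave-one-country-out. Variants that change entry or
#' membership re-derive follow-up and risk sets from scratch.
#'
#' @param cohort A `ct_cohort`.
#' @param config An [analysis_config()].
#' @param endpoint Endpoint analysed across the suite.
#' @param followup_cap Named per-country attained-age caps for the
#'   `followup_cap` variant; defaults to the country age caps of the
#'   simulation configuration plus the entry offset, when the cohort was
#'   simulated.
#' @return A data.frame (variant, n_cases, err_per_100mGy, ci_low,
#'   ci_high, status).
#' @export
run_sensitivity_suite <- function(cohort, config = analysis_config(),
                                  endpoint = "all_heme",
                                  followup_cap = NULL) {
  if (is.null(cohort$followup))
    cohort <- apply_inclusion_exclusion(cohort)
  base_rules <- inclusion_rules()
  all_ids <- cohort$persons$person_id
  if (is.null(followup_cap) && !is.null(cohort$config))
    followup_cap <- cohort$config$country_age_cap + 2

  variants <- list()
  add <- function(name, fit) variants[[name]] <<- fit
  safely <- function(expr) tryCatch(expr, error = function(e)
    structure(list(status = conditionMessage(e)), class = "err_fit"))

  for (v in config$sensitivity) {
    if (v == "lag_1")
      add("lag_1", safely(refit_subset(cohort, all_ids, config,
                                       base_rules, lag = 1,
                                       endpoint = endpoint)))
    else if (v == "lag_5")
      add("lag_5", safely(refit_subset(cohort, all_ids, config,
                                       base_rules, lag = 5,
                                       endpoint = endpoint)))
    else if (v == "median_dose")
      add("median_dose",
          safely(refit_subset(cohort, all_ids, config, base_rules,
                              metric = "abm_dose_median",
                              endpoint = endpoint)))
    else if (grepl("^truncate_", v)) {
      p <- as.numeric(sub("truncate_", "", v))
      z_end <- end_of_followup_dose(cohort, config$metric)
      keep <- names(z_end)[truncate_at_percentile(z_end, p)]
      add(v, safely(refit_subset(cohort, keep, config, base_rules,
                                 endpoint = endpoint)))
    } else if (v == "exclude_5y")
      add("exclude_5y",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(entry_offset = 5),
                              endpoint = endpoint)))
    else if (v == "exclude_10y")
      add("exclude_10y",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(entry_offset = 10),
                              endpoint = endpoint)))
    else if (v == "born_after_registry")
      add("born_after_registry",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(
                                drop_born_before_registry = TRUE),
                              endpoint = endpoint)))
    else if (v == "drop_low_reporting")
      add("drop_low_reporting",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(drop_low_reporting = TRUE),
                              endpoint = endpoint)))
    else if (v == "require_vital_status")
      add("require_vital_status",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(
                                require_vital_status = TRUE),
                              endpoint = endpoint)))
    else if (v == "drop_transplant")
      add("drop_transplant",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(drop_transplant = TRUE),
                              endpoint = endpoint)))
    else if (v == "followup_cap") {
      if (is.null(followup_cap)) next
      add("followup_cap",
          safely(refit_subset(cohort, all_ids, config,
                              inclusion_rules(
                                followup_cap = followup_cap),
                              endpoint = endpoint)))
    } else if (v == "leave_one_country_out") {
      for (ctry in sort(unique(cohort$persons$country))) {
        keep <- all_ids[cohort$persons$country != ctry]
        add(paste0("drop_country_", ctry),
            safely(refit_subset(cohort, keep, config, base_rules,
                                endpoint = endpoint)))
      }
    }
  }
  rows <- lapply(names(variants), function(nm) {
    f <- variants[[nm]]
    if (identical(f$status, "ok"))
      data.frame(variant = nm, n_cases = f$n_cases,
                 err_per_100mGy = 100 * f$beta,
                 ci_low = 100 * f$ci[1], ci_high = 100 * f$ci[2],
                 status = "ok")
    else
      data.frame(variant = nm, n_cases = f$n_cases %||% NA_integer_,
                 err_per_100mGy = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, status = f$status)
  })
  do.call(rbind, rows)
}

#' Exam-count exposure analysis
#'
#' Refits the continuous linear model with the lagged cumulative number of
#' CT examinations as the exposure metric; the coefficient is the excess
#' relative risk per examination.
#'
#' @param cohort A `ct_cohort`.
#' @param config An [analysis_config()].
#' @param endpoint Endpoint group.
#' @return An `err_fit` whose `beta` is per examination.
#' @export
run_exam_count_analysis <- function(cohort, config = analysis_config(),
                                    endpoint = "all_heme") {
  if (is.null(cohort$followup))
    cohort <- apply_inclusion_exclusion(cohort)
  rs <- build_risk_sets(cohort, endpoint = endpoint, lag = config$lag,
                        metric = "exam_count",
                        strata_vars = config$strata_vars)
  fit_linear_err(rs)
}

#' Write report tables for a results bundle
#'
#' Emits tidy CSVs mirroring the published table layout: a dose-response
#' table (categorical RRs with the reference row at RR 1.00 and no CI,
#' the trend p and the continuous ERR/100 mGy per endpoint), an
#' effect-modification table, an EAR table, and the sensitivity grid when
#' supplied. A `signif` display flag marks estimates whose CI excludes
#' the null (1 for RRs, 0 for ERRs).
#'
#' @param bundle From [run_main_analysis()].
#' @param dir Output directory.
#' @param sensitivity Optional data.frame from [run_sensitivity_suite()].
#' @return Invisibly, the files written.
#' @export
render_report <- function(bundle, dir, sensitivity = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dr <- list(); em <- list(); ear <- list()
  for (ep in names(bundle$endpoints)) {
    r <- bundle$endpoints[[ep]]
    if (!identical(r$status, "ok")) {
      dr[[ep]] <- data.frame(endpoint = ep, model = "status",
                             parameter = r$status, cases = NA,
                             estimate = NA, ci_low = NA, ci_high = NA,
                             p = NA, signif = NA)
      next
    }
    ct <- r$categorical$table
    dr[[ep]] <- rbind(
      data.frame(endpoint = ep, model = "categorical",
                 parameter = ct$category, cases = ct$cases,
                 estimate = ct$rr, ci_low = ct$ci_low,
                 ci_high = ct$ci_high, p = NA_real_,
                 signif = !is.na(ct$ci_low) &
                   (ct$ci_low > 1 | ct$ci_high < 1)),
      data.frame(endpoint = ep, model = "trend", parameter = "P_trend",
                 cases = sum(ct$cases), estimate = NA, ci_low = NA,
                 ci_high = NA, p = r$categorical$trend_p, signif = NA),
      data.frame(endpoint = ep, model = "continuous",
                 parameter = "ERR_per_100mGy",
                 cases = r$continuous$n_cases,
                 estimate = 100 * r$continuous$beta,
                 ci_low = 100 * r$continuous$ci[1],
                 ci_high = 100 * r$continuous$ci[2], p = NA_real_,
                 signif = r$continuous$ci[1] > 0 |
                   r$continuous$ci[2] < 0))
    for (ht in c("het_age_at_exposure", "het_time_since_exposure",
                 "het_sex")) {
      h <- r[[ht]]
      if (is.null(h)) next
      em[[paste(ep, ht)]] <- rbind(
        data.frame(endpoint = ep, modifier = sub("het_", "", ht),
                   level = h$window_labels,
                   estimate = 100 * h$beta,
                   ci_low = 100 * h$ci[, 1], ci_high = 100 * h$ci[, 2],
                   p = NA_real_),
        data.frame(endpoint = ep, modifier = sub("het_", "", ht),
                   level = "heterogeneity_p", estimate = NA,
                   ci_low = NA, ci_high = NA, p = h$p_value))
    }
    if (!is.null(r$ear) && identical(r$ear$status, "ok"))
      ear[[ep]] <- data.frame(
        endpoint = ep, parameter = "EAR_per_100000PY_per_100mGy",
        estimate = ear_scale(r$ear$alpha),
        ci_low = ear_scale(r$ear$ci[1]),
        ci_high = ear_scale(r$ear$ci[2]), cases = r$ear$n_cases)
  }
  wr <- function(df, f) {
    p <- file.path(dir, f)
    write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(files, wr(do.call(rbind, dr), "dose_response.csv"))
  if (length(em))
    files <- c(files, wr(do.call(rbind, em), "effect_modification.csv"))
  if (length(ear)) files <- c(files, wr(do.call(rbind, ear), "ear.csv"))
  if (!is.null(sensitivity)) {
    files <- c(files, wr(sensitivity, "sensitivity.csv"))
  } else {
    writeLines("sensitivity suite: not run",
               file.path(dir, "sensitivity_not_run.txt"))
  }
  if (!is.null(bundle$exclusion_log))
    files <- c(files, wr(bundle$exclusion_log, "exclusion_log.csv"))
  invisible(files)
}
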