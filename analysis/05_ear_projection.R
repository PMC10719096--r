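#!/usr/bin/env Rscript
# Absolute excess risk: person-year table, additive Poisson fit, and the
# projection arithmetic (percent increase per examination at a typical
# 8 mGy dose; expected excess cases among 10,000 examined over 12
# years). The projection is also evaluated at the published coefficients
# as a self-contained check of the arithmetic.

library(pedctrisk)

cohort <- apply_inclusion_exclusion(read_cohort_tables("scratch/cohort"))

pyt <- tabulate_person_years(cohort, "all_heme")
fit <- fit_ear(pyt)
print(fit)

f_err <- fit_linear_err(build_risk_sets(cohort, "all_heme"))
print(f_err)

rows <- data.frame(
  quantity = c(
    "fitted_EAR_per_100000PY_per_100mGy",
    "fitted_EAR_ci_low", "fitted_EAR_ci_high",
    "fitted_pct_increase_per_exam_8mGy",
    "fitted_excess_cases_per_10000_12y",
    "published_pct_increase_per_exam_8mGy",
    "published_excess_cases_per_10000_12y"),
  value = round(c(
    ear_scale(fit$alpha), ear_scale(fit$ci[1]), ear_scale(fit$ci[2]),
    err_implied_percent_increase(100 * f_err$beta, 8),
    predict_excess_cases(fit$alpha, 8, 10000, 12, lag = 2),
    err_implied_percent_increase(
      published_value("err_per_100mGy_all_heme"), 8),
    predict_excess_cases(
      ear_unscale(published_value("ear_per_100k_py_per_100mGy")),
      8, 10000, 12, lag = 2)), 3))
write.csv(rows, "results/table_ear_projection.csv", row.names = FALSE)
print(rows, row.names = FALSE)
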