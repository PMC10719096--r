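#!/usr/bin/env Rscript
# Derive follow-up and apply the inclusion/exclusion rules: entry two
# years after the first CT or at complete registry coverage (whichever is
# later), exit at the first of diagnosis, death, emigration or
# administrative end; drop prior cancers, diagnoses within one year of
# the first CT, and follow-up shorter than two years.

library(pedctrisk)

cohort <- read_cohort_tables("scratch/cohort")
cohort <- apply_inclusion_exclusion(cohort)

fu <- cohort$followup
inc <- fu[fu$included, ]
cat(sprintf("included %d of %d persons; %.0f person-years; mean follow-up %.1f y\n",
            nrow(inc), nrow(fu), person_years(cohort),
            mean(inc$exit_age - inc$entry_age)))
print(cohort$exclusion_log, row.names = FALSE)
write.csv(cohort$exclusion_log, "results/exclusion_log.csv",
          row.names = FALSE)

# Table-1-style cohort summary
z_end <- end_of_followup_dose(cohort)
summ <- data.frame(
  quantity = c("n_included", "person_years", "mean_followup_y",
               "n_cases_all_heme",
               "mean_cum_dose_mGy", "median_cum_dose_mGy",
               "male_share", "uk_share"),
  value = round(c(nrow(inc), person_years(cohort),
                  mean(inc$exit_age - inc$entry_age),
                  build_risk_sets(cohort, "all_heme")$n_cases,
                  mean(z_end), median(z_end),
                  mean(cohort$persons$sex == "male"),
                  mean(cohort$persons$country == "UK")), 3))
write.csv(summ, "results/table1_summary.csv", row.names = FALSE)
print(summ, row.names = FALSE)
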