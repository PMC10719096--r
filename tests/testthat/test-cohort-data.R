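test_that("outcome classification follows the malignancy hierarchy", {
  map <- default_morphology_mapping()

  # a Hodgkin code expands to the full lymphoid chain
  expect_setequal(classify_outcome("9650", 3L, map)[[1]],
                  c("all_heme", "lymphoid", "HL"))
  # non-malignant behavior codes are never cases
  expect_identical(classify_outcome("9650", 1L, map)[[1]], character(0))
  # therapy-related codes are dropped from every endpoint
  expect_identical(classify_outcome("9920", 3L, map)[[1]], character(0))
  # unknown codes are routed to 'unspecified' with a warning
  expect_warning(g <- classify_outcome("1234", 3L, map))
  expect_true("unspecified" %in% g[[1]])

  # hierarchy containment for every code in the mapping
  groups <- suppressWarnings(
    classify_outcome(map$morphology_code, rep(3L, nrow(map)), map))
  for (g in groups) {
    if (length(g) == 0) next
    expect_true("all_heme" %in% g)
    if (any(c("HL", "NHL") %in% g)) expect_true("lymphoid" %in% g)
    if (any(c("matureB", "matureTNK", "precursor") %in% g))
      expect_true("NHL" %in% g)
    if (any(c("AML_ALMP_ALAL", "MPN_MDS") %in% g))
      expect_true("myeloid_AL" %in% g)
    expect_false(all(c("lymphoid", "myeloid_AL") %in% g))
  }

  # pure function: repeated calls agree
  expect_identical(classify_outcome("9680", 3L, map),
                   classify_outcome("9680", 3L, map))
})

make_person <- function(id = "P1", birth = 2000, registry = 1950,
                        death = NA_real_, admin = 2016) {
  data.frame(person_id = id, sex = "female", country = "UK",
             birth_date = birth, registry_start = registry,
             death_date = death, emigration_date = NA_real_,
             admin_end_date = admin, ses = NA_integer_,
             transplant = FALSE, low_reporting_hospital = FALSE,
             vital_status_known = TRUE, stringsAsFactors = FALSE)
}
make_exam <- function(pid, age, birth = 2000) {
  data.frame(exam_id = paste0("E", seq_along(age), "_", pid),
             person_id = pid, age_at_exam = age,
             calendar_year = as.integer(birth + age),
             body_region = "head_neck", hospital_id = "H1",
             abm_dose_mean = 10, abm_dose_median = 10,
             stringsAsFactors = FALSE)
}
no_outcome <- data.frame(person_id = character(0),
                         age_at_diagnosis = numeric(0),
                         morphology_code = character(0),
                         behavior_code = integer(0))

test_that("follow-up entry and exit follow the 2-year / registry rules", {
  # first CT at 6, registry from birth, diagnosis at 14
  oc <- data.frame(person_id = "P1", age_at_diagnosis = 14,
                   morphology_code = "9650", behavior_code = 3L)
  co <- derive_followup(as_cohort(make_person(), make_exam("P1", 6), oc))
  expect_equal(co$followup$entry_age, 8)
  expect_equal(co$followup$exit_age, 14)
  expect_equal(co$followup$exit_reason, "diagnosis")
  expect_true(co$followup$included)

  # registry starts when the person is 10, administrative end at age 12:
  # entry is the later of (first CT + 2) and registry availability
  co <- derive_followup(as_cohort(
    make_person(registry = 2010, admin = 2012),
    make_exam("P1", 6), no_outcome))
  expect_equal(co$followup$entry_age, 10)
  expect_equal(co$followup$exit_age, 12)
  expect_equal(co$followup$exit_reason, "admin_end")

  # death 1.5 years after the first CT: follow-up shorter than 2 years
  co <- derive_followup(as_cohort(make_person(death = 2007.5),
                                  make_exam("P1", 6), no_outcome))
  expect_false(co$followup$included)
  expect_equal(co$followup$exclusion_reason,
               "followup_lt_2y_or_late_entry")
})

test_that("inclusion/exclusion rules and the exclusion log reconcile", {
  # diagnosis half a year after the first CT
  oc <- data.frame(person_id = "P1", age_at_diagnosis = 6.5,
                   morphology_code = "9650", behavior_code = 3L)
  persons <- rbind(make_person("P1"), make_person("P2"))
  exams <- rbind(make_exam("P1", 6), make_exam("P2", 3))
  co <- apply_inclusion_exclusion(as_cohort(persons, exams, oc))
  fu <- co$followup
  expect_equal(fu$exclusion_reason[fu$person_id == "P1"],
               "cancer_within_1y")
  expect_true(fu$included[fu$person_id == "P2"])
  expect_equal(co$exclusion_log$n[co$exclusion_log$reason ==
                                    "cancer_within_1y"], 1L)

  # no rules triggered: everyone retained
  co2 <- apply_inclusion_exclusion(as_cohort(persons[2, ],
                                             make_exam("P2", 3),
                                             no_outcome))
  expect_true(all(co2$followup$included))
  expect_equal(nrow(co2$exclusion_log), 0L)

  # planted short-follow-up persons are all counted in the log
  n_short <- 40
  ids <- sprintf("S%02d", seq_len(n_short))
  pshort <- do.call(rbind, lapply(ids, function(i)
    make_person(i, death = 2013)))     # death at age 13
  eshort <- do.call(rbind, lapply(ids, function(i)
    make_exam(i, 12)))                 # first CT at 12 -> entry 14 > 13
  co3 <- apply_inclusion_exclusion(
    as_cohort(rbind(persons[2, ], pshort),
              rbind(make_exam("P2", 3), eshort), no_outcome))
  expect_equal(
    co3$exclusion_log$n[co3$exclusion_log$reason ==
                          "followup_lt_2y_or_late_entry"], n_short)

  # emptying the cohort is an explicit error
  expect_error(apply_inclusion_exclusion(
    as_cohort(pshort, eshort, no_outcome)), "no persons remain")
})

test_that("person-years equal the sum of included at-risk intervals", {
  co <- apply_inclusion_exclusion(simulate_cohort(test_config(n_persons = 2000)))
  fu <- co$followup
  expect_equal(person_years(co),
               sum((fu$exit_age - fu$entry_age)[fu$included]),
               tolerance = 1e-9)
  # every included person has at least 2 years from first CT to exit
  expect_true(all((fu$exit_age - fu$first_ct_age)[fu$included] >= 2))
})

test_that("cohort tables survive a write/read round trip", {
  cfg <- test_config(seed = 42, n_persons = 1000)
  co <- simulate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  back <- read_cohort_tables(dir)
  expect_equal(nrow(back$persons), nrow(co$persons))
  expect_equal(nrow(back$exams), nrow(co$exams))
  expect_equal(back$persons$birth_date, co$persons$birth_date,
               tolerance = 1e-12)
  expect_equal(back$exams$abm_dose_mean, co$exams$abm_dose_mean,
               tolerance = 1e-12)
  expect_equal(back$outcomes$age_at_diagnosis,
               co$outcomes$age_at_diagnosis, tolerance = 1e-12)
  expect_equal(back$truth$true_beta, co$truth$true_beta)
  unlink(dir, recursive = TRUE)
})

test_that("schema violations are reported by name", {
  p <- make_person(); p$registry_start <- NULL
  expect_error(as_cohort(p, make_exam("P1", 3), no_outcome),
               "registry_start")
  p2 <- rbind(make_person("P1"), make_person("P1"))
  expect_error(as_cohort(p2, make_exam("P1", 3), no_outcome),
               "duplicate")
})
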