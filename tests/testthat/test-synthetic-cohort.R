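test_that("generation is deterministic under (config, seed)", {
  cfg <- test_config(seed = 31, n_persons = 400)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$exams, b$exams)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)
})

test_that("empty and invalid configurations are handled", {
  expect_equal(nrow(sample_persons(test_config(n_persons = 0))), 0)
  expect_error(sim_config(country_weights = c(UK = 0.5, FR = 0.2)),
               "probability")
})

test_that("demographic margins converge to the configured shares", {
  cfg <- test_config(seed = 5, n_persons = 10000)
  p <- sample_persons(cfg)
  expect_equal(mean(p$sex == "male"), 0.56, tolerance = 0.015)
  expect_equal(mean(p$country == "UK"), 0.353, tolerance = 0.02)
})

test_that("examination histories match the published count and mix", {
  cfg <- test_config(seed = 8, n_persons = 50000)
  p <- sample_persons(cfg)
  ex <- sample_exam_histories(p, cfg)
  m <- nrow(ex) / nrow(p)
  expect_gt(m, 1.45); expect_lt(m, 1.60)
  expect_equal(mean(ex$body_region == "head_neck"), 0.81,
               tolerance = 0.01)
  # exam ages non-decreasing within person and below the age cap
  expect_false(is.unsorted(ex$person_id))
  d <- ave(ex$age_at_exam, ex$person_id, FUN = function(x) c(0, diff(x)))
  expect_true(all(d >= 0))
  expect_true(all(ex$age_at_exam <=
                    cfg$country_age_cap[p$country[match(ex$person_id,
                                                        p$person_id)]]))
  # degenerate count model: exactly one exam each
  cfg1 <- test_config(seed = 9, n_persons = 500, exam_extra_mean = 1e-9)
  ex1 <- sample_exam_histories(sample_persons(cfg1), cfg1)
  expect_equal(nrow(ex1), 500)
})

test_that("dose ensembles honor the uncertainty model", {
  newborn_head <- data.frame(
    exam_id = c("A", "B", "C"), person_id = c("P1", "P2", "P3"),
    age_at_exam = 0.2, calendar_year = c(1985L, 1985L, 1985L),
    body_region = "head_neck",
    hospital_id = c("H1", "H1", "H2"), stringsAsFactors = FALSE)

  # degenerate GSDs: every realization equals the period geometric mean
  cfg0 <- sim_config(gsd_unshared = 1, gsd_shared = 1,
                     n_realizations = 200)
  d0 <- sample_dose_realizations(newborn_head, cfg0, seed = 1)
  expect_true(all(d0$ensembles[1, ] == 15))   # head, newborn, <1991
  expect_equal(d0$true_dose, rep(15, 3))

  # unshared GSD recovered from a large ensemble
  cfg2 <- sim_config(gsd_unshared = 2, gsd_shared = 1,
                     n_realizations = 10000)
  d2 <- sample_dose_realizations(newborn_head[1, ], cfg2, seed = 2)
  gsd <- exp(sd(log(d2$ensembles[1, ])))
  expect_gt(gsd, 1.95); expect_lt(gsd, 2.05)

  # shared multiplier identical across exams of one hospital x period
  cfg3 <- sim_config(gsd_unshared = 1, gsd_shared = 2,
                     n_realizations = 50)
  d3 <- sample_dose_realizations(newborn_head, cfg3, seed = 3)
  expect_equal(d3$ensembles[1, ], d3$ensembles[2, ])   # same hospital
  expect_false(all(d3$ensembles[1, ] == d3$ensembles[3, ]))

  # missing dose-model cell is a config error naming the cell
  bad <- newborn_head; bad$body_region <- "dental"
  expect_error(sample_dose_realizations(bad, cfg0), "dental")
})

# helper: uniform cohort for closed-form outcome checks -----------------
flat_cohort <- function(n, dose, horizon = 10, beta = 0, lag = 2,
                        rate = 1e-3) {
  persons <- data.frame(
    person_id = sprintf("F%05d", 1:n), sex = "male", country = "UK",
    birth_date = 2000, registry_start = 1950, death_date = NA_real_,
    emigration_date = NA_real_, admin_end_date = 2000 + horizon,
    ses = NA_integer_, transplant = FALSE,
    low_reporting_hospital = FALSE, vital_status_known = TRUE,
    stringsAsFactors = FALSE)
  exams <- data.frame(
    exam_id = sprintf("X%05d", 1:n), person_id = persons$person_id,
    age_at_exam = 0, calendar_year = 2000L, body_region = "head_neck",
    hospital_id = "H1", true_dose_mGy = dose, stringsAsFactors = FALSE)
  cfg <- sim_config(n_persons = n, true_beta = beta, lag = lag,
                    baseline_hazard = list(age_breaks = c(0, 100),
                                           rate_male = rate,
                                           rate_female = rate))
  list(persons = persons, exams = exams, config = cfg)
}

test_that("event counts match the closed-form piecewise expectation", {
  # beta = 0, constant hazard 1e-3/PY, 1000 persons, 10 PY each:
  # expected events 1000 * (1 - exp(-0.01)) ~ 9.95
  f <- flat_cohort(1000, dose = 0, beta = 0)
  ot <- simulate_outcomes(f$persons, f$exams, f$config, seed = 21)
  expected <- 1000 * (1 - exp(-0.01))
  band <- qpois(c(0.0025, 0.9975), expected)
  expect_gte(nrow(ot$outcomes), band[1])
  expect_lte(nrow(ot$outcomes), band[2])

  # zero baseline hazard: no events at all
  f0 <- flat_cohort(500, dose = 0, beta = 0.02, rate = 0)
  expect_equal(nrow(simulate_outcomes(f0$persons, f0$exams, f0$config,
                                      seed = 1)$outcomes), 0)

  # RR = 3 scaling: Z = 100 mGy effective from the start (lag 0)
  f3 <- flat_cohort(4000, dose = 100, beta = 0.02, lag = 0)
  ot3 <- simulate_outcomes(f3$persons, f3$exams, f3$config, seed = 22)
  expected3 <- 4000 * (1 - exp(-3 * 0.01))
  band3 <- qpois(c(0.0025, 0.9975), expected3)
  expect_gte(nrow(ot3$outcomes), band3[1])
  expect_lte(nrow(ot3$outcomes), band3[2])
})

test_that("doses inside the lag window cannot influence the hazard", {
  # all follow-up lies within `lag` of the only exam: a huge dose must
  # leave the simulated outcomes identical to a zero dose
  fa <- flat_cohort(2000, dose = 0, beta = 0.05, lag = 2, horizon = 2)
  fb <- flat_cohort(2000, dose = 1e5, beta = 0.05, lag = 2, horizon = 2)
  oa <- simulate_outcomes(fa$persons, fa$exams, fa$config, seed = 4)
  ob <- simulate_outcomes(fb$persons, fb$exams, fb$config, seed = 4)
  expect_identical(oa$outcomes$person_id, ob$outcomes$person_id)
  expect_equal(oa$outcomes$age_at_diagnosis, ob$outcomes$age_at_diagnosis)
})

test_that("piecewise-exponential inversion matches fine-grid thinning", {
  # one hazard profile: baseline 0.02 on [0,5), 0.05 on [5,20); dose step
  # at age 8 (exam at 6, lag 2) doubling the relative risk
  n <- 5000
  persons <- data.frame(
    person_id = sprintf("T%05d", 1:n), sex = "female", country = "UK",
    birth_date = 2000, registry_start = 1950, death_date = NA_real_,
    emigration_date = NA_real_, admin_end_date = 2020,
    ses = NA_integer_, transplant = FALSE,
    low_reporting_hospital = FALSE, vital_status_known = TRUE,
    stringsAsFactors = FALSE)
  exams <- data.frame(
    exam_id = sprintf("Y%05d", 1:n), person_id = persons$person_id,
    age_at_exam = 6, calendar_year = 2006L, body_region = "head_neck",
    hospital_id = "H1", true_dose_mGy = 50, stringsAsFactors = FALSE)
  cfg <- sim_config(n_persons = n, true_beta = 0.02, lag = 2,
                    baseline_hazard = list(age_breaks = c(0, 5, 20),
                                           rate_male = c(0.02, 0.05),
                                           rate_female = c(0.02, 0.05)))
  ot <- simulate_outcomes(persons, exams, cfg, seed = 17)
  engine_times <- ot$outcomes$age_at_diagnosis - 6  # clock from first CT

  # independent sampler: discrete thinning on a fine grid
  set.seed(18)
  grid <- seq(6, 20, by = 0.002)
  lam <- ifelse(grid < 5, 0.02, 0.05) * ifelse(grid >= 8, 2, 1)
  p_step <- lam * 0.002
  draws <- replicate(5000, {
    hit <- which(runif(length(grid)) < p_step)
    if (length(hit)) grid[hit[1]] - 6 else NA_real_
  })
  grid_times <- draws[!is.na(draws)]

  expect_gt(suppressWarnings(ks.test(engine_times, grid_times))$p.value, 0.01)
})

test_that("the truth table carries the generating parameters", {
  co <- simulate_cohort(test_config(seed = 12, n_persons = 800))
  expect_equal(unique(co$truth$true_beta), 0.02)
  expect_equal(unique(co$truth$seed), 12)
  expect_equal(sum(co$truth$event), nrow(co$outcomes))
  # events recorded with their true lagged cumulative dose
  tr <- co$truth[co$truth$event == 1, ]
  for (i in seq_len(min(5, nrow(tr)))) {
    ex <- co$exams[co$exams$person_id == tr$person_id[i], ]
    expect_equal(tr$true_cum_dose_at_event[i],
                 sum(ex$true_dose_mGy[ex$age_at_exam <=
                                        tr$event_age[i] - 2]),
                 tolerance = 1e-9)
  }
})
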