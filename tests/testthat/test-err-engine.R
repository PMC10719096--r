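test_that("the toy cohort reproduces the closed-form ERR", {
  co <- toy_cohort()
  rs <- build_risk_sets(co, "all_heme", lag = 2)
  expect_equal(rs$n_cases, 2L)
  expect_equal(sort(rs$n_members), c(2L, 3L))
  # engine likelihood equals the hand-derived expression on a grid
  for (b in c(-0.05, 0, 0.01, 0.0414, 0.2, 1))
    expect_equal(linear_err_loglik(b, rs), toy_loglik(b),
                 tolerance = 1e-12)
  fit <- fit_linear_err(rs)
  expect_equal(fit$beta, (sqrt(2) - 1) / 10, tolerance = 1e-6)
  # profile CI endpoints sit exactly at the chi-square drop
  for (b in fit$ci)
    expect_equal(2 * (fit$loglik - linear_err_loglik(b, rs)),
                 qchisq(0.95, 1), tolerance = 1e-6)
})

test_that("the null likelihood is the log product of risk-set sizes", {
  co <- toy_cohort()
  rs <- build_risk_sets(co, "all_heme")
  expect_equal(linear_err_loglik(0, rs), -sum(log(rs$n_members)))
})

test_that("engine risk sets match an exhaustive brute-force oracle", {
  co <- apply_inclusion_exclusion(
    simulate_cohort(test_config(seed = 3, n_persons = 2500,
                                hazard_mult = 20)))
  rs <- build_risk_sets(co, "all_heme")
  bf <- brute_force_risk_sets(co, "all_heme")
  expect_equal(rs$n_cases, length(bf))
  expect_gt(rs$n_cases, 10)
  expect_equal(rs$n_members, lengths(lapply(bf, `[[`, "members")))
  expect_equal(rs$sum_z, vapply(bf, function(s) sum(s$z), numeric(1)),
               tolerance = 1e-12)
  for (b in c(0, 0.005, 0.02, 0.1))
    expect_equal(linear_err_loglik(b, rs), brute_force_loglik(b, bf),
                 tolerance = 1e-12)

  # membership invariant, checked exhaustively
  fu <- co$followup
  for (s in bf) {
    j <- match(s$members, fu$person_id)
    expect_true(all(fu$entry_age[j] < s$t & s$t <= fu$exit_age[j]))
    expect_true(s$case %in% s$members)
  }
  # stratification contract: members share the case's stratum
  strat <- stratum_ids(co$persons)
  names(strat) <- co$persons$person_id
  for (i in seq_len(rs$n_cases)) {
    mem <- rs$member_person[rs$member_set == i]
    expect_true(all(strat[mem] == rs$cases$stratum[i]))
  }
})

test_that("identical fits from identical inputs, flat data flagged", {
  co <- toy_cohort()
  rs <- build_risk_sets(co, "all_heme")
  f1 <- fit_linear_err(rs); f2 <- fit_linear_err(rs)
  expect_identical(f1, f2)

  # all-zero exposures: explicit non-identifiable status, not a number
  co0 <- co
  co0$exams$abm_dose_mean <- 0
  rs0 <- build_risk_sets(co0, "all_heme")
  f0 <- fit_linear_err(rs0)
  expect_equal(f0$status, "non_identifiable")
  expect_true(is.na(f0$beta))
  # constant likelihood in beta
  expect_equal(linear_err_loglik(0, rs0), linear_err_loglik(0.5, rs0))
})

test_that("categorical fit agrees with conditional logistic regression", {
  co <- apply_inclusion_exclusion(
    simulate_cohort(test_config(seed = 6, n_persons = 4000,
                                hazard_mult = 30)))
  rs <- build_risk_sets(co, "all_heme", cutpoints = c(0, 5, 15))
  fit <- suppressWarnings(fit_categorical_rr(rs))
  expect_equal(fit$table$rr[1], 1)
  expect_true(is.na(fit$table$ci_low[1]))

  # independent oracle: survival::clogit on the member-level data
  cat_all <- categorize_dose(rs$member_z, rs$cutpoints)
  keep <- colSums(rs$cat_counts) > 0
  df <- data.frame(set = rs$member_set, case = 0L,
                   cat = factor(cat_all))
  idx <- vapply(seq_len(rs$n_cases), function(i)
    which(rs$member_set == i &
            rs$member_person == rs$cases$case_person[i])[1], integer(1))
  df$case[idx] <- 1L
  suppressPackageStartupMessages(library(survival))
  cl <- survival::clogit(case ~ cat + strata(set), data = df)
  expect_equal(unname(fit$gamma), unname(coef(cl)), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(cl)))), tolerance = 1e-3)
})

test_that("categorical relative risks recover a designed RR of 2", {
  # designed risk sets: 3 categories, cases drawn with RR (1, 2, 1)
  set.seed(40)
  rr_true <- c(1, 2, 1)
  n_sets <- 1500
  member_cat <- replicate(n_sets, sample(1:3, 12, replace = TRUE),
                          simplify = FALSE)
  case_cat <- vapply(member_cat, function(m) {
    w <- rr_true[m] / sum(rr_true[m])
    m[sample.int(length(m), 1, prob = w)]
  }, integer(1))
  rs <- make_cat_risk_sets(member_cat, case_cat, K = 3)
  fit <- fit_categorical_rr(rs)
  expect_gt(fit$table$rr[2], 1.8)
  expect_lt(fit$table$rr[2], 2.2)
  expect_equal(fit$table$rr[3], 1, tolerance = 0.2)

  # category relabeling invariance: shifting every member one category
  # up leaves the fitted contrasts unchanged
  rs_shift <- make_cat_risk_sets(lapply(member_cat, `+`, 1L),
                                 case_cat + 1L, K = 4)
  fit_shift <- suppressWarnings(fit_categorical_rr(rs_shift))
  expect_equal(fit_shift$gamma, fit$gamma, tolerance = 1e-6)
})

test_that("trend test detects gradients and is calibrated under nulls", {
  set.seed(41)
  # strong gradient: RR doubling per category
  rr_true <- c(1, 2, 4)
  member_cat <- replicate(800, sample(1:3, 10, replace = TRUE),
                          simplify = FALSE)
  case_cat <- vapply(member_cat, function(m)
    m[sample.int(length(m), 1, prob = rr_true[m])], integer(1))
  tr <- test_trend(make_cat_risk_sets(member_cat, case_cat, K = 3))
  expect_lt(tr$p_value, 1e-3)

  # permuted case categories: p-values uniform (KS at the 1% level)
  pvals <- replicate(200, {
    cc <- vapply(member_cat, function(m)
      m[sample.int(length(m), 1)], integer(1))
    test_trend(make_cat_risk_sets(member_cat, cc, K = 3))$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # single occupied category: explicit undefined status
  rs1 <- make_cat_risk_sets(replicate(10, rep(1L, 5), simplify = FALSE),
                            rep(1L, 10), K = 3)
  expect_true(is.na(test_trend(rs1)$p_value))

  # mean-dose scores give a similar answer to index scores
  tr2 <- test_trend(make_cat_risk_sets(member_cat, case_cat, K = 3),
                    score = "mean_dose")
  expect_lt(tr2$p_value, 1e-3)
})

test_that("heterogeneity test structure matches the window design", {
  co <- apply_inclusion_exclusion(
    simulate_cohort(test_config(seed = 13, n_persons = 6000,
                                hazard_mult = 30)))
  rs <- build_risk_sets(co, "all_heme", windows = c(0, 5, 10),
                        window_by = "age_at_exposure")
  het <- test_heterogeneity(rs)
  expect_equal(length(het$beta), 3L)
  expect_equal(het$df, 2L)
  expect_true(het$p_value >= 0 && het$p_value <= 1)
  # the full model can only improve on the common slope
  expect_gte(het$loglik_full, het$loglik_common - 1e-8)

  # all exposure in one window: no heterogeneity to test, LRT 0
  rs1 <- build_risk_sets(co, "all_heme", windows = c(0, 50, 60),
                         window_by = "age_at_exposure")
  het1 <- test_heterogeneity(rs1)
  expect_equal(het1$lrt_statistic, 0)

  # windowed exposures conserve the scalar exposure
  expect_equal(rowSums(rs$member_zmat), rs$member_z, tolerance = 1e-9)
})
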