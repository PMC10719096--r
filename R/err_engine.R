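# Stratified partial-likelihood engine for linear excess-relative-risk
# models on the attained-age time scale.
#
# At each case's exact diagnosis age t a risk set is formed from all
# members of the case's stratum (sex x country x birth cohort by default)
# under follow-up at t (entry < t <= exit). With RR = 1 + beta * Z the
# partial-likelihood contribution is log RR_case - log sum_j RR_j; because
# the RR is linear in beta, each risk set enters the likelihood only
# through its size, the case's exposure and the member exposure sum (the
# member-level exposures are kept for admissibility checks and oracle
# verification).

#' Build risk sets for a partial-likelihood analysis
#'
#' @param cohort A `ct_cohort` with follow-up derived (see
#'   [apply_inclusion_exclusion()]).
#' @param endpoint Endpoint group (see [endpoint_groups()]).
#' @param lag Dose lag in years applied when evaluating exposures.
#' @param metric Per-exam exposure metric: `"abm_dose_mean"` (main),
#'   `"abm_dose_median"` or `"exam_count"`.
#' @param strata_vars Stratification variables for [stratum_ids()].
#' @param cutpoints Optional dose cutpoints; when given, members are
#'   assigned time-varying cumulative-dose categories at the event age.
#' @param windows,window_by Optional exposure-window decomposition (see
#'   [decompose_dose_windows()]): member exposures become vectors of
#'   window components.
#' @param group_var Alternative to `windows`: split the (scalar) exposure
#'   by a person-level subgroup (`"sex"` or `"birth_cohort"`) for
#'   dose-by-subgroup interaction tests.
#' @param mapping Morphology mapping table.
#' @return An object of class `err_risk_sets`.
#' @export
build_risk_sets <- function(cohort, endpoint = "all_heme", lag = 2,
                            metric = "abm_dose_mean",
                            strata_vars = c("sex", "country",
                                            "birth_cohort"),
                            cutpoints = NULL, windows = NULL,
                            window_by = c("age_at_exposure",
                                          "time_since_exposure"),
                            group_var = NULL,
                            mapping = default_morphology_mapping()) {
  window_by <- match.arg(window_by)
  fu <- cohort$followup
  if (is.null(fu)) stop("derive follow-up first")
  p <- cohort$persons
  stratum <- stratum_ids(p, strata_vars)

  inc <- fu$included
  mem <- data.table::data.table(
    person_id = fu$person_id[inc],
    entry = fu$entry_age[inc], exit = fu$exit_age[inc],
    stratum = stratum[match(fu$person_id[inc], p$person_id)])

  is_case <- outcome_in_endpoint(cohort$outcomes, endpoint, mapping)
  oc <- cohort$outcomes[is_case, , drop = FALSE]
  oc <- oc[oc$person_id %in% mem$person_id, , drop = FALSE]
  fidx <- match(oc$person_id, fu$person_id)
  keep <- oc$age_at_diagnosis > fu$entry_age[fidx] &
    oc$age_at_diagnosis <= fu$exit_age[fidx]
  oc <- oc[keep, , drop = FALSE]
  if (nrow(oc) == 0L)
    return(structure(list(n_cases = 0L, status = "no cases",
                          endpoint = endpoint),
                     class = "err_risk_sets"))
  cases <- data.table::data.table(
    set = seq_len(nrow(oc)), case_person = oc$person_id,
    t = oc$age_at_diagnosis,
    stratum = stratum[match(oc$person_id, p$person_id)])

  # all (risk set, member) pairs: same stratum, entry < t <= exit
  pairs <- mem[cases, on = .(stratum, entry < t, exit >= t),
               .(set = i.set, person_id = x.person_id, t = i.t),
               allow.cartesian = TRUE]
  data.table::setorder(pairs, set, person_id)

  # lagged cumulative exposure of every member at the event age
  h <- dose_history(cohort, metric)
  steps <- data.table::as.data.table(h)
  data.table::setnames(steps, "age", "qage")
  steps[, cumz := cumsum(dose), by = person_id]
  # exams can tie exactly in age: keep one step per distinct age with
  # the full cumulative dose, so the rolling join stays one-to-one
  steps <- steps[, .(cumz = cumz[.N]), by = .(person_id, qage)]
  pairs[, qage := t - lag]
  pairs[, z := steps[pairs, on = .(person_id, qage), roll = Inf, x.cumz]]
  pairs[is.na(z), z := 0]

  roll_z_at <- function(ages) {
    q <- data.table::data.table(person_id = pairs$person_id, qage = ages)
    z <- steps[q, on = .(person_id, qage), roll = Inf, x.cumz]
    ifelse(is.na(z), 0, z)
  }

  zmat <- NULL
  wlabs <- NULL
  if (!is.null(windows)) {
    k <- length(windows)
    wlabs <- c(paste0("[", windows[-k], ",", windows[-1], ")"),
               paste0(windows[k], "+"))
    zmat <- matrix(0, nrow(pairs), k, dimnames = list(NULL, wlabs))
    if (window_by == "age_at_exposure") {
      # cumulative dose restricted to exam ages below each window bound
      up <- c(windows[-1], Inf)
      for (m in seq_len(k)) {
        hi <- roll_z_at(pmin(pairs$t - lag, up[m] - 1e-12))
        lo <- if (windows[m] <= 0) 0 else
          roll_z_at(pmin(pairs$t - lag, windows[m] - 1e-12))
        zmat[, m] <- hi - lo
      }
    } else {
      # time since exposure in [w_m, w_{m+1})  <=>
      # exam age in (t - w_{m+1}, t - w_m], with the lag as a floor
      up <- c(windows[-1], Inf)
      for (m in seq_len(k)) {
        hi <- roll_z_at(pmin(pairs$t - windows[m], pairs$t - lag))
        lo <- roll_z_at(pairs$t - up[m])
        zmat[, m] <- hi - lo
      }
    }
  } else if (!is.null(group_var)) {
    gv <- switch(group_var,
                 sex = p$sex,
                 birth_cohort = birth_cohort_bin(p$birth_date),
                 stop("unsupported group_var: ", group_var))
    gmem <- gv[match(pairs$person_id, p$person_id)]
    wlabs <- sort(unique(gv))
    zmat <- matrix(0, nrow(pairs), length(wlabs),
                   dimnames = list(NULL, wlabs))
    zmat[cbind(seq_len(nrow(pairs)), match(gmem, wlabs))] <- pairs$z
  }

  n_members <- pairs[, .N, by = set]$N
  is_case_row <- pairs$person_id == cases$case_person[pairs$set]
  # a person can (in principle) appear once per risk set only
  case_rows <- which(is_case_row)
  stopifnot(length(case_rows) == nrow(cases))

  cat_case <- cat_counts <- NULL
  if (!is.null(cutpoints)) {
    cat <- categorize_dose(pairs$z, cutpoints)
    K <- length(cutpoints)
    cat_counts <- matrix(0L, nrow(cases), K,
                         dimnames = list(NULL,
                                         dose_category_labels(cutpoints)))
    tab <- pairs[, .(n = .N), by = .(set, cat = cat)]
    cat_counts[cbind(tab$set, tab$cat)] <- tab$n
    cat_case <- cat[case_rows]
  }

  structure(list(
    n_cases = nrow(cases),
    cases = data.frame(case_person = cases$case_person,
                       event_age = cases$t, stratum = cases$stratum,
                       n_members = n_members),
    case_z = pairs$z[case_rows],
    sum_z = as.numeric(pairs[, .(s = sum(z)), by = set]$s),
    n_members = n_members,
    member_z = pairs$z,
    member_set = pairs$set,
    member_person = pairs$person_id,
    case_zmat = if (!is.null(zmat)) zmat[case_rows, , drop = FALSE],
    sum_zmat = if (!is.null(zmat))
      rowsum(zmat, pairs$set, reorder = TRUE),
    member_zmat = zmat,
    window_labels = wlabs,
    cat_case = cat_case, cat_counts = cat_counts,
    cutpoints = cutpoints,
    max_z = max(pairs$z),
    informative = any(pairs[, .(v = max(z) - min(z)), by = set]$v > 0),
    n_singleton = sum(n_members == 1L),
    endpoint = endpoint, lag = lag, metric = metric,
    strata_vars = strata_vars, status = "ok"),
    class = "err_risk_sets")
}

#' @export
print.err_risk_sets <- function(x, ...) {
  cat("<err_risk_sets>", x$n_cases, "risk sets, endpoint", x$endpoint,
      "\n")
  if (x$n_cases) {
    cat("  mean size", round(mean(x$n_members), 1), "; lag", x$lag,
        "y; metric", x$metric, "\n")
    if (x$n_singleton)
      cat("  ", x$n_singleton,
          "singleton risk set(s) contribute no information\n")
  }
  invisible(x)
}

#' Partial log-likelihood of the linear ERR model
#'
#' `sum_j [ log(1 + beta Z_case_j) - log sum_i (1 + beta Z_ij) ]` over the
#' risk sets. `beta` may be a vector when the risk sets carry windowed
#' exposures (`RR = 1 + sum_m beta_m Z_m`). Returns `-Inf` when any
#' member's relative risk would be non-positive.
#'
#' @param beta ERR per unit exposure (scalar, or vector of window
#'   coefficients).
#' @param rs An `err_risk_sets`.
#' @return Log-likelihood value.
#' @export
linear_err_loglik <- function(beta, rs) {
  if (length(beta) == 1L) {
    if (1 + beta * rs$max_z <= 0 || any(1 + beta * rs$case_z <= 0))
      return(-Inf)
    return(sum(log1p(beta * rs$case_z)) -
             sum(log(rs$n_members + beta * rs$sum_z)))
  }
  if (is.null(rs$member_zmat)) stop("risk sets carry no windowed exposures")
  stopifnot(length(beta) == ncol(rs$member_zmat))
  rrm <- 1 + as.numeric(rs$member_zmat %*% beta)
  if (any(rrm <= 0)) return(-Inf)
  sum(log1p(as.numeric(rs$case_zmat %*% beta))) -
    sum(log(rs$n_members + as.numeric(rs$sum_zmat %*% beta)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# admissible lower bound for scalar beta (exposures are non-negative)
beta_lower_bound <- function(rs) {
  if (rs$max_z <= 0) -Inf else -1 / rs$max_z
}

#' Fit the linear ERR model
#'
#' Maximizes the stratified partial likelihood of `RR = 1 + beta Z` over
#' the admissible interval `(-1/max Z, cap)` by bounded one-dimensional
#' search (golden section with parabolic refinement), and finds the
#' profile-likelihood confidence interval by root-finding on
#' `2 [l(beta_hat) - l(beta)] = qchisq(level, 1)`. A boundary flag is set
#' when the estimate or a bound hits the edge of the admissible interval
#' or the search cap.
#'
#' @param rs An `err_risk_sets` with scalar exposures.
#' @param conf_level Confidence level for the profile interval.
#' @param cap Upper search bound for beta (per unit exposure).
#' @return Object of class `err_fit`: `beta` (per unit exposure; multiply
#'   by 100 for ERR per 100 mGy), `ci`, `loglik`, `null_loglik`,
#'   `boundary`, `status`, `n_cases`.
#' @export
fit_linear_err <- function(rs, conf_level = 0.95, cap = 1e4) {
  if (rs$n_cases == 0L)
    return(structure(list(status = "no cases", n_cases = 0L),
                     class = "err_fit"))
  out <- list(n_cases = rs$n_cases, lag = rs$lag, metric = rs$metric,
              endpoint = rs$endpoint, conf_level = conf_level)
  if (!isTRUE(rs$informative)) {
    out$status <- "non_identifiable"
    out$beta <- NA_real_
    out$ci <- c(NA_real_, NA_real_)
    class(out) <- "err_fit"
    return(out)
  }
  lo <- beta_lower_bound(rs)
  lo_adm <- if (is.finite(lo)) lo + max(1e-12, abs(lo) * 1e-9) else -cap
  f <- function(b) linear_err_loglik(b, rs)
  opt <- optimize(f, c(lo_adm, cap), maximum = TRUE, tol = 1e-9)
  beta_hat <- opt$maximum
  ll_max <- opt$objective
  boundary <- beta_hat <= lo_adm + 1e-7 * max(1, abs(lo_adm)) ||
    beta_hat >= cap * (1 - 1e-7)

  crit <- qchisq(conf_level, 1) / 2
  target <- ll_max - crit
  g <- function(b) f(b) - target
  ci <- c(NA_real_, NA_real_)
  ci_boundary <- c(FALSE, FALSE)
  # lower bound
  bl <- lo_adm + (beta_hat - lo_adm) * 1e-6
  if (g(bl) > 0) {
    ci[1] <- lo
    ci_boundary[1] <- TRUE
  } else {
    ci[1] <- uniroot(g, c(bl, beta_hat), tol = 1e-12)$root
  }
  # upper bound: expand a bracket
  hi <- beta_hat + max(1e-4, abs(beta_hat))
  while (g(hi) > 0 && hi < cap) hi <- beta_hat + (hi - beta_hat) * 2
  if (hi >= cap && g(min(hi, cap)) > 0) {
    ci[2] <- cap
    ci_boundary[2] <- TRUE
  } else {
    ci[2] <- uniroot(g, c(beta_hat, min(hi, cap)), tol = 1e-12)$root
  }

  out$beta <- beta_hat
  out$loglik <- ll_max
  out$null_loglik <- f(0)
  out$ci <- ci
  out$boundary <- boundary || any(ci_boundary)
  out$status <- "ok"
  class(out) <- "err_fit"
  out
}

#' @export
print.err_fit <- function(x, ...) {
  cat("Linear ERR fit (", x$endpoint %||% "?", ", ", x$n_cases,
      " cases)\n", sep = "")
  if (!identical(x$status, "ok")) {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("  ERR/100 mGy = %.3f  (%.0f%% profile CI %.3f to %.3f)\n",
              100 * x$beta, 100 * x$conf_level, 100 * x$ci[1],
              100 * x$ci[2]))
  if (isTRUE(x$boundary)) cat("  note: boundary of admissible region\n")
  invisible(x)
}

# conditional multinomial log-likelihood for category parameters
# gamma: log RR for categories 2..K (reference = first retained category)
cat_loglik <- function(gamma, counts, case_cat_idx) {
  rr <- exp(c(0, gamma))
  den <- as.numeric(counts %*% rr)
  sum(log(rr[case_cat_idx])) - sum(log(den))
}

cat_grad <- function(gamma, counts, case_cat_idx) {
  rr <- exp(c(0, gamma))
  den <- as.numeric(counts %*% rr)
  pk <- sweep(counts, 2, rr, "*") / den  # expected membership shares
  ncase <- tabulate(case_cat_idx, nbins = length(rr))
  (ncase - colSums(pk))[-1]
}

#' Fit categorical relative risks
#'
#' Multiplicative category effects estimated on the log scale by the same
#' stratified partial likelihood, with the lowest dose category as the
#' reference (RR = 1). Confidence intervals are Wald intervals
#' `exp(gamma +- z * SE)` from the observed information; the dose-response
#' trend p-value comes from [test_trend()].
#'
#' @param rs Risk sets built with `cutpoints`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `rr_fit` with a `table` data.frame (category,
#'   cases, rr, ci_low, ci_high) and `trend_p`.
#' @export
fit_categorical_rr <- function(rs, conf_level = 0.95) {
  if (is.null(rs$cat_counts)) stop("risk sets carry no dose categories")
  counts <- rs$cat_counts
  occupied <- colSums(counts) > 0
  if (any(!occupied))
    warning("dropping empty dose categor(ies): ",
            paste(colnames(counts)[!occupied], collapse = ", "))
  counts <- counts[, occupied, drop = FALSE]
  case_idx <- match(colnames(rs$cat_counts)[rs$cat_case],
                    colnames(counts))
  K <- ncol(counts)
  ncase <- tabulate(case_idx, nbins = K)
  if (K == 1L) {
    tab <- data.frame(category = colnames(counts), cases = ncase,
                      rr = 1, ci_low = NA_real_, ci_high = NA_real_)
    return(structure(list(table = tab, trend_p = NA_real_,
                          loglik = cat_loglik(numeric(0), counts,
                                              case_idx),
                          status = "single category"),
                     class = "rr_fit"))
  }
  opt <- optim(rep(0, K - 1), fn = function(g)
    -cat_loglik(g, counts, case_idx),
    gr = function(g) -cat_grad(g, counts, case_idx),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  gamma <- opt$par
  # observed information (analytic)
  rr <- exp(c(0, gamma))
  den <- as.numeric(counts %*% rr)
  pk <- sweep(counts, 2, rr, "*") / den
  info <- crossprod(pk) * -1
  diag(info) <- diag(info) + colSums(pk)
  info <- info[-1, -1, drop = FALSE]
  se <- sqrt(diag(solve(info)))
  zq <- -qnorm((1 - conf_level) / 2)
  tab <- data.frame(
    category = colnames(counts),
    cases = ncase,
    rr = rr,
    ci_low = c(NA, exp(gamma - zq * se)),
    ci_high = c(NA, exp(gamma + zq * se)))
  trend <- test_trend(rs)
  structure(list(table = tab, gamma = gamma, se = se,
                 loglik = -opt$value, trend_p = trend$p_value,
                 trend = trend, status = "ok"),
            class = "rr_fit")
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Categorical RR fit\n")
  print(transform(x$table, rr = round(rr, 2),
                  ci_low = round(ci_low, 2), ci_high = round(ci_high, 2)),
        row.names = FALSE)
  if (!is.na(x$trend_p))
    cat(sprintf("  P for trend: %.3g\n", x$trend_p))
  invisible(x)
}

#' Trend test across dose categories
#'
#' Replaces the category indicators by an ordinal score (the category
#' index 0, 1, 2, ... by default, or the mean member exposure per
#' category) and tests the log-linear slope by likelihood ratio against
#' the null of no trend (chi-squared, 1 df, two-sided).
#'
#' @param rs Risk sets built with `cutpoints`.
#' @param score `"index"` or `"mean_dose"`.
#' @return List with `p_value`, `statistic`, `theta` (fitted slope) and
#'   `status`.
#' @export
test_trend <- function(rs, score = c("index", "mean_dose")) {
  score <- match.arg(score)
  if (is.null(rs$cat_counts)) stop("risk sets carry no dose categories")
  counts <- rs$cat_counts
  occupied <- colSums(counts) > 0
  counts <- counts[, occupied, drop = FALSE]
  case_idx <- match(colnames(rs$cat_counts)[rs$cat_case],
                    colnames(counts))
  with_cases <- unique(case_idx)
  if (ncol(counts) < 2L || length(with_cases) < 1L)
    return(list(p_value = NA_real_, statistic = NA_real_,
                theta = NA_real_, status = "single occupied category"))
  s <- if (score == "index") seq_len(ncol(counts)) - 1 else {
    # mean member exposure per retained category
    mcat <- match(colnames(rs$cat_counts)[categorize_dose(rs$member_z,
                                                          rs$cutpoints)],
                  colnames(counts))
    as.numeric(tapply(rs$member_z, mcat, mean))
  }
  ll <- function(theta) {
    w <- exp(theta * s)
    sum(theta * s[case_idx]) - sum(log(as.numeric(counts %*% w)))
  }
  ll0 <- ll(0)
  opt <- optimize(ll, c(-30, 30), maximum = TRUE, tol = 1e-10)
  lrt <- 2 * (opt$objective - ll0)
  lrt <- max(lrt, 0)
  list(p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
       statistic = lrt, theta = opt$maximum, status = "ok")
}

# maximize the windowed linear ERR likelihood; start from the common fit
fit_linear_err_multi <- function(rs, start) {
  neg <- function(b) {
    v <- linear_err_loglik(b, rs)
    if (!is.finite(v)) 1e10 else -v
  }
  grad <- function(b) {
    num_c <- 1 + as.numeric(rs$case_zmat %*% b)
    den <- rs$n_members + as.numeric(rs$sum_zmat %*% b)
    -(colSums(rs$case_zmat / num_c) - colSums(rs$sum_zmat / den))
  }
  o1 <- optim(start, neg, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  o2 <- tryCatch(optim(o1$par, neg, gr = grad, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14)),
                 error = function(e) o1)
  best <- if (o2$value <= o1$value &&
              is.finite(linear_err_loglik(o2$par, rs))) o2 else o1
  list(beta = best$par, loglik = -best$value)
}

#' Test heterogeneity of the ERR across exposure windows or subgroups
#'
#' Compares the full model `RR = 1 + sum_m beta_m Z_m` (one ERR
#' coefficient per exposure window or subgroup) against the reduced
#' common-slope model `RR = 1 + beta sum_m Z_m` by likelihood ratio with
#' `m - 1` degrees of freedom. Windows with no exposure anywhere are
#' reported non-identifiable and reduce the degrees of freedom.
#'
#' @param rs Risk sets built with `windows`/`window_by` or `group_var`.
#' @param conf_level Level for the per-window profile intervals.
#' @param ci Compute per-window profile intervals (skip for speed when
#'   only the likelihood-ratio test is needed).
#' @return Object of class `het_test`: per-window estimates with profile
#'   CIs, `lrt_statistic`, `df`, `p_value`, and the common-slope fit.
#' @export
test_heterogeneity <- function(rs, conf_level = 0.95, ci = TRUE) {
  if (is.null(rs$member_zmat)) stop("risk sets carry no windowed exposures")
  m_all <- ncol(rs$member_zmat)
  active <- colSums(rs$sum_zmat) > 0
  zm <- rs$member_zmat[, active, drop = FALSE]
  rs_act <- rs
  rs_act$member_zmat <- zm
  rs_act$case_zmat <- rs$case_zmat[, active, drop = FALSE]
  rs_act$sum_zmat <- rs$sum_zmat[, active, drop = FALSE]
  m <- sum(active)

  # common slope on the total exposure
  rs_tot <- rs
  rs_tot$case_z <- rowSums(rs$case_zmat)
  rs_tot$sum_z <- rowSums(rs$sum_zmat)
  rs_tot$member_z <- rowSums(rs$member_zmat)
  rs_tot$max_z <- max(rs_tot$member_z)
  rs_tot$case_zmat <- rs_tot$member_zmat <- rs_tot$sum_zmat <- NULL
  common <- fit_linear_err(rs_tot, conf_level = conf_level)

  if (m < 2L) {
    return(structure(list(common = common, beta = rep(NA_real_, m_all),
                          lrt_statistic = 0, df = 0, p_value = NA_real_,
                          window_labels = rs$window_labels,
                          status = "fewer than two informative windows"),
                     class = "het_test"))
  }
  full <- fit_linear_err_multi(rs_act, rep(common$beta, m))
  lrt <- max(0, 2 * (full$loglik - common$loglik))
  df <- m - 1L
  p <- pchisq(lrt, df = df, lower.tail = FALSE)

  # profile CI for each window coefficient
  crit <- qchisq(conf_level, 1) / 2
  prof <- function(j, b) {
    if (m == 2L) {
      other <- setdiff(seq_len(m), j)
      f1 <- function(x) {
        bb <- numeric(m); bb[j] <- b; bb[other] <- x
        v <- linear_err_loglik(bb, rs_act)
        if (is.finite(v)) -v else 1e10
      }
      -optimize(f1, c(-1, 100) * max(1e-3, abs(full$beta[other]) * 50 +
                                       0.1))$objective
    } else {
      f1 <- function(x) {
        bb <- numeric(m); bb[j] <- b; bb[-j] <- x
        v <- linear_err_loglik(bb, rs_act)
        if (is.finite(v)) -v else 1e10
      }
      -optim(full$beta[-j], f1, method = "Nelder-Mead",
             control = list(maxit = 500, reltol = 1e-10))$value
    }
  }
  cim <- matrix(NA_real_, m, 2)
  if (ci) for (j in seq_len(m)) {
    target <- full$loglik - crit
    gg <- function(b) prof(j, b) - target
    span <- max(0.05, abs(full$beta[j]) * 2)
    lo <- full$beta[j] - span
    tries <- 0
    while (gg(lo) > 0 && tries < 12) { lo <- full$beta[j] -
      (full$beta[j] - lo) * 2; tries <- tries + 1 }
    cim[j, 1] <- if (gg(lo) <= 0)
      uniroot(gg, c(lo, full$beta[j]), tol = 1e-8)$root else NA_real_
    hi <- full$beta[j] + span
    tries <- 0
    while (gg(hi) > 0 && tries < 12) { hi <- full$beta[j] +
      (hi - full$beta[j]) * 2; tries <- tries + 1 }
    cim[j, 2] <- if (gg(hi) <= 0)
      uniroot(gg, c(full$beta[j], hi), tol = 1e-8)$root else NA_real_
  }

  beta_full <- rep(NA_real_, m_all)
  beta_full[active] <- full$beta
  ci_full <- matrix(NA_real_, m_all, 2)
  ci_full[active, ] <- cim
  structure(list(common = common, beta = beta_full, ci = ci_full,
                 loglik_full = full$loglik,
                 loglik_common = common$loglik,
                 lrt_statistic = lrt, df = df, p_value = p,
                 window_labels = rs$window_labels, status = "ok"),
            class = "het_test")
}

#' @export
print.het_test <- function(x, ...) {
  cat("ERR heterogeneity test\n")
  if (identical(x$status, "ok")) {
    for (j in seq_along(x$beta))
      cat(sprintf("  %-12s ERR/100 mGy %.3f (%.3f to %.3f)\n",
                  x$window_labels[j], 100 * x$beta[j], 100 * x$ci[j, 1],
                  100 * x$ci[j, 2]))
    cat(sprintf("  LRT %.3f on %d df, p = %.3g\n", x$lrt_statistic, x$df,
                x$p_value))
  } else cat("  status:", x$status, "\n")
  invisible(x)
}
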