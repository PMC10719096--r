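# Additive excess-absolute-risk model on person-year tables.
#
# The grouped-data twin of the individual partial-likelihood analysis:
# follow-up is cross-classified into cells by attained-age band, sex,
# country, birth cohort and cumulative-dose stratum; cell counts are
# modeled as Poisson with rate PY * (lambda_bg(stratum) + alpha * dose),
# i.e. a background rate per background stratum plus an additive excess
# proportional to the person-year-weighted mean lagged cumulative dose.
# The canonical unit of alpha is cases per person-year per mGy, with
# formatters to the conventional "per 100,000 PY per 100 mGy".

#' Tabulate person-years, cases and mean dose
#'
#' Splits every included person's follow-up `[entry, exit)` at attained-age
#' band boundaries and at dose-step ages (exam age + lag), so that the
#' lagged cumulative dose and the age band are constant on every
#' sub-interval, then accumulates person-years, case counts and the
#' PY-weighted mean dose by cell.
#'
#' @param cohort A `ct_cohort` with follow-up derived.
#' @param endpoint Endpoint group for the case counts.
#' @param age_bands Attained-age band breaks (must cover all follow-up).
#' @param cutpoints Dose-stratum cutpoints.
#' @param lag Dose lag (years).
#' @param metric Per-exam dose metric.
#' @param strata_vars Classification variables kept in the table.
#' @param mapping Morphology mapping table.
#' @return Object of class `py_table`: a data.frame of cells with
#'   `person_years`, `cases`, `mean_dose`.
#' @export
tabulate_person_years <- function(cohort, endpoint = "all_heme",
                                  age_bands = seq(0, 60, 5),
                                  cutpoints = c(0, 5, 10, 15, 25, 50),
                                  lag = 2, metric = "abm_dose_mean",
                                  strata_vars = c("sex", "country",
                                                  "birth_cohort"),
                                  mapping = default_morphology_mapping()) {
  fu <- cohort$followup
  if (is.null(fu)) stop("derive follow-up first")
  inc <- fu[fu$included, ]
  p <- cohort$persons
  if (max(inc$exit_age) > max(age_bands) || min(inc$entry_age) <
      min(age_bands))
    stop("age_bands do not cover follow-up up to age ",
         round(max(inc$exit_age), 2))

  per <- data.table::data.table(person_id = inc$person_id,
                                entry = inc$entry_age, exit = inc$exit_age)
  h <- dose_history(cohort, metric)
  steps <- data.table::as.data.table(h)
  steps[, qage := age + lag]
  steps[, cumz := cumsum(dose), by = person_id]
  steps <- steps[, .(cumz = cumz[.N], age = age[.N]),
                 by = .(person_id, qage)]

  brk <- rbind(per[, .(person_id, age = entry)],
               per[, .(person_id, age = exit)],
               data.table::data.table(
                 person_id = rep(per$person_id, each = length(age_bands)),
                 age = rep(age_bands, nrow(per))),
               steps[, .(person_id, age = qage)])
  brk <- brk[per, on = "person_id"][age >= entry & age <= exit,
                                    .(person_id, age)]
  brk <- unique(brk)
  data.table::setorder(brk, person_id, age)
  brk[, nxt := data.table::shift(age, -1L), by = person_id]
  iv <- brk[!is.na(nxt) & nxt > age]

  iv[, z := steps[iv, on = .(person_id, qage = age), roll = Inf, x.cumz]]
  iv[is.na(z), z := 0]
  iv[, py := nxt - age]
  iv[, age_band := findInterval(age, age_bands)]
  iv[, dose_stratum := categorize_dose(z, cutpoints)]

  # case lands in the interval ending at the diagnosis age
  is_case <- outcome_in_endpoint(cohort$outcomes, endpoint, mapping)
  oc <- cohort$outcomes[is_case, , drop = FALSE]
  fidx <- match(oc$person_id, fu$person_id)
  ok <- !is.na(fidx) & fu$included[fidx] &
    oc$age_at_diagnosis > fu$entry_age[fidx] &
    oc$age_at_diagnosis <= fu$exit_age[fidx]
  oc <- oc[ok, , drop = FALSE]
  iv[, case := 0L]
  if (nrow(oc)) {
    cdt <- data.table::data.table(person_id = oc$person_id,
                                  dage = oc$age_at_diagnosis)
    iv[cdt, on = .(person_id, age < dage, nxt >= dage), case := 1L]
  }

  pm <- match(iv$person_id, p$person_id)
  for (v in strata_vars)
    iv[, (v) := switch(v, sex = p$sex[pm], country = p$country[pm],
                       birth_cohort = birth_cohort_bin(p$birth_date[pm]),
                       ses = p$ses[pm])]

  cells <- iv[, .(person_years = sum(py), cases = sum(case),
                  mean_dose = sum(py * z) / sum(py)),
              by = c("age_band", strata_vars, "dose_stratum")]
  agelabs <- paste0("[", age_bands[-length(age_bands)], ",",
                    age_bands[-1], ")")
  cells[, age_band := agelabs[age_band]]
  cells[, dose_stratum := dose_category_labels(cutpoints)[dose_stratum]]
  out <- as.data.frame(cells)
  attr(out, "age_bands") <- age_bands
  attr(out, "cutpoints") <- cutpoints
  attr(out, "lag") <- lag
  attr(out, "strata_vars") <- strata_vars
  attr(out, "endpoint") <- endpoint
  class(out) <- c("py_table", "data.frame")
  out
}

#' Fit the additive excess-absolute-risk model
#'
#' Maximum likelihood for Poisson cell counts with rate
#' `PY * (lambda_s + alpha * mean_dose)`, one background rate per
#' background stratum (parameterized on the log scale, so rates stay
#' positive) and a single additive dose coefficient `alpha`, constrained so
#' every fitted rate is positive. The confidence interval for `alpha` is
#' profile-likelihood based.
#'
#' @param pyt A `py_table`.
#' @param background Cell variables defining the background strata
#'   (coarser than the table classification to keep the model
#'   identifiable; attained age and sex by default).
#' @param conf_level Level for the profile interval.
#' @return Object of class `ear_fit`: `alpha` (cases per PY per mGy),
#'   `ci`, `loglik`, `lambda_bg`.
#' @export
fit_ear <- function(pyt, background = c("age_band", "sex"),
                    conf_level = 0.95) {
  y <- pyt$cases
  py <- pyt$person_years
  d <- pyt$mean_dose
  s <- factor(do.call(paste, c(pyt[background], sep = "|")))
  S <- nlevels(s)
  si <- as.integer(s)
  if (sum(y) == 0) return(structure(list(status = "no cases"),
                                    class = "ear_fit"))
  if (all(abs(d - ave(d, si)) < 1e-12))
    return(structure(list(status = "non_identifiable",
                          alpha = NA_real_, ci = c(NA_real_, NA_real_)),
                     class = "ear_fit"))

  # positivity is binding only where cases were observed; in zero-case
  # cells the likelihood is linear in the rate and its maximum can sit
  # exactly on the boundary, so those cells get a steep smooth barrier
  # below zero instead of a hard wall (violations at the optimum are of
  # machine-epsilon size)
  barrier <- 1e18
  pos <- y > 0
  nll <- function(par) {
    lam <- exp(par[seq_len(S)])[si]
    rate <- lam + par[S + 1] * d
    if (any(rate[pos] <= 0)) return(1e10)
    ll <- sum(y[pos] * log(rate[pos] * py[pos])) - sum(py * rate)
    neg <- rate < 0
    if (any(neg)) ll <- ll - barrier * sum(rate[neg]^2)
    -ll
  }
  grd <- function(par) {
    lamS <- exp(par[seq_len(S)])
    lam <- lamS[si]
    rate <- lam + par[S + 1] * d
    if (any(rate[pos] <= 0)) return(rep(0, S + 1))
    w <- -py
    w[pos] <- w[pos] + y[pos] / rate[pos]
    neg <- rate < 0
    w[neg] <- w[neg] - 2 * barrier * rate[neg]
    g_lam <- rowsum(w * lam, si)[, 1]
    c(-g_lam, -sum(w * d))
  }
  start <- c(unname(log(pmax(rowsum(y, si)[, 1], 0.5) /
                          rowsum(py, si)[, 1])), 0)
  # alpha lives on the scale rate/dose, far below the log-rates
  pscale <- c(rep(1, S), max(exp(start[seq_len(S)])) / max(d, 1))
  ctl <- list(maxit = 2000, reltol = 1e-14, parscale = pscale)
  opt <- optim(start, nll, gr = grd, method = "BFGS", control = ctl)
  opt <- optim(opt$par, nll, gr = grd, method = "BFGS", control = ctl)
  alpha <- unname(opt$par[S + 1])
  ll <- -opt$value

  # profile likelihood for alpha
  prof <- function(a) {
    inner <- optim(opt$par[seq_len(S)], function(l)
      nll(c(l, a)), gr = function(l) grd(c(l, a))[seq_len(S)],
      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    -inner$value
  }
  crit <- qchisq(conf_level, 1) / 2
  target <- ll - crit
  g <- function(a) prof(a) - target
  step <- max(abs(alpha), 1e-7)
  lo <- alpha - step
  tries <- 0
  while (g(lo) > 0 && tries < 20) { lo <- alpha - (alpha - lo) * 2
    tries <- tries + 1 }
  ci_lo <- if (g(lo) <= 0) uniroot(g, c(lo, alpha), tol = 1e-12)$root
    else NA_real_
  hi <- alpha + step
  tries <- 0
  while (g(hi) > 0 && tries < 20) { hi <- alpha + (hi - alpha) * 2
    tries <- tries + 1 }
  ci_hi <- if (g(hi) <= 0) uniroot(g, c(alpha, hi), tol = 1e-12)$root
    else NA_real_

  structure(list(alpha = alpha, ci = c(ci_lo, ci_hi), loglik = ll,
                 lambda_bg = setNames(exp(opt$par[seq_len(S)]),
                                      levels(s)),
                 conf_level = conf_level, n_cases = sum(y),
                 person_years = sum(py), status = "ok"),
            class = "ear_fit")
}

#' Rescale an EAR coefficient to reporting units
#'
#' The canonical unit is cases per person-year per mGy; results are
#' conventionally reported per 100,000 (or 10,000) person-years per
#' 100 mGy. The round trip canonical -> formatted -> canonical is exact.
#'
#' @param alpha EAR in cases per PY per mGy.
#' @param per_py Person-year multiplier (1e5 by default).
#' @param per_mgy Dose multiplier (100 by default).
#' @return Rescaled coefficient.
#' @export
ear_scale <- function(alpha, per_py = 1e5, per_mgy = 100) {
  alpha * per_py * per_mgy
}

#' @rdname ear_scale
#' @param value Coefficient in the `(per_py, per_mgy)` units.
#' @export
ear_unscale <- function(value, per_py = 1e5, per_mgy = 100) {
  value / (per_py * per_mgy)
}

#' @export
print.ear_fit <- function(x, ...) {
  cat("Additive EAR fit\n")
  if (!identical(x$status, "ok")) {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  EAR = %.2f per 100,000 PY per 100 mGy (%.0f%% profile CI %.2f to %.2f)\n",
    ear_scale(x$alpha), 100 * x$conf_level, ear_scale(x$ci[1]),
    ear_scale(x$ci[2])))
  invisible(x)
}
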