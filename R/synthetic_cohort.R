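# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure of a multinational registry-linked
# cohort of patients who underwent CT before age 22: demographics, skewed
# age at first CT, an over-dispersed examination count, body-region mix
# dominated by head/neck scans, per-exam ABM dose ensembles with
# period-declining geometric means and two-component (shared x unshared)
# lognormal uncertainty, and rare hematological-malignancy outcomes drawn
# from a piecewise-constant baseline hazard multiplied by the linear
# relative-risk factor 1 + beta * Z(t - lag).

#' Simulation configuration
#'
#' Returns the default generator configuration. Defaults emulate the
#' published cohort margins: 56% male; nine countries with the published
#' cohort shares; birth-cohort distribution over the bins 1960-1979 ...
#' 2005-2012; age at first CT skewed late (30.6% at >=15 years); exam count
#' 1 + negative binomial calibrated to mean 1.52 / s.d. 1.46 examinations
#' per patient; 81% head/neck examinations; head newborn geometric-mean
#' dose declining 15 -> 12 mGy across the periods <1991 / 1991-2001 /
#' >2001 and chest 18 -> 7 mGy; ensemble geometric s.d. about 2 from the
#' two uncertainty components; 200 realizations per examination; baseline
#' hazard of order 1e-4 cases per person-year (pediatric/young-adult
#' hematological-malignancy incidence); true ERR 0.02 per mGy with a
#' 2-year dose lag.
#'
#' @param n_persons Cohort size.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of `(config, seed)`.
#' @param true_beta True excess relative risk per mGy.
#' @param lag Dose lag in years.
#' @param n_realizations Dose realizations per examination.
#' @param gsd_unshared,gsd_shared Geometric standard deviations of the
#'   unshared (per examination) and shared (per hospital x period)
#'   lognormal dose-uncertainty components.
#' @param dose_uncertainty If `FALSE`, doses are the deterministic
#'   geometric means (no ensembles, measured dose equal to true dose) —
#'   the configuration used for estimator-property simulations.
#' @param hazard_mult Scalar multiplier on the baseline hazard (used to
#'   reach a target case count at reduced cohort sizes).
#' @param ... Overrides for any other configuration element.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 10000, seed = 1, true_beta = 0.02,
                       lag = 2, n_realizations = 200,
                       gsd_unshared = 1.8, gsd_shared = 1.3,
                       dose_uncertainty = TRUE, hazard_mult = 1, ...) {
  cfg <- list(
    n_persons = n_persons,
    seed = seed,
    country_weights = c(UK = 0.353, NL = 0.161, SE = 0.136, FR = 0.119,
                        NO = 0.081, ES = 0.076, DE = 0.045, DK = 0.018,
                        BE = 0.011),
    sex_male_prob = 0.56,
    birth_cohort = list(
      breaks = c(1960, 1980, 1985, 1990, 1995, 2000, 2005, 2013),
      probs = c(0.075, 0.097, 0.174, 0.216, 0.186, 0.150, 0.102)),
    age_first_ct = list(
      breaks = c(0, 1, 5, 10, 15, 22),
      probs = c(0.115, 0.170, 0.192, 0.217, 0.306)),
    exam_extra_mean = 0.52,      # mean of exams beyond the first
    exam_extra_size = 0.1678,    # NB dispersion: var 0.52 + 0.52^2/size = 2.13
    exam_gap_mean = 1,           # years between successive exams (exponential)
    country_age_cap = c(UK = 22, NL = 18, SE = 22, FR = 10, NO = 22,
                        ES = 22, DE = 15, DK = 22, BE = 16),
    exam_year_range = c(1977, 2014),
    body_region_probs = c(head_neck = 0.81, chest = 0.07,
                          abdomen_pelvis = 0.08, spine = 0.02,
                          other = 0.02),
    dose_age_breaks = c(0, 1, 5, 10, 15, 22),
    dose_period_breaks = c(-Inf, 1991, 2002, Inf),  # <1991, 1991-2001, >2001
    dose_model = default_dose_model(),
    gsd_unshared = gsd_unshared,
    gsd_shared = gsd_shared,
    n_realizations = n_realizations,
    dose_uncertainty = dose_uncertainty,
    hospitals_per_country = 30,
    low_reporting_hospital_prob = 0.08,
    baseline_hazard = list(
      age_breaks = c(0, 5, 10, 15, 20, 30, 40, 60),
      rate_male   = c(7, 6, 7, 10, 12, 15, 18) * 1e-5 * 1.1,
      rate_female = c(7, 6, 7, 10, 12, 15, 18) * 1e-5 * 0.9),
    hazard_mult = hazard_mult,
    true_beta = true_beta,
    lag = lag,
    admin_end_year = 2016,
    death_rate = 2e-4,
    emigration_rate = 2e-3,
    emigration_countries = c("DK", "NO", "SE"),
    registry_start_year = c(UK = 1971, NL = 1989, SE = 1958, FR = 1975,
                            NO = 1953, ES = 1985, DE = 1995, DK = 1943,
                            BE = 2004),
    ses_countries = c("BE", "FR", "NL", "ES"),
    transplant_prob_uk = 0.005,
    vital_unknown = c(DE = 1, FR = 0.5),
    subtype_weights = c(HL = 0.240, mature_B = 0.255, mature_TNK = 0.037,
                        precursor = 0.175, NHL_NOS = 0.018,
                        lymphoid_NOS = 0.001, AML_ALMP_ALAL = 0.101,
                        MPN_MDS = 0.145, myeloid_NOS = 0.016,
                        histiocytic = 0.008, unspecified = 0.004),
    subtype_codes = c(HL = "9650", mature_B = "9680", mature_TNK = "9702",
                      precursor = "9836", NHL_NOS = "9591",
                      lymphoid_NOS = "9820", AML_ALMP_ALAL = "9861",
                      MPN_MDS = "9863", myeloid_NOS = "9800",
                      histiocytic = "9751", unspecified = "8000"))
  dots <- list(...)
  cfg[names(dots)] <- dots
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("invalid probability vector for ", what)
  }
  check_probs(cfg$country_weights, "country_weights")
  check_probs(cfg$birth_cohort$probs, "birth_cohort")
  check_probs(cfg$age_first_ct$probs, "age_first_ct")
  check_probs(cfg$body_region_probs, "body_region_probs")
  check_probs(cfg$subtype_weights, "subtype_weights")
  if (any(unlist(cfg$baseline_hazard[c("rate_male", "rate_female")]) < 0))
    stop("negative baseline hazard rate")
  structure(cfg, class = "sim_config")
}

# Geometric-mean ABM dose (mGy) per body region x age band x period.
# Anchors: head/neck newborn 15 -> 12 mGy over the three periods, constant
# 2.6 mGy at ages >= 15; chest newborn 18 -> 7 mGy, 8 -> 5 at ages >= 15.
default_dose_model <- function() {
  regions <- c("head_neck", "chest", "abdomen_pelvis", "spine", "other")
  gm <- rbind(
    # age bands: [0,1) [1,5) [5,10) [10,15) [15,22)   period <1991
    head_neck      = c(15.0, 9.0, 6.0, 4.0, 2.6),
    chest          = c(18.0, 15.0, 12.0, 10.0, 8.0),
    abdomen_pelvis = c(14.0, 12.0, 10.0, 9.0, 8.0),
    spine          = c(8.0, 7.0, 6.0, 5.0, 4.0),
    other          = c(4.0, 3.5, 3.0, 2.5, 2.0))
  gm2 <- rbind(  # 1991-2001
    head_neck      = c(13.5, 8.0, 5.2, 3.5, 2.6),
    chest          = c(12.0, 10.0, 9.0, 8.0, 6.5),
    abdomen_pelvis = c(10.0, 9.0, 8.0, 7.0, 6.5),
    spine          = c(6.0, 5.5, 5.0, 4.5, 4.0),
    other          = c(3.5, 3.0, 2.8, 2.3, 1.8))
  gm3 <- rbind(  # >2001
    head_neck      = c(12.0, 7.0, 4.5, 3.0, 2.6),
    chest          = c(7.0, 6.5, 6.0, 5.5, 5.0),
    abdomen_pelvis = c(7.0, 6.5, 6.0, 5.5, 5.0),
    spine          = c(5.0, 4.5, 4.0, 3.5, 3.0),
    other          = c(3.0, 2.8, 2.5, 2.0, 1.6))
  out <- expand.grid(body_region = regions, age_band = 1:5, period = 1:3,
                     stringsAsFactors = FALSE)
  mlist <- list(gm, gm2, gm3)
  out$gm <- mapply(function(r, b, p) mlist[[p]][r, b],
                   out$body_region, out$age_band, out$period)
  out
}

#' Sample the persons table
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to the config seed).
#' @return Persons data.frame; death/emigration dates are filled in later
#'   by [simulate_cohort()] since they depend on the examination history.
#' @export
sample_persons <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_persons
  if (n == 0) {
    return(data.frame(person_id = character(0), sex = character(0),
                      country = character(0), birth_date = numeric(0),
                      registry_start = numeric(0), death_date = numeric(0),
                      emigration_date = numeric(0),
                      admin_end_date = numeric(0), ses = integer(0),
                      transplant = logical(0),
                      low_reporting_hospital = logical(0),
                      vital_status_known = logical(0)))
  }
  sex <- ifelse(runif(n) < config$sex_male_prob, "male", "female")
  country <- sample(names(config$country_weights), n, replace = TRUE,
                    prob = config$country_weights)
  bc <- config$birth_cohort
  bin <- sample.int(length(bc$probs), n, replace = TRUE, prob = bc$probs)
  birth <- bc$breaks[bin] + runif(n) * (bc$breaks[bin + 1] - bc$breaks[bin])
  ses <- ifelse(country %in% config$ses_countries,
                sample.int(5, n, replace = TRUE), NA_integer_)
  transplant <- country == "UK" & runif(n) < config$transplant_prob_uk
  vu <- config$vital_unknown
  p_unknown <- ifelse(country %in% names(vu), vu[country], 0)
  vital_known <- runif(n) >= p_unknown
  data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = sex, country = country, birth_date = birth,
    registry_start = unname(config$registry_start_year[country]),
    death_date = NA_real_, emigration_date = NA_real_,
    admin_end_date = config$admin_end_year,
    ses = ses, transplant = transplant,
    low_reporting_hospital = FALSE, vital_status_known = vital_known,
    stringsAsFactors = FALSE)
}

#' Sample examination histories
#'
#' Each person receives `1 + NegBinom` examinations; the first at an age
#' drawn from the configured age-band mixture, later ones after
#' exponential gaps. Examination ages are capped at the country-specific
#' age limit and at the end of the examination-collection window.
#'
#' @param persons Persons table from [sample_persons()].
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Exams data.frame (one hospital per person, where the shared
#'   dose-uncertainty component lives).
#' @export
sample_exam_histories <- function(persons, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(persons)
  if (n == 0) {
    return(data.frame(exam_id = character(0), person_id = character(0),
                      age_at_exam = numeric(0), calendar_year = integer(0),
                      body_region = character(0), hospital_id = character(0)))
  }
  n_exams <- 1L + rnbinom(n, size = config$exam_extra_size,
                          mu = config$exam_extra_mean)
  afc <- config$age_first_ct
  bin <- sample.int(length(afc$probs), n, replace = TRUE, prob = afc$probs)
  first <- afc$breaks[bin] + runif(n) * (afc$breaks[bin + 1] -
                                           afc$breaks[bin])
  cap <- pmin(unname(config$country_age_cap[persons$country]),
              config$exam_year_range[2] - persons$birth_date)
  cap <- pmax(cap, 0.1)
  first <- pmin(pmax(first, 0.02), cap - 0.01)
  hosp <- paste0(persons$country, "_H",
                 sample.int(config$hospitals_per_country, n, replace = TRUE))

  pid <- rep.int(seq_len(n), n_exams)
  ord <- sequence(n_exams)                 # exam index within person
  gaps <- rexp(length(pid), rate = 1 / config$exam_gap_mean)
  gaps[ord == 1L] <- 0
  dt <- data.table::data.table(pi = pid, k = ord, gap = gaps)
  dt[, age := first[pi] + cumsum(gap), by = pi]
  dt[, age := pmin(age, cap[pi])]
  region <- sample(names(config$body_region_probs), nrow(dt),
                   replace = TRUE, prob = config$body_region_probs)
  # rows are already sorted: pid is non-decreasing by construction and
  # exam ages are cumulative sums of non-negative gaps within person
  data.frame(
    exam_id = sprintf("E%08d", seq_len(nrow(dt))),
    person_id = persons$person_id[dt$pi],
    age_at_exam = dt$age,
    calendar_year = as.integer(floor(persons$birth_date[dt$pi] + dt$age)),
    body_region = region,
    hospital_id = hosp[dt$pi],
    stringsAsFactors = FALSE)
}

# geometric-mean dose per exam from the dose model; errors on missing cells
exam_gm_dose <- function(exams, config) {
  band <- findInterval(exams$age_at_exam, config$dose_age_breaks,
                       all.inside = TRUE)
  period <- findInterval(exams$calendar_year, config$dose_period_breaks,
                         all.inside = TRUE)
  dm <- config$dose_model
  regions <- unique(dm$body_region)
  nb <- max(dm$age_band); np <- max(dm$period)
  arr <- array(NA_real_, c(length(regions), nb, np))
  arr[cbind(match(dm$body_region, regions), dm$age_band, dm$period)] <-
    dm$gm
  ri <- match(exams$body_region, regions)
  if (anyNA(ri))
    stop("dose model lacks cell(s): body region ",
         paste(unique(exams$body_region[is.na(ri)]), collapse = ", "))
  gm <- arr[cbind(ri, band, period)]
  if (anyNA(gm)) {
    bad <- which(is.na(gm))[1]
    stop(sprintf("dose model lacks cell: (%s, age band %d, period %d)",
                 exams$body_region[bad], band[bad], period[bad]))
  }
  gm
}

#' Sample per-examination dose-realization ensembles
#'
#' Each realization k of an examination's ABM dose is
#' `gm * S[hospital, period, k] * U[exam, k]`, with `S` the shared and `U`
#' the unshared lognormal multiplier (median 1, geometric standard
#' deviations from the config). Within a realization index the shared
#' multiplier is identical for all examinations from the same hospital and
#' period. The "true" dose of an examination is one further independent
#' draw from the same error model (the realization that actually
#' occurred).
#'
#' @param exams Exams table.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `true_dose` (numeric vector along exams) and
#'   `ensembles` (matrix exams x realizations, rownames = exam ids); with
#'   `dose_uncertainty = FALSE` both collapse to the geometric means and
#'   `ensembles` is `NULL`.
#' @export
sample_dose_realizations <- function(exams, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- exam_gm_dose(exams, config)
  if (!isTRUE(config$dose_uncertainty)) {
    return(list(true_dose = gm, ensembles = NULL))
  }
  k <- config$n_realizations
  sdu <- log(config$gsd_unshared)
  sds <- log(config$gsd_shared)
  period <- findInterval(exams$calendar_year, config$dose_period_breaks,
                         all.inside = TRUE)
  grp <- factor(paste(exams$hospital_id, period))
  g <- as.integer(grp)
  ng <- nlevels(grp)
  ne <- nrow(exams)
  # multipliers centered at mean 1, so the ensemble mean is an unbiased
  # estimate of the central dose
  mlu <- -sdu^2 / 2
  mls <- -sds^2 / 2
  shared_true <- if (sds > 0) rlnorm(ng, mls, sds) else rep(1, ng)
  unshared_true <- if (sdu > 0) rlnorm(ne, mlu, sdu) else rep(1, ne)
  true_dose <- gm * shared_true[g] * unshared_true
  shared <- if (sds > 0) matrix(rlnorm(ng * k, mls, sds), ng, k) else
    matrix(1, ng, k)
  unshared <- if (sdu > 0) matrix(rlnorm(ne * k, mlu, sdu), ne, k) else
    matrix(1, ne, k)
  ens <- gm * shared[g, , drop = FALSE] * unshared
  rownames(ens) <- exams$exam_id
  list(true_dose = true_dose, ensembles = ens)
}

# death/emigration dates given exam histories (they start the clock at the
# first examination; a death before any exam would contradict cohort entry)
sample_vital_events <- function(persons, exams, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(persons)
  fca <- first_ct_age(exams, persons$person_id)
  death_age <- fca + rexp(n, rate = config$death_rate)
  admin_age <- config$admin_end_year - persons$birth_date
  dd <- persons$birth_date + death_age
  dd[death_age >= admin_age] <- NA_real_
  persons$death_date <- dd
  emig <- persons$country %in% config$emigration_countries
  emig_age <- fca + rexp(n, rate = config$emigration_rate)
  em <- persons$birth_date + emig_age
  em[!(emig & emig_age < admin_age)] <- NA_real_
  persons$emigration_date <- em
  persons
}

#' Simulate hematological-malignancy outcomes
#'
#' Event times are drawn from the hazard
#' `lambda0(t, sex) * (1 + beta * Z_true(t - lag))`, where `Z_true` is the
#' true cumulative ABM dose and `lambda0` the piecewise-constant baseline.
#' Both factors are step functions of age, so the hazard is piecewise
#' constant and sampling uses exact piecewise-exponential inversion (no
#' discretization error). The clock starts at the first examination; times
#' beyond the censoring horizon (death, emigration or administrative end)
#' are censored.
#'
#' @param persons Persons table with vital-event dates filled in.
#' @param exams Exams table carrying a `true_dose_mGy` column.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `outcomes` (person_id, age_at_diagnosis,
#'   morphology_code, behavior_code) and `truth` (per-person event
#'   indicator, event age, true lagged cumulative dose at event,
#'   true beta, seed).
#' @export
simulate_outcomes <- function(persons, exams, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exams$true_dose_mGy)) stop("exams lack true_dose_mGy")
  bh <- config$baseline_hazard
  beta <- config$true_beta
  n <- nrow(persons)

  pdt <- data.table::data.table(
    pi = seq_len(n), sex = persons$sex,
    horizon = pmin(persons$death_date, persons$emigration_date,
                   persons$admin_end_date, na.rm = TRUE) -
      persons$birth_date)
  pdt[, start := first_ct_age(exams, persons$person_id)]
  pdt <- pdt[horizon > start]

  # dose steps: cumulative true dose becomes effective at exam age + lag
  ed <- data.table::data.table(
    pi = match(exams$person_id, persons$person_id),
    step_age = exams$age_at_exam + config$lag,
    dose = exams$true_dose_mGy)
  data.table::setorder(ed, pi, step_age)
  ed[, z := cumsum(dose), by = pi]
  # exams clamped to the age cap can tie exactly: keep one step per
  # distinct (person, age) carrying the full cumulative dose
  ed <- ed[, .(z = z[.N]), by = .(pi, step_age)]
  if (beta < 0) {
    zmax <- max(ed$z)
    if (1 + beta * zmax <= 0)
      stop("negative hazard: true_beta too negative for achievable doses")
  }

  # breakpoints: start, horizon, baseline band edges strictly inside the
  # window, dose steps inside the window (duplicates collapse to
  # zero-length pieces, dropped below)
  edges <- bh$age_breaks
  lo_idx <- findInterval(pdt$start, edges) + 1L   # first edge > start
  hi_idx <- findInterval(pdt$horizon, edges,
                         left.open = TRUE)        # last edge < horizon
  cnt <- pmax(hi_idx - lo_idx + 1L, 0L)
  edge_brk <- data.table::data.table(
    pi = rep.int(pdt$pi, cnt),
    age = edges[sequence(cnt, from = lo_idx)])
  sdt <- ed[pdt, on = "pi", nomatch = NULL][step_age > start &
                                              step_age < horizon]
  brk <- rbind(pdt[, .(pi, age = start)],
               pdt[, .(pi, age = horizon)],
               edge_brk,
               sdt[, .(pi, age = step_age)])
  data.table::setorder(brk, pi, age)
  brk[, nxt := data.table::shift(age, -1L), by = pi]
  pieces <- brk[!is.na(nxt) & nxt > age]

  # covariate and baseline rate on each piece (constant on [age, nxt))
  ed2 <- ed[, .(pi, step_age, z)]
  pieces <- ed2[pieces, on = c("pi", "step_age" = "age"), roll = Inf]
  data.table::setnames(pieces, "step_age", "age")
  pieces[is.na(z), z := 0]
  band <- findInterval(pieces$age, edges, all.inside = TRUE)
  sexm <- persons$sex[pieces$pi] == "male"
  rate0 <- bh$rate_female[band]
  rate0[sexm] <- bh$rate_male[band][sexm]
  rate0 <- rate0 * config$hazard_mult
  pieces[, rate := rate0 * (1 + beta * z)]
  if (any(pieces$rate < 0)) stop("negative hazard on a piece")
  pieces[, H := rate * (nxt - age)]
  pieces[, cumH := cumsum(H), by = pi]

  Evec <- rep(NA_real_, n)
  Evec[pdt$pi] <- rexp(nrow(pdt))
  pieces[, E := Evec[pi]]
  hit <- pieces[cumH >= E]
  hit <- hit[!duplicated(pi)]
  hit[, event_age := age + (E - (cumH - H)) / rate]

  ev_pi <- hit$pi
  subt <- sample(names(config$subtype_weights), length(ev_pi),
                 replace = TRUE, prob = config$subtype_weights)
  outcomes <- data.frame(
    person_id = persons$person_id[ev_pi],
    age_at_diagnosis = as.numeric(hit$event_age),
    morphology_code = as.character(unname(config$subtype_codes[subt])),
    behavior_code = rep(3L, length(ev_pi)),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    person_id = persons$person_id, event = 0L, event_age = NA_real_,
    true_cum_dose_at_event = NA_real_,
    true_beta = beta, seed = config$seed, stringsAsFactors = FALSE)
  truth$event[ev_pi] <- 1L
  truth$event_age[ev_pi] <- hit$event_age
  truth$true_cum_dose_at_event[ev_pi] <- hit$z
  list(outcomes = outcomes, truth = truth)
}

#' Simulate a complete cohort
#'
#' Orchestrates [sample_persons()], [sample_exam_histories()],
#' [sample_dose_realizations()], vital-event sampling and
#' [simulate_outcomes()] under a single seed, attaches the summarized dose
#' metrics (ensemble mean and median) and the true per-exam dose to the
#' exam table, and returns a `ct_cohort` with the truth table.
#'
#' @param config A [sim_config()].
#' @param keep_ensembles Keep the full realization matrix in the result
#'   (memory-heavy for large cohorts).
#' @return A `ct_cohort` with elements `truth` and `config` (and
#'   `ensembles` if requested).
#' @export
simulate_cohort <- function(config = sim_config(), keep_ensembles = FALSE) {
  set.seed(config$seed)
  persons <- sample_persons(config, seed = NULL)
  exams <- sample_exam_histories(persons, config)
  d <- sample_dose_realizations(exams, config)
  exams$true_dose_mGy <- d$true_dose
  if (is.null(d$ensembles)) {
    exams$abm_dose_mean <- d$true_dose
    exams$abm_dose_median <- d$true_dose
  } else {
    exams$abm_dose_mean <- rowMeans(d$ensembles)
    exams$abm_dose_median <- apply(d$ensembles, 1, median)
  }
  persons <- sample_vital_events(persons, exams, config)
  # low-reporting flag lives at hospital level; person inherits it
  hosp <- unique(exams$hospital_id)
  low <- hosp[runif(length(hosp)) < config$low_reporting_hospital_prob]
  ph <- exams$hospital_id[match(persons$person_id, exams$person_id)]
  persons$low_reporting_hospital <- ph %in% low
  ot <- simulate_outcomes(persons, exams, config)
  cohort <- as_cohort(persons, exams, ot$outcomes, truth = ot$truth)
  cohort$config <- config
  if (keep_ensembles) cohort$ensembles <- d$ensembles
  cohort
}
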