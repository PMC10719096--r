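# Fixtures and independent oracles shared across the test files.

# Four-person single-stratum toy cohort with a closed-form ERR estimate.
#
# Risk set at age 10 (case P1): members P1 (Z=10), P2 (0), P3 (0).
# Risk set at age 12 (case P2): members P2 (Z=0), P3 (10).
# l(beta) = log(1+10b) - log(3+10b) - log(2+10b);
# dl/db = 0  <=>  1 - 2x - x^2 = 0 with x = 10b, so b = (sqrt(2)-1)/10.
toy_cohort <- function() {
  persons <- data.frame(
    person_id = c("P1", "P2", "P3", "P4"),
    sex = "male", country = "UK",
    birth_date = 1990, registry_start = 1950,
    death_date = c(NA, NA, NA, 1999),
    emigration_date = NA_real_, admin_end_date = 2016,
    ses = NA_integer_, transplant = FALSE,
    low_reporting_hospital = FALSE, vital_status_known = TRUE,
    stringsAsFactors = FALSE)
  exams <- data.frame(
    exam_id = paste0("E", 1:5),
    person_id = c("P1", "P2", "P3", "P3", "P4"),
    age_at_exam = c(7, 5, 3, 9, 1),
    calendar_year = 1990L + c(7L, 5L, 3L, 9L, 1L),
    body_region = "head_neck", hospital_id = "UK_H1",
    abm_dose_mean = c(10, 0, 0, 10, 0),
    abm_dose_median = c(10, 0, 0, 10, 0),
    stringsAsFactors = FALSE)
  outcomes <- data.frame(
    person_id = c("P1", "P2"),
    age_at_diagnosis = c(10, 12),
    morphology_code = "9650", behavior_code = 3L,
    stringsAsFactors = FALSE)
  apply_inclusion_exclusion(as_cohort(persons, exams, outcomes))
}

toy_loglik <- function(beta) {
  log(1 + 10 * beta) - log(3 + 10 * beta) - log(2 + 10 * beta)
}

# small simulation config for fast tests
test_config <- function(seed = 1, n_persons = 5000, ...) {
  sim_config(n_persons = n_persons, seed = seed,
             dose_uncertainty = FALSE, ...)
}

# Brute-force risk sets and partial likelihood, written independently of
# the engine: plain loops over persons, no data.table.
brute_force_risk_sets <- function(cohort, endpoint = "all_heme", lag = 2,
                                  metric = "abm_dose_mean") {
  fu <- cohort$followup
  p <- cohort$persons
  strat <- stratum_ids(p)
  names(strat) <- p$person_id
  inc <- fu[fu$included, ]
  groups <- classify_outcome(cohort$outcomes$morphology_code,
                             cohort$outcomes$behavior_code)
  is_case <- vapply(groups, function(g) endpoint %in% g, logical(1))
  oc <- cohort$outcomes[is_case, , drop = FALSE]
  sets <- list()
  for (i in seq_len(nrow(oc))) {
    pid <- oc$person_id[i]
    j <- match(pid, inc$person_id)
    if (is.na(j)) next
    t <- oc$age_at_diagnosis[i]
    if (!(t > inc$entry_age[j] && t <= inc$exit_age[j])) next
    members <- inc$person_id[inc$entry_age < t & t <= inc$exit_age &
                               strat[inc$person_id] == strat[pid]]
    z <- vapply(members, function(m) {
      ex <- cohort$exams[cohort$exams$person_id == m, ]
      d <- if (metric == "exam_count") rep(1, nrow(ex)) else ex[[metric]]
      sum(d[ex$age_at_exam <= t - lag])
    }, numeric(1))
    sets[[length(sets) + 1L]] <- list(t = t, case = pid,
                                      members = members, z = z)
  }
  sets
}

brute_force_loglik <- function(beta, sets) {
  s <- 0
  for (rs in sets) {
    rr <- 1 + beta * rs$z
    if (any(rr <= 0)) return(-Inf)
    s <- s + log(rr[[match(rs$case, rs$members)]]) - log(sum(rr))
  }
  s
}

# Construct an err_risk_sets object directly from member-level data, for
# tests of the categorical machinery on designed risk sets.
# member_cat: list of integer vectors (categories per member);
# case_cat: integer vector (category of the case in each set).
make_cat_risk_sets <- function(member_cat, case_cat, K,
                               cutpoints = seq(0, by = 5,
                                               length.out = K)) {
  n <- length(member_cat)
  counts <- t(vapply(member_cat, function(m) tabulate(m, nbins = K),
                     integer(K)))
  colnames(counts) <- dose_category_labels(cutpoints)
  member_z <- unlist(lapply(member_cat, function(m)
    cutpoints[m] + 0.5))
  structure(list(
    n_cases = n, n_members = lengths(member_cat),
    case_z = cutpoints[case_cat] + 0.5,
    sum_z = vapply(seq_len(n), function(i)
      sum(cutpoints[member_cat[[i]]] + 0.5), numeric(1)),
    member_z = member_z,
    member_set = rep(seq_len(n), lengths(member_cat)),
    cat_case = case_cat,
    cat_counts = counts, cutpoints = cutpoints,
    max_z = max(member_z), informative = TRUE,
    n_singleton = 0L, endpoint = "synthetic", lag = 2,
    metric = "abm_dose_mean", status = "ok"),
    class = "err_risk_sets")
}
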