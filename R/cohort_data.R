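#' @importFrom stats median optimise optimize optim uniroot quantile rbinom
#'   rnbinom runif rexp rlnorm rpois setNames qchisq pchisq qnorm rnorm
#'   aggregate ave
#'   complete.cases var sd
#' @importFrom utils read.csv write.csv head
#' @import data.table
NULL

# Endpoint vocabulary -----------------------------------------------------

#' Endpoint groups recognised by the outcome classifier
#'
#' Hematological malignancies are analysed under a hierarchy of endpoint
#' groups following the revised WHO classification of lymphoid and myeloid
#' malignancies: every malignant case belongs to `all_heme`; lymphoid cases
#' additionally to `lymphoid` and then `HL` or `NHL` (with NHL subtypes
#' `matureB`, `matureTNK`, `precursor`); myeloid malignancies and acute
#' leukemia to `myeloid_AL` and then `AML_ALMP_ALAL` or `MPN_MDS`.
#' `leukemia_excl_CLL` is a legacy cross-lineage grouping kept for
#' comparability with earlier leukemia studies.
#'
#' @return Character vector of endpoint group labels.
#' @export
endpoint_groups <- function() {
  c("all_heme", "lymphoid", "HL", "NHL", "matureB", "matureTNK",
    "precursor", "myeloid_AL", "AML_ALMP_ALAL", "MPN_MDS",
    "leukemia_excl_CLL", "histiocytic", "unspecified")
}

# subtype -> hierarchy expansion (excludes the cross-cutting leukemia flag)
.subtype_groups <- list(
  HL            = c("all_heme", "lymphoid", "HL"),
  mature_B      = c("all_heme", "lymphoid", "NHL", "matureB"),
  mature_TNK    = c("all_heme", "lymphoid", "NHL", "matureTNK"),
  precursor     = c("all_heme", "lymphoid", "NHL", "precursor"),
  NHL_NOS       = c("all_heme", "lymphoid", "NHL"),
  lymphoid_NOS  = c("all_heme", "lymphoid"),
  AML_ALMP_ALAL = c("all_heme", "myeloid_AL", "AML_ALMP_ALAL"),
  MPN_MDS       = c("all_heme", "myeloid_AL", "MPN_MDS"),
  myeloid_NOS   = c("all_heme", "myeloid_AL"),
  histiocytic   = c("all_heme", "histiocytic"),
  unspecified   = c("all_heme", "unspecified")
)

#' Default morphology-to-group mapping table
#'
#' An editable table mapping ICD-O-3 morphology codes to malignancy
#' subtypes, with flags for codes excluded as therapy-related or linked to
#' predisposing syndromes. The default covers the major ICD-O-3 code blocks
#' for hematological malignancies; users with registry-specific code lists
#' should supply their own table with the same columns
#' (`morphology_code`, `subtype`, `leukemia_excl_cll`, `therapy_related`).
#'
#' @return A data.frame, one row per morphology code.
#' @export
default_morphology_mapping <- function() {
  path <- system.file("extdata", "morphology_groups.csv",
                      package = "pedctrisk", mustWork = TRUE)
  m <- read.csv(path, colClasses = c(
    morphology_code = "character", subtype = "character",
    leukemia_excl_cll = "logical", therapy_related = "logical"))
  m
}

#' Classify an outcome into endpoint groups
#'
#' Applies the malignancy-only rule (ICD-O-3 behavior code 3), drops codes
#' flagged as therapy-related or linked to predisposing syndromes, and
#' expands the mapped subtype into the full endpoint hierarchy. Codes absent
#' from the mapping table are routed to `unspecified` with a warning rather
#' than silently dropped.
#'
#' @param morphology_code Character vector of ICD-O-3 morphology codes.
#' @param behavior_code Integer vector of ICD-O-3 behavior codes.
#' @param mapping Mapping table as from [default_morphology_mapping()].
#' @return A list (one element per input) of character vectors of endpoint
#'   groups; empty vector for non-malignant or excluded codes.
#' @export
classify_outcome <- function(morphology_code, behavior_code,
                             mapping = default_morphology_mapping()) {
  stopifnot(length(morphology_code) == length(behavior_code))
  idx <- match(as.character(morphology_code), mapping$morphology_code)
  unknown <- is.na(idx) & behavior_code == 3
  if (any(unknown)) {
    warning(sprintf(
      "%d morphology code(s) not in mapping table routed to 'unspecified': %s",
      sum(unknown), paste(unique(morphology_code[unknown]), collapse = ", ")))
  }
  out <- vector("list", length(morphology_code))
  for (i in seq_along(out)) {
    if (behavior_code[i] != 3) {
      out[[i]] <- character(0)
      next
    }
    if (is.na(idx[i])) {
      out[[i]] <- .subtype_groups[["unspecified"]]
      next
    }
    row <- mapping[idx[i], ]
    if (isTRUE(row$therapy_related)) {
      out[[i]] <- character(0)
      next
    }
    g <- .subtype_groups[[row$subtype]]
    if (is.null(g)) stop("unknown subtype in mapping table: ", row$subtype)
    if (isTRUE(row$leukemia_excl_cll)) g <- c(g, "leukemia_excl_CLL")
    out[[i]] <- g
  }
  out
}

# returns logical vector: does each outcome row belong to `endpoint`?
outcome_in_endpoint <- function(outcomes, endpoint,
                                mapping = default_morphology_mapping()) {
  if (nrow(outcomes) == 0L) return(logical(0))
  groups <- classify_outcome(outcomes$morphology_code, outcomes$behavior_code,
                             mapping)
  vapply(groups, function(g) endpoint %in% g, logical(1))
}

# Cohort container --------------------------------------------------------

person_cols <- c("person_id", "sex", "country", "birth_date",
                 "registry_start", "death_date", "emigration_date",
                 "admin_end_date", "ses", "transplant",
                 "low_reporting_hospital", "vital_status_known")
exam_cols <- c("exam_id", "person_id", "age_at_exam", "calendar_year",
               "body_region", "hospital_id")
outcome_cols <- c("person_id", "age_at_diagnosis", "morphology_code",
                  "behavior_code")

#' Assemble a CT cohort object
#'
#' Bundles the three standard tables (persons, examinations, outcomes) after
#' validating schemas and the cross-table invariants: unique person ids,
#' exam ids referencing known persons, event dates after birth, and at most
#' one outcome per person (the first malignancy ends follow-up).
#'
#' @param persons,exams,outcomes Data frames with the schemas documented in
#'   [read_cohort_tables()].
#' @param truth Optional simulation truth table (see [simulate_cohort()]).
#' @return An object of class `ct_cohort`: a list with elements `persons`,
#'   `exams`, `outcomes` and optionally `truth`, `followup`,
#'   `exclusion_log`.
#' @export
as_cohort <- function(persons, exams, outcomes, truth = NULL) {
  check_schema(persons, person_cols, "persons")
  check_schema(exams, exam_cols, "exams")
  check_schema(outcomes, outcome_cols, "outcomes")
  if (anyDuplicated(persons$person_id))
    stop("duplicate person_id in persons table")
  if (anyDuplicated(outcomes$person_id))
    stop("more than one outcome per person; first cancer ends follow-up")
  if (!all(exams$person_id %in% persons$person_id))
    stop("exams reference unknown person_id")
  if (!all(outcomes$person_id %in% persons$person_id))
    stop("outcomes reference unknown person_id")
  bad <- rep(FALSE, nrow(persons))
  for (col in c("death_date", "emigration_date", "admin_end_date")) {
    v <- persons[[col]]
    bad <- bad | (!is.na(v) & v <= persons$birth_date)
  }
  if (any(bad)) stop("event date on or before birth_date for person(s): ",
                     paste(head(persons$person_id[bad]), collapse = ", "))
  if (any(is.na(persons$registry_start)))
    stop("registry_start missing; required for every person")
  if (any(is.na(persons$admin_end_date)))
    stop("admin_end_date missing; required for every person")
  structure(list(persons = persons, exams = exams, outcomes = outcomes,
                 truth = truth), class = "ct_cohort")
}

check_schema <- function(df, required, name) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s table lacks required column(s): %s", name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat("<ct_cohort>", nrow(x$persons), "persons,", nrow(x$exams), "exams,",
      nrow(x$outcomes), "outcomes\n")
  if (!is.null(x$followup))
    cat("  follow-up derived:", sum(x$followup$included), "included,",
        sum(!x$followup$included), "excluded\n")
  invisible(x)
}

# IO ----------------------------------------------------------------------

#' Read the cohort tables from a directory of CSV files
#'
#' Expects `persons.csv`, `exams.csv`, `outcomes.csv` and optionally
#' `doses.csv` (long format: `exam_id`, `realization_index`,
#' `abm_dose_mGy`) or a summarized `dose_summary.csv` (`exam_id`,
#' `abm_dose_mean`, `abm_dose_median`). Dose summaries are merged onto the
#' exam table. All dates are decimal calendar years.
#'
#' @param dir Directory containing the CSV files.
#' @return A `ct_cohort`.
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(f, classes) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    read.csv(p, colClasses = classes)
  }
  persons <- rd("persons.csv", c(person_id = "character",
                                 sex = "character", country = "character"))
  exams <- rd("exams.csv", c(exam_id = "character",
                             person_id = "character",
                             body_region = "character",
                             hospital_id = "character"))
  outcomes <- if (file.exists(file.path(dir, "outcomes.csv"))) {
    rd("outcomes.csv", c(person_id = "character",
                         morphology_code = "character"))
  } else {
    data.frame(person_id = character(0), age_at_diagnosis = numeric(0),
               morphology_code = character(0), behavior_code = integer(0))
  }
  for (col in c("transplant", "low_reporting_hospital", "vital_status_known"))
    persons[[col]] <- as.logical(persons[[col]])
  dsp <- file.path(dir, "dose_summary.csv")
  if (file.exists(dsp)) {
    ds <- read.csv(dsp, colClasses = c(exam_id = "character"))
    exams <- merge(exams, ds, by = "exam_id", sort = FALSE)
  } else if (file.exists(file.path(dir, "doses.csv"))) {
    long <- read.csv(file.path(dir, "doses.csv"),
                     colClasses = c(exam_id = "character"))
    ens <- ensembles_from_long(long)
    exams <- merge(exams, summarize_ensembles(ens), by = "exam_id",
                   sort = FALSE)
  }
  exams <- exams[order(exams$person_id, exams$age_at_exam), ]
  rownames(exams) <- NULL
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv")))
    truth <- read.csv(file.path(dir, "truth.csv"),
                      colClasses = c(person_id = "character"))
  as_cohort(persons, exams, outcomes, truth = truth)
}

#' Write the cohort tables to a directory of CSV files
#'
#' Inverse of [read_cohort_tables()]; numeric columns are written at full
#' precision (15 significant digits) so that a write/read round trip
#' reproduces the tables.
#'
#' @param cohort A `ct_cohort`.
#' @param dir Output directory (created if absent).
#' @param ensembles Optional dose-ensemble matrix (exams in rows) to emit as
#'   long-format `doses.csv`.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, ensembles = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    p <- file.path(dir, f)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 15))
    write.csv(df, p, row.names = FALSE, na = "")
    p
  }
  files <- c(wr(cohort$persons, "persons.csv"),
             wr(cohort$exams, "exams.csv"),
             wr(cohort$outcomes, "outcomes.csv"))
  if (!is.null(cohort$truth)) files <- c(files, wr(cohort$truth, "truth.csv"))
  if (!is.null(ensembles)) {
    long <- data.frame(
      exam_id = rep(rownames(ensembles), times = ncol(ensembles)),
      realization_index = rep(seq_len(ncol(ensembles)),
                              each = nrow(ensembles)),
      abm_dose_mGy = as.vector(ensembles))
    files <- c(files, wr(long, "doses.csv"))
  }
  invisible(files)
}

# Follow-up ---------------------------------------------------------------

#' Derive follow-up intervals
#'
#' Follow-up starts `entry_offset` years after the first CT examination (2
#' years by default, to limit reverse causation) or at the age when complete
#' cancer registration became available in the person's country/region,
#' whichever is later. Exit is the earliest of any cancer diagnosis, death,
#' emigration and administrative end of registry follow-up. A person whose
#' exit does not come after entry contributes no person-time and is flagged
#' not included. The at-risk window is the half-open interval
#' `[entry_age, exit_age)`; an event at exactly `exit_age` belongs to it.
#'
#' @param cohort A `ct_cohort`.
#' @param entry_offset Years between first CT and start of follow-up.
#' @param followup_cap Optional named vector (by country) of maximum attained
#'   ages: exit is capped at the country value (used by the sensitivity
#'   analysis ending follow-up shortly after the country-specific maximum
#'   age at exposure).
#' @return The cohort with a `followup` data.frame added (`person_id`,
#'   `entry_age`, `exit_age`, `exit_reason`, `included`,
#'   `exclusion_reason`).
#' @export
derive_followup <- function(cohort, entry_offset = 2, followup_cap = NULL) {
  p <- cohort$persons
  fca <- first_ct_age(cohort$exams, p$person_id)
  if (anyNA(fca)) stop("person(s) without any examination: ",
                       paste(head(p$person_id[is.na(fca)]), collapse = ", "))
  diag_age <- rep(NA_real_, nrow(p))
  m <- match(p$person_id, cohort$outcomes$person_id)
  diag_age[!is.na(m)] <- cohort$outcomes$age_at_diagnosis[m[!is.na(m)]]

  entry <- pmax(fca + entry_offset, p$registry_start - p$birth_date)
  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  a_diag <- inf_na(diag_age)
  a_death <- inf_na(p$death_date - p$birth_date)
  a_emig <- inf_na(p$emigration_date - p$birth_date)
  a_admin <- inf_na(p$admin_end_date - p$birth_date)
  if (!is.null(followup_cap))
    a_admin <- pmin(a_admin, inf_na(unname(followup_cap[p$country])))
  exit <- pmin(a_diag, a_death, a_emig, a_admin)
  # ties resolved by priority: diagnosis > death > emigration > admin end
  reason <- rep("admin_end", nrow(p))
  reason[a_emig == exit] <- "emigration"
  reason[a_death == exit] <- "death"
  reason[a_diag == exit] <- "diagnosis"
  included <- exit > entry
  fu <- data.frame(
    person_id = p$person_id,
    entry_age = entry, exit_age = exit, exit_reason = reason,
    included = included,
    exclusion_reason = ifelse(included, NA_character_,
                              "followup_lt_2y_or_late_entry"),
    first_ct_age = fca, diag_age = diag_age,
    stringsAsFactors = FALSE)
  cohort$followup <- fu
  cohort
}

#' Inclusion/exclusion rule set
#'
#' @param entry_offset Years from first CT to entry (2 main; 5 or 10 in the
#'   exclusion-window sensitivity analyses).
#' @param exclude_prior_cancer,exclude_cancer_within_1y Core cohort rules.
#' @param drop_transplant,drop_low_reporting,require_vital_status,
#'   drop_born_before_registry Optional sensitivity filters.
#' @param followup_cap Optional named per-country vector of attained-age
#'   caps on exit.
#' @return A list of rules for [apply_inclusion_exclusion()].
#' @export
inclusion_rules <- function(entry_offset = 2,
                            exclude_prior_cancer = TRUE,
                            exclude_cancer_within_1y = TRUE,
                            drop_transplant = FALSE,
                            drop_low_reporting = FALSE,
                            require_vital_status = FALSE,
                            drop_born_before_registry = FALSE,
                            followup_cap = NULL) {
  list(entry_offset = entry_offset,
       exclude_prior_cancer = exclude_prior_cancer,
       exclude_cancer_within_1y = exclude_cancer_within_1y,
       drop_transplant = drop_transplant,
       drop_low_reporting = drop_low_reporting,
       require_vital_status = require_vital_status,
       drop_born_before_registry = drop_born_before_registry,
       followup_cap = followup_cap)
}

#' Apply inclusion/exclusion rules
#'
#' Derives (or re-derives) follow-up under the rule set, then marks persons
#' excluded for: a cancer diagnosis before the first CT, a diagnosis within
#' one year of the first CT, follow-up shorter than the entry offset (which
#' also absorbs diagnoses between 1 year and entry), and any requested
#' sensitivity filters. The exclusion log counts persons per reason (a
#' person is logged under the first applicable reason, in the order above).
#'
#' @param cohort A `ct_cohort`.
#' @param rules From [inclusion_rules()].
#' @return The cohort with `followup$included` finalized and an
#'   `exclusion_log` data.frame (`reason`, `n`) attached. Errors if no
#'   persons remain.
#' @export
apply_inclusion_exclusion <- function(cohort, rules = inclusion_rules()) {
  cohort <- derive_followup(cohort, entry_offset = rules$entry_offset,
                            followup_cap = rules$followup_cap)
  fu <- cohort$followup
  p <- cohort$persons
  reason <- rep(NA_character_, nrow(fu))
  mark <- function(cond, lab) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(is.na(reason) & cond, lab, reason)
  }
  if (rules$exclude_prior_cancer)
    mark(fu$diag_age < fu$first_ct_age, "prior_cancer")
  if (rules$exclude_cancer_within_1y)
    mark(fu$diag_age < fu$first_ct_age + 1, "cancer_within_1y")
  mark(!fu$included, "followup_lt_2y_or_late_entry")
  if (rules$drop_transplant) mark(p$transplant, "transplant")
  if (rules$drop_low_reporting)
    mark(p$low_reporting_hospital, "low_reporting_hospital")
  if (rules$require_vital_status)
    mark(!p$vital_status_known, "no_vital_status")
  if (rules$drop_born_before_registry)
    mark(p$birth_date < p$registry_start, "born_before_registry")

  fu$included <- is.na(reason)
  fu$exclusion_reason <- reason
  if (!any(fu$included)) stop("no persons remain after exclusions")
  tab <- table(reason[!is.na(reason)])
  log <- data.frame(reason = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  cohort$followup <- fu
  cohort$exclusion_log <- log
  cohort
}

#' Total person-years of included follow-up
#' @param cohort A `ct_cohort` with follow-up derived.
#' @return Sum of `exit_age - entry_age` over included persons.
#' @export
person_years <- function(cohort) {
  fu <- cohort$followup
  if (is.null(fu)) stop("derive follow-up first")
  sum((fu$exit_age - fu$entry_age)[fu$included])
}

# age at first CT per person, aligned to `person_ids`; grouping is done
# on integer indices (character grouping is the slow path at cohort scale)
first_ct_age <- function(exams, person_ids) {
  pi <- match(exams$person_id, person_ids)
  if (anyNA(pi)) stop("exams reference unknown person_id")
  dt <- data.table::data.table(pi = pi, age = exams$age_at_exam)
  agg <- dt[, .(fca = min(age)), by = pi]
  out <- rep(NA_real_, length(person_ids))
  out[agg$pi] <- agg$fca
  out
}

# Strata ------------------------------------------------------------------

default_birth_cohort_breaks <- c(1960, 1980, 1985, 1990, 1995, 2000, 2005, 2013)

birth_cohort_bin <- function(birth_date,
                             breaks = default_birth_cohort_breaks) {
  labs <- paste0(breaks[-length(breaks)], "-", breaks[-1] - 1)
  labs[findInterval(birth_date, breaks, all.inside = TRUE)]
}

#' Stratum labels for the partial-likelihood analyses
#'
#' Builds the cross-classification used to stratify the baseline hazard:
#' sex x country x birth cohort (bins 1960-1979, 1980-1984, ...,
#' 2005-2012), optionally crossed with socio-economic status.
#'
#' @param persons Persons table.
#' @param vars Stratification variables, any of `"sex"`, `"country"`,
#'   `"birth_cohort"`, `"ses"`.
#' @return Character vector of stratum ids, one per person.
#' @export
stratum_ids <- function(persons,
                        vars = c("sex", "country", "birth_cohort")) {
  parts <- lapply(vars, function(v) switch(v,
    sex = persons$sex,
    country = persons$country,
    birth_cohort = birth_cohort_bin(persons$birth_date),
    ses = ifelse(is.na(persons$ses), "ses_na", paste0("ses", persons$ses)),
    stop("unknown stratification variable: ", v)))
  do.call(paste, c(parts, sep = "|"))
}
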