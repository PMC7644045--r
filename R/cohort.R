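#' Attribute patients to practices by office-visit counts
#'
#' A patient is attributed to a practice when they have at least `min_visits`
#' office visits (office-visit CPT set) to that practice's providers during
#' the measure year. Patients reaching the threshold at two or more practices
#' are excluded as cared for by multiple practices; patients reaching it
#' nowhere are excluded for too few visits.
#'
#' @param visits visit-claim table.
#' @param practice_set a `practice_set` from [gate_and_assign()]; only
#'   included practices receive patients.
#' @param codesets a [codeset_config()].
#' @param min_visits attribution threshold (default 2 office visits).
#' @param year measure year (default 2015).
#' @param patient_ids patients to attribute (default: all patients in
#'   `visits`).
#' @return Data frame `patient_id`, `practice_id` (`NA` when excluded),
#'   `attribution_status` in `attributed` / `too_few_visits` /
#'   `multiple_practices`.
#' @export
attribute_patients <- function(visits, practice_set, codesets = codeset_config(),
                               min_visits = 2, year = 2015,
                               patient_ids = NULL) {
  stopifnot(inherits(practice_set, "practice_set"))
  if (is.null(patient_ids)) patient_ids <- sort(unique(visits$patient_id))
  inc <- practice_set$practices$practice_id[practice_set$practices$included]
  memb <- practice_set$membership
  memb <- memb[memb$practice_id %in% inc, ]
  v <- visits[visits$cpt_code %in% codesets$office_visit_cpt &
                format(visits$service_date, "%Y") == as.character(year) &
                visits$provider_id %in% memb$provider_id &
                visits$patient_id %in% patient_ids, ]
  v$practice_id <- memb$practice_id[match(v$provider_id, memb$provider_id)]
  counts <- as.data.frame(table(patient_id = v$patient_id,
                                practice_id = v$practice_id),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq >= min_visits, ]
  n_prac <- table(counts$patient_id)
  status <- stats::setNames(rep("too_few_visits", length(patient_ids)),
                            patient_ids)
  single <- names(n_prac)[n_prac == 1]
  multi <- names(n_prac)[n_prac > 1]
  status[single] <- "attributed"
  status[multi] <- "multiple_practices"
  prac <- stats::setNames(rep(NA_character_, length(patient_ids)), patient_ids)
  prac[counts$patient_id[counts$patient_id %in% single]] <-
    counts$practice_id[counts$patient_id %in% single]
  data.frame(patient_id = patient_ids,
             practice_id = unname(prac),
             attribution_status = unname(status),
             stringsAsFactors = FALSE)
}

# completed calendar years between birth and reference date (birthday rule,
# so a 66th birthday on the index date itself counts)
age_in_years <- function(birth, on) {
  b <- as.POSIXlt(as.Date(birth)); o <- as.POSIXlt(as.Date(on))
  (o$year - b$year) -
    as.integer(o$mon < b$mon | (o$mon == b$mon & o$mday < b$mday))
}

COHORT_REASONS <- c("too_few_visits", "multiple_practices", "enrollment_gap",
                    "medicare_advantage", "died", "under_66", "ltc_resident",
                    "unknown_rurality", "none")

#' Apply the eligibility cascade to attributed patients
#'
#' Sequential first-fail exclusions, in the fixed order: incomplete
#' parts A/B/D enrollment across the two-year window; Medicare Advantage
#' enrollment; death before the end of the measure year; age under 66 on the
#' index date; long-term-care nursing facility use (any claim bearing a
#' configured nursing-facility CPT code not billed by a skilled nursing
#' facility); unknown rural/urban residence.
#'
#' @param attribution result of [attribute_patients()].
#' @param beneficiaries beneficiary table (see [simulate_claims()] for the
#'   expected columns).
#' @param visits visit-claim table (supplies nursing-facility claims; must
#'   carry an `snf_biller` logical column).
#' @param codesets a [codeset_config()].
#' @param practice_set optional `practice_set` carrying team types to attach.
#' @param index_date age reference date (default `"2015-01-01"`).
#' @return Data frame of cohort records: one row per candidate with
#'   `patient_id`, `practice_id`, `team_type`, `age_on_index`, covariates,
#'   `included`, `exclusion_reason`.
#' @export
apply_eligibility <- function(attribution, beneficiaries, visits,
                              codesets = codeset_config(),
                              practice_set = NULL,
                              index_date = as.Date("2015-01-01")) {
  index_date <- as.Date(index_date)
  missing <- setdiff(attribution$patient_id, beneficiaries$patient_id)
  if (length(missing) > 0)
    stop("no beneficiary record for patient(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  ben <- beneficiaries[match(attribution$patient_id, beneficiaries$patient_id), ]
  ltc_claims <- visits[visits$cpt_code %in% codesets$nursing_facility_cpt &
                         !visits$snf_biller, ]
  has_ltc <- attribution$patient_id %in% ltc_claims$patient_id
  age <- age_in_years(ben$birth_date, index_date)

  reason <- rep("none", nrow(attribution))
  fail <- function(cond, why) reason <<- ifelse(reason == "none" & cond,
                                                why, reason)
  fail(attribution$attribution_status == "too_few_visits", "too_few_visits")
  fail(attribution$attribution_status == "multiple_practices",
       "multiple_practices")
  fail(!ben$enrollment_complete_2014_2015, "enrollment_gap")
  fail(ben$medicare_advantage, "medicare_advantage")
  fail(!ben$alive_through_2015, "died")
  fail(age < 66, "under_66")
  fail(has_ltc, "ltc_resident")
  fail(ben$rurality == "unknown", "unknown_rurality")

  covar_cols <- setdiff(names(ben),
                        c("patient_id", "home_practice_id", "area_id",
                          "birth_date", "enrollment_complete_2014_2015",
                          "medicare_advantage", "alive_through_2015"))
  cohort <- cbind(
    data.frame(patient_id = attribution$patient_id,
               practice_id = attribution$practice_id,
               age_on_index = age, stringsAsFactors = FALSE),
    ben[, covar_cols, drop = FALSE])
  cohort$included <- reason == "none"
  cohort$exclusion_reason <- reason
  if (!is.null(practice_set)) {
    p <- practice_set$practices
    cohort$team_type <- p$team_type[match(cohort$practice_id, p$practice_id)]
  } else cohort$team_type <- NA_character_
  rownames(cohort) <- NULL
  cohort
}

#' CONSORT-style cohort flow table
#'
#' @param cohort result of [apply_eligibility()].
#' @return Data frame `reason`, `n`: one row per exclusion reason (in cascade
#'   order) plus `none` (= included).
#' @export
cohort_flow <- function(cohort) {
  n <- table(factor(cohort$exclusion_reason, levels = COHORT_REASONS))
  data.frame(reason = names(n), n = as.integer(n), stringsAsFactors = FALSE)
}

#' Build the analytic cohort from a practice set and claims
#'
#' Convenience wrapper: attribute, re-apply the practice size floor
#' (practices with fewer than `min_patients` attributed diabetic patients
#' leave the study together with their patients), then run the eligibility
#' cascade.
#'
#' @inheritParams attribute_patients
#' @param beneficiaries beneficiary table.
#' @param min_patients practice-level floor on attributed diabetic patients
#'   (default 20).
#' @return List with `cohort` (eligibility records, included practices only),
#'   `practice_set` (with the size filter applied) and `attribution`.
#' @export
build_cohort <- function(visits, practice_set, beneficiaries,
                         codesets = codeset_config(), min_visits = 2,
                         min_patients = 20, year = 2015) {
  attribution <- attribute_patients(visits, practice_set, codesets,
                                    min_visits = min_visits, year = year,
                                    patient_ids = beneficiaries$patient_id)
  att <- attribution[attribution$attribution_status == "attributed", ]
  counts <- table(att$practice_id)
  p <- practice_set$practices
  drop <- p$included & p$practice_id %in% names(counts)[counts < min_patients] |
    p$included & !p$practice_id %in% names(counts)
  p$n_attributed <- ifelse(p$practice_id %in% names(counts),
                           as.integer(counts[p$practice_id]), 0L)
  p$exclusion_reason[drop] <- "too_few_patients"
  p$included[drop] <- FALSE
  practice_set$practices <- p
  # patients of dropped practices leave with the practice
  kept <- p$practice_id[p$included]
  attribution <- attribution[is.na(attribution$practice_id) |
                               attribution$practice_id %in% kept, ]
  cohort <- apply_eligibility(attribution, beneficiaries, visits, codesets,
                              practice_set = practice_set)
  list(cohort = cohort, practice_set = practice_set,
       attribution = attribution)
}
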