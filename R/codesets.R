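#' Measure code-set configuration
#'
#' All claims-based measures in this package match codes as exact strings
#' against named code sets. Real HEDIS/NDC value sets and the AHRQ prevention
#' quality indicator logic are licensing-restricted; the defaults shipped here
#' are small synthetic stand-ins that exercise the same plumbing. Supply your
#' own sets to run against real coding systems.
#'
#' @param office_visit_cpt CPT codes counting as a primary-care office visit
#'   (used for patient attribution, visit counts and continuity).
#' @param specialist_visit_cpt CPT codes counting as a specialist visit or
#'   consultation (office visits plus consultation codes).
#' @param eye_exam_codes,hba1c_codes,nephropathy_codes procedure codes for the
#'   three diabetes process-of-care measures. An empty vector disables the
#'   measure (its flag is reported as `NA`, not `FALSE`).
#' @param nursing_facility_cpt CPT codes flagging long-term-care nursing
#'   facility use (exclusion from the cohort when billed by a non-SNF).
#' @param ed_revenue_codes facility revenue codes identifying an emergency
#'   department visit on outpatient claims.
#' @param preventable_hosp_dx_codes diagnosis codes whose presence on an
#'   inpatient stay flags a potentially preventable (ambulatory-care-sensitive)
#'   hospitalization. The default is a synthetic toy list, not the AHRQ set.
#' @param drug_classes drug class labels recognised on prescription fills.
#'
#' @return An object of class `codeset_config` (a named list of character
#'   vectors).
#' @export
codeset_config <- function(
    office_visit_cpt = c(sprintf("992%02d", 1:5), sprintf("992%02d", 11:15)),
    specialist_visit_cpt = c(sprintf("992%02d", 1:5), sprintf("992%02d", 11:15),
                             sprintf("992%02d", 41:45)),
    eye_exam_codes = c("92002", "92004", "92012", "92014", "2022F"),
    hba1c_codes = c("83036", "83037", "3044F"),
    nephropathy_codes = c("82043", "82044", "3060F"),
    nursing_facility_cpt = c(sprintf("993%02d", 4:10), "99315", "99316", "99318"),
    ed_revenue_codes = c(sprintf("045%d", 0:9), "0981"),
    preventable_hosp_dx_codes = c("E1100", "E1101", "I110", "I500", "J189",
                                  "J440", "J441", "E860"),
    drug_classes = c("antidiabetic", "statin", "ace_arb", "high_risk")) {
  x <- list(
    office_visit_cpt = as.character(office_visit_cpt),
    specialist_visit_cpt = as.character(specialist_visit_cpt),
    eye_exam_codes = as.character(eye_exam_codes),
    hba1c_codes = as.character(hba1c_codes),
    nephropathy_codes = as.character(nephropathy_codes),
    nursing_facility_cpt = as.character(nursing_facility_cpt),
    ed_revenue_codes = as.character(ed_revenue_codes),
    preventable_hosp_dx_codes = as.character(preventable_hosp_dx_codes),
    drug_classes = as.character(drug_classes)
  )
  class(x) <- "codeset_config"
  x
}

#' Read a code-set configuration from JSON
#'
#' @param path path to a JSON file with named code arrays (any subset of the
#'   `codeset_config()` arguments; missing sets fall back to the defaults).
#' @return A `codeset_config`.
#' @export
read_codesets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(codeset_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown code set name(s): ", paste(bad, collapse = ", "))
  do.call(codeset_config, raw)
}

#' Write a code-set configuration to JSON
#'
#' @param codesets a `codeset_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codesets <- function(codesets, path) {
  stopifnot(inherits(codesets, "codeset_config"))
  jsonlite::write_json(unclass(codesets), path, pretty = TRUE)
  invisible(path)
}

# CMS specialty codes treated as primary-care physicians; NPs (50) and PAs
# (97) additionally require a primary-care taxonomy flag.
PCP_SPECIALTIES <- c("01", "08", "11", "38")
NP_SPECIALTY <- "50"
PA_SPECIALTY <- "97"

# Specialist CMS specialty codes used for specialist-contact flags.
SPECIALIST_SPECIALTIES <- c(cardiologist = "06", nephrologist = "39",
                            endocrinologist = "46")
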