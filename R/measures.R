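#' Modified Continuity Index
#'
#' Dispersion-of-care index computed from the number of visits `N` and the
#' number of distinct providers `k` seen:
#' \deqn{MMCI = \frac{1 - k/(N + 0.1)}{1 - 1/(N + 0.1)}}
#' It approaches 1 when all visits go to a single provider and 0 when every
#' visit goes to a different provider. A single visit returns 1 by
#' convention. The unnormalised variant `1 - k/(N + 0.1)` is available via
#' `normalized = FALSE`.
#'
#' @param visit_provider_ids vector of provider ids, one entry per visit
#'   (order irrelevant).
#' @param normalized use the normalised 0-1 form (default TRUE).
#' @return The index in `(0, 1]`; `NA` for an empty visit sequence.
#' @export
continuity_index <- function(visit_provider_ids, normalized = TRUE) {
  n <- length(visit_provider_ids)
  if (n == 0) return(NA_real_)
  k <- length(unique(visit_provider_ids))
  mmci(n, k, normalized = normalized)
}

#' @rdname continuity_index
#' @param n number of visits (>= 1).
#' @param k number of distinct providers (1 <= k <= n).
#' @export
mmci <- function(n, k, normalized = TRUE) {
  stopifnot(all(n >= 1), all(k >= 1), all(k <= n))
  raw <- 1 - k / (n + 0.1)
  if (!normalized) return(raw)
  ifelse(n == 1, 1, raw / (1 - 1 / (n + 0.1)))
}

#' Proportion of days covered by merged prescription fills
#'
#' Each fill of `s` days supply covers the closed day interval
#' `[fill_date, fill_date + s - 1]`. Overlapping fills are merged so every
#' calendar day counts at most once. The denominator starts at the later of
#' the window start and the diagnosis date (days before the initial
#' diagnosis are not eligible).
#'
#' @param fills data frame with `fill_date` (Date) and `days_supply`
#'   (integer); may be empty or overlapping.
#' @param window_start,window_end measurement window (Dates, inclusive).
#' @param diagnosis_date diagnosis date; `NULL` or a date before
#'   `window_start` leaves the window untouched.
#' @return Covered-day proportion in `[0, 1]`; `NA` when the eligible window
#'   is empty.
#' @export
pdc <- function(fills, window_start, window_end, diagnosis_date = NULL) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!is.null(diagnosis_date) && !is.na(diagnosis_date))
    window_start <- max(window_start, as.Date(diagnosis_date))
  denom <- as.numeric(window_end - window_start) + 1
  if (denom <= 0) return(NA_real_)
  if (is.null(fills) || nrow(fills) == 0) return(0)
  start <- as.numeric(as.Date(fills$fill_date))
  end <- start + fills$days_supply - 1
  # clip to window, drop fills fully outside
  lo <- as.numeric(window_start); hi <- as.numeric(window_end)
  start <- pmax(start, lo); end <- pmin(end, hi)
  keep <- start <= end
  if (!any(keep)) return(0)
  start <- start[keep]; end <- end[keep]
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  covered <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) cur_e <- max(cur_e, end[i])
    else { covered <- covered + (cur_e - cur_s + 1); cur_s <- start[i]; cur_e <- end[i] }
  }
  covered <- covered + (cur_e - cur_s + 1)
  covered / denom
}

year_of <- function(d) format(as.Date(d), "%Y")

#' Per-patient measure panel
#'
#' Computes, for every included cohort member, the process-of-care flags
#' (eye examination, HbA1c test, nephropathy monitoring), specialist contact
#' flags (endocrinologist, cardiologist, nephrologist via office-visit or
#' consultation codes), office-visit counts and Modified Continuity Indices
#' at three provider levels (any provider, any primary-care provider, the
#' patient's own practice), the antidiabetic proportion of days covered,
#' medication-class flags, and utilization flags (any ED visit, any
#' potentially preventable hospitalization).
#'
#' @param cohort cohort records from [build_cohort()] (included rows are
#'   used).
#' @param visits,prescriptions,facility_stays claim tables.
#' @param providers provider table.
#' @param practice_set `practice_set` defining own-practice membership.
#' @param codesets a [codeset_config()].
#' @param year measure year (default 2015).
#' @return Data frame, one row per included patient, with measure columns as
#'   described above. Disabled measures (empty code set) are `NA`.
#' @export
build_measure_panel <- function(cohort, visits, prescriptions, facility_stays,
                                providers, practice_set,
                                codesets = codeset_config(), year = 2015) {
  pat <- cohort[cohort$included, ]
  ids <- pat$patient_id
  v <- visits[year_of(visits$service_date) == as.character(year) &
                visits$patient_id %in% ids, ]
  panel <- data.frame(patient_id = ids, stringsAsFactors = FALSE)

  flag_any <- function(codes) {
    if (length(codes) == 0) return(rep(NA, length(ids)))
    ids %in% v$patient_id[v$cpt_code %in% codes]
  }
  panel$eye_exam <- flag_any(codesets$eye_exam_codes)
  panel$hba1c_test <- flag_any(codesets$hba1c_codes)
  panel$nephropathy_monitoring <- flag_any(codesets$nephropathy_codes)

  spec_code <- stats::setNames(providers$specialty_code, providers$provider_id)
  sv <- v[v$cpt_code %in% codesets$specialist_visit_cpt, ]
  for (sp in names(SPECIALIST_SPECIALTIES)) {
    hit <- sv$patient_id[spec_code[sv$provider_id] == SPECIALIST_SPECIALTIES[[sp]]]
    panel[[paste0("saw_", sp)]] <- ids %in% hit
  }

  ## visit counts and continuity at three provider levels
  ov <- v[v$cpt_code %in% codesets$office_visit_cpt, ]
  pc_ids <- providers$provider_id[is_primary_care(providers)]
  memb <- practice_set$membership
  own_prac <- stats::setNames(pat$practice_id, pat$patient_id)
  count_mci <- function(sub, suffix) {
    n <- tapply(sub$provider_id, sub$patient_id, length)
    k <- tapply(sub$provider_id, sub$patient_id, function(x) length(unique(x)))
    nn <- stats::setNames(rep(0L, length(ids)), ids)
    nn[names(n)] <- as.integer(n)
    mci <- rep(NA_real_, length(ids)); names(mci) <- ids
    mci[names(n)] <- mmci(as.numeric(n), as.numeric(k))
    panel[[paste0("visits_", suffix)]] <<- unname(nn)
    panel[[paste0("mci_", suffix)]] <<- unname(mci)
  }
  count_mci(ov, "any_provider")
  count_mci(ov[ov$provider_id %in% pc_ids, ], "any_pcp")
  prov_prac <- memb$practice_id[match(ov$provider_id, memb$provider_id)]
  own_ok <- !is.na(prov_prac) & prov_prac == own_prac[ov$patient_id]
  count_mci(ov[own_ok, ], "own_practice")

  ## medication measures
  rx <- prescriptions[prescriptions$patient_id %in% ids, ]
  bad <- setdiff(unique(rx$drug_class), codesets$drug_classes)
  if (length(bad) > 0)
    stop("unknown drug class label(s): ", paste(bad, collapse = ", "))
  rx_year <- rx[year_of(rx$fill_date) == as.character(year), ]
  ws <- as.Date(sprintf("%d-01-01", year))
  we <- as.Date(sprintf("%d-12-31", year))
  ad <- rx_year[rx_year$drug_class == "antidiabetic", ]
  ad_split <- split(ad[, c("fill_date", "days_supply")], ad$patient_id)
  dx <- stats::setNames(as.Date(pat$diabetes_diagnosis_date), pat$patient_id)
  pdc_v <- rep(NA_real_, length(ids)); names(pdc_v) <- ids
  # PDC is reported for patients with any antidiabetic fill in the window
  # (per-measure sub-cohort); others are NA
  any_ad <- ids %in% rx$patient_id[rx$drug_class == "antidiabetic"]
  for (pid in ids[any_ad])
    pdc_v[pid] <- pdc(ad_split[[pid]], ws, we, dx[pid])
  panel$pdc_antidiabetic <- unname(pdc_v)
  panel$statin_use <- ids %in% rx_year$patient_id[rx_year$drug_class == "statin"]
  panel$ace_arb_use <- ids %in% rx_year$patient_id[rx_year$drug_class == "ace_arb"]
  panel$high_risk_med_use <-
    ids %in% rx_year$patient_id[rx_year$drug_class == "high_risk"]

  ## utilization
  fs <- facility_stays[facility_stays$patient_id %in% ids &
                         year_of(facility_stays$admit_date) == as.character(year), ]
  util <- utilization_flags(fs, codesets)
  panel$any_ed_visit <- ids %in% util$ed_patients
  panel$any_preventable_hosp <- ids %in% util$preventable_patients

  panel
}

#' Utilization flags from facility stays
#'
#' An ED visit is an inpatient stay with a positive ED charge or an
#' outpatient facility claim with an ED revenue code. A preventable
#' hospitalization is an inpatient stay bearing any diagnosis code in the
#' configured ambulatory-care-sensitive list.
#'
#' @param facility_stays table with `patient_id`, `stay_type`
#'   (`inpatient`/`outpatient`), `ed_charge`, `revenue_codes` and
#'   `diagnosis_codes` (semicolon-separated strings).
#' @param codesets a [codeset_config()].
#' @return List with `ed_patients` and `preventable_patients` (patient id
#'   vectors).
#' @export
utilization_flags <- function(facility_stays, codesets = codeset_config()) {
  if (is.null(facility_stays) || nrow(facility_stays) == 0)
    return(list(ed_patients = character(0), preventable_patients = character(0)))
  has_code <- function(field, codes) {
    vapply(strsplit(field, ";", fixed = TRUE),
           function(x) any(trimws(x) %in% codes), logical(1))
  }
  ed <- (facility_stays$stay_type == "inpatient" &
           facility_stays$ed_charge > 0) |
    (facility_stays$stay_type == "outpatient" &
       has_code(facility_stays$revenue_codes, codesets$ed_revenue_codes))
  prev <- facility_stays$stay_type == "inpatient" &
    has_code(facility_stays$diagnosis_codes,
             codesets$preventable_hosp_dx_codes)
  list(ed_patients = unique(facility_stays$patient_id[ed]),
       preventable_patients = unique(facility_stays$patient_id[prev]))
}
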