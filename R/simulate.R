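#' Simulation configuration for synthetic claim bundles
#'
#' Defines the data-generating process for a fully synthetic two-year claims
#' window (2014-2015 analogue): providers grouped into latent practices with
#' dense within-practice patient sharing, four team compositions, per-practice
#' random intercepts on binary care measures, covariate effects on the logit
#' scale, office-visit and prescription-fill processes, and facility stays.
#'
#' @param n_service_areas number of service areas (network units).
#' @param practices_per_area latent practices per area.
#' @param practice_size_range integer `c(min, max)` providers per practice.
#' @param team_type_mix proportions over the four team compositions
#'   (`PCP`, `PCP_NP`, `PCP_NP_PA`, `PCP_PA`); must sum to 1.
#' @param patients_per_practice diabetic patients whose home practice is each
#'   practice.
#' @param within_practice_share_rate probability an office visit goes to the
#'   patient's home practice.
#' @param cross_practice_share_rate probability an office visit goes to a
#'   foreign practice in the same area. The remainder
#'   `1 - within - cross` goes to area specialists (cardiology, nephrology,
#'   endocrinology), which generates specialist-contact measures.
#' @param usual_provider_weight probability a within-practice visit goes to the
#'   patient's designated usual provider rather than a uniformly drawn member.
#'   The default 0 (uniform) keeps pairwise shared-patient counts above the
#'   30-patient edge threshold at desk scale; raising it concentrates care and
#'   lifts continuity indices at the cost of sparser sharing.
#' @param practice_intercept_sd standard deviation (logit scale) of the
#'   per-practice, per-measure Gaussian random intercept.
#' @param outcome_base_rates named baseline probabilities for the binary
#'   measures in the reference (PCP-only) team at covariate means.
#' @param team_type_log_odds measures x 4 matrix of additive log-odds by team
#'   type (columns `PCP`, `PCP_NP`, `PCP_NP_PA`, `PCP_PA`; reference column
#'   must be 0). Row names must match `names(outcome_base_rates)`.
#' @param covariate_log_odds log-odds per unit for `age10` (age minus 75,
#'   decades), `male`, and `dual` applied to every binary measure.
#' @param visit_count_mean expected primary-care office visits per patient per
#'   calendar year (before the within/cross/specialist split).
#' @param rx_fill_model list describing antidiabetic refill behaviour:
#'   `any_fill_prob`, `first_fill_day_max`, `days_supply` (named probability
#'   vector over day counts), `gap` (named probability vector over days
#'   between exhaustion and the next fill; negative = overlapping early fill).
#' @param eligibility_rates named probabilities steering the cohort cascade:
#'   `enrollment_complete`, `medicare_advantage`, `alive`, `under66`, `ltc`,
#'   `snf_billed_ltc_code`, `unknown_rurality`.
#' @param comorbidity_prevalence named prevalences for binary comorbidity
#'   flags.
#' @param diagnosed_in_measure_year_rate share of patients whose diabetes
#'   diagnosis date falls inside the measure year (exercises PDC denominator
#'   truncation).
#' @param seed master seed; per-table child seeds are derived from it by fixed
#'   offsets (see [derive_seed()]).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(
    n_service_areas = 10,
    practices_per_area = 10,
    practice_size_range = c(3L, 8L),
    team_type_mix = c(PCP = 0.40, PCP_NP = 0.33, PCP_NP_PA = 0.12, PCP_PA = 0.15),
    patients_per_practice = 60,
    within_practice_share_rate = 0.92,
    cross_practice_share_rate = 0.02,
    usual_provider_weight = 0,
    practice_intercept_sd = 0.5,
    outcome_base_rates = c(eye_exam = 0.65, hba1c_test = 0.91,
                           nephropathy_monitoring = 0.87,
                           statin_use = 0.73, ace_arb_use = 0.75,
                           high_risk_med_use = 0.20,
                           any_ed_visit = 0.37, any_preventable_hosp = 0.05),
    team_type_log_odds = default_team_effects(),
    covariate_log_odds = c(age10 = -0.10, male = 0.05, dual = -0.15),
    visit_count_mean = 12,
    rx_fill_model = list(
      any_fill_prob = 0.75,
      first_fill_day_max = 15,
      days_supply = c("30" = 0.4, "90" = 0.6),
      gap = c("-7" = 0.15, "0" = 0.30, "14" = 0.25, "30" = 0.15, "60" = 0.15)),
    eligibility_rates = c(enrollment_complete = 0.96, medicare_advantage = 0.02,
                          alive = 0.97, under66 = 0.02, ltc = 0.02,
                          snf_billed_ltc_code = 0.01, unknown_rurality = 0.01),
    comorbidity_prevalence = c(hypertension = 0.87, hyperlipidemia = 0.77,
                               ischemic_heart_disease = 0.43,
                               chronic_kidney_disease = 0.35,
                               copd = 0.15, depression = 0.17),
    diagnosed_in_measure_year_rate = 0.10,
    seed = 1L) {
  cfg <- list(
    n_service_areas = n_service_areas,
    practices_per_area = practices_per_area,
    practice_size_range = as.integer(practice_size_range),
    team_type_mix = team_type_mix,
    patients_per_practice = patients_per_practice,
    within_practice_share_rate = within_practice_share_rate,
    cross_practice_share_rate = cross_practice_share_rate,
    usual_provider_weight = usual_provider_weight,
    practice_intercept_sd = practice_intercept_sd,
    outcome_base_rates = outcome_base_rates,
    team_type_log_odds = team_type_log_odds,
    covariate_log_odds = covariate_log_odds,
    visit_count_mean = visit_count_mean,
    rx_fill_model = rx_fill_model,
    eligibility_rates = eligibility_rates,
    comorbidity_prevalence = comorbidity_prevalence,
    diagnosed_in_measure_year_rate = diagnosed_in_measure_year_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

TEAM_TYPES <- c("PCP", "PCP_NP", "PCP_NP_PA", "PCP_PA")

#' Default team-type effects on the binary care measures
#'
#' Log odds ratios by team composition (reference: PCP-only), one row per
#' measure. The default magnitudes mirror the adjusted odds ratios typically
#' reported for team-based diabetes care: slightly better guideline adherence
#' and slightly more high-risk prescribing in teams with NPs or PAs, near-null
#' utilization differences.
#'
#' @return An 8 x 4 numeric matrix with measure row names and team-type
#'   column names.
#' @export
default_team_effects <- function() {
  or <- rbind(
    eye_exam               = c(1, 1.04, 1.08, 1.10),
    hba1c_test             = c(1, 1.11, 1.11, 1.15),
    nephropathy_monitoring = c(1, 1.03, 1.17, 1.13),
    statin_use             = c(1, 0.96, 1.01, 0.99),
    ace_arb_use            = c(1, 0.99, 1.01, 1.03),
    high_risk_med_use      = c(1, 1.03, 1.00, 1.06),
    any_ed_visit           = c(1, 1.02, 1.06, 0.98),
    any_preventable_hosp   = c(1, 0.98, 1.00, 0.96))
  colnames(or) <- TEAM_TYPES
  log(or)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop("invalid configuration: '", field, "' must be a positive integer",
           call. = FALSE)
  }
  chk_rate <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("invalid configuration: '", field, "' must lie in [0, 1]",
           call. = FALSE)
  }
  chk_count(cfg$n_service_areas, "n_service_areas")
  chk_count(cfg$practices_per_area, "practices_per_area")
  chk_count(cfg$patients_per_practice, "patients_per_practice")
  if (length(cfg$practice_size_range) != 2 ||
      cfg$practice_size_range[1] > cfg$practice_size_range[2] ||
      cfg$practice_size_range[1] < 1)
    stop("invalid configuration: 'practice_size_range' must be c(min, max) ",
         "with 1 <= min <= max", call. = FALSE)
  if (!identical(names(cfg$team_type_mix), TEAM_TYPES) ||
      abs(sum(cfg$team_type_mix) - 1) > 1e-8 || any(cfg$team_type_mix < 0))
    stop("invalid configuration: 'team_type_mix' must be non-negative ",
         "proportions over ", paste(TEAM_TYPES, collapse = ", "),
         " summing to 1", call. = FALSE)
  chk_rate(cfg$within_practice_share_rate, "within_practice_share_rate")
  chk_rate(cfg$cross_practice_share_rate, "cross_practice_share_rate")
  if (cfg$within_practice_share_rate + cfg$cross_practice_share_rate > 1)
    stop("invalid configuration: 'within_practice_share_rate' + ",
         "'cross_practice_share_rate' must not exceed 1", call. = FALSE)
  chk_rate(cfg$usual_provider_weight, "usual_provider_weight")
  if (cfg$practice_intercept_sd < 0)
    stop("invalid configuration: 'practice_intercept_sd' must be >= 0",
         call. = FALSE)
  chk_rate(cfg$outcome_base_rates, "outcome_base_rates")
  tlo <- cfg$team_type_log_odds
  if (!is.matrix(tlo) || !identical(colnames(tlo), TEAM_TYPES) ||
      !setequal(rownames(tlo), names(cfg$outcome_base_rates)))
    stop("invalid configuration: 'team_type_log_odds' must be a matrix with ",
         "columns ", paste(TEAM_TYPES, collapse = ", "), " and one row per ",
         "entry of 'outcome_base_rates'", call. = FALSE)
  if (cfg$visit_count_mean < 0)
    stop("invalid configuration: 'visit_count_mean' must be >= 0",
         call. = FALSE)
  chk_rate(cfg$eligibility_rates, "eligibility_rates")
  chk_rate(cfg$comorbidity_prevalence, "comorbidity_prevalence")
  chk_rate(cfg$diagnosed_in_measure_year_rate, "diagnosed_in_measure_year_rate")
  rx <- cfg$rx_fill_model
  chk_rate(rx$any_fill_prob, "rx_fill_model$any_fill_prob")
  for (f in c("days_supply", "gap")) {
    if (abs(sum(rx[[f]]) - 1) > 1e-8 || any(rx[[f]] < 0))
      stop("invalid configuration: 'rx_fill_model$", f,
           "' must be a probability vector summing to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Derive a child seed from the master seed
#'
#' Each table of the bundle is generated under its own child seed so that the
#' bundle is reproducible table-by-table. Offsets are fixed constants.
#'
#' @param seed master seed (integer).
#' @param offset fixed stage offset (integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + as.double(offset) * 9973) %% 2147483629)
}

MEASURE_YEAR_START <- as.Date("2015-01-01")
MEASURE_YEAR_END <- as.Date("2015-12-31")
WINDOW_START <- as.Date("2014-01-01")

# uniform draw of one member per row from ragged groups, vectorised via a
# flat member vector + per-group offsets
draw_member <- function(group_idx, offsets, sizes, flat) {
  pick <- offsets[group_idx] +
    floor(runif(length(group_idx)) * sizes[group_idx])
  flat[pick + 1L]
}

#' Generate a synthetic claims bundle with known ground truth
#'
#' Produces beneficiary, provider, office-visit, prescription and
#' facility-stay tables for a two-year window, together with truth tables
#' recording the planted practice memberships, team types, random intercepts
#' and the drawn patient-level measure outcomes. Identical configurations
#' (including seed) give identical bundles.
#'
#' @param config a [sim_config()].
#' @param codesets a [codeset_config()] supplying the procedure/revenue codes
#'   the emitted claims draw from.
#' @return An object of class `claims_bundle`: a list with elements
#'   `beneficiaries`, `providers`, `visits`, `prescriptions`,
#'   `facility_stays`, `truth` (itself a list of `provider_practice`,
#'   `practices`, `patient_outcomes`, `params`) and `config`.
#' @export
simulate_claims <- function(config, codesets = codeset_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config

  ## ---- practices and providers -------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  n_prac <- cfg$n_service_areas * cfg$practices_per_area
  prac <- data.frame(
    practice_id = sprintf("A%02d_P%02d",
                          rep(seq_len(cfg$n_service_areas),
                              each = cfg$practices_per_area),
                          rep(seq_len(cfg$practices_per_area),
                              cfg$n_service_areas)),
    area_id = sprintf("A%02d", rep(seq_len(cfg$n_service_areas),
                                   each = cfg$practices_per_area)),
    stringsAsFactors = FALSE)
  prac$team_type <- sample(TEAM_TYPES, n_prac, replace = TRUE,
                           prob = cfg$team_type_mix)
  lo <- cfg$practice_size_range[1]; hi <- cfg$practice_size_range[2]
  prac$n_providers <- sample(seq(lo, hi), n_prac, replace = TRUE)
  # mixed teams need room for every role present
  need <- c(PCP = 1L, PCP_NP = 2L, PCP_NP_PA = 3L, PCP_PA = 2L)[prac$team_type]
  prac$n_providers <- pmax(prac$n_providers, need)

  specialties <- vector("list", n_prac)
  for (i in seq_len(n_prac)) {
    s <- prac$n_providers[i]
    tt <- prac$team_type[i]
    n_np <- if (tt %in% c("PCP_NP", "PCP_NP_PA")) max(1L, rbinom(1, s - 2L, 0.25)) else 0L
    n_pa <- if (tt %in% c("PCP_PA", "PCP_NP_PA")) max(1L, rbinom(1, s - 1L - n_np, 0.25)) else 0L
    n_pcp <- s - n_np - n_pa
    specialties[[i]] <- c(sample(PCP_SPECIALTIES, n_pcp, replace = TRUE,
                                 prob = c(0.08, 0.47, 0.40, 0.05)),
                          rep(NP_SPECIALTY, n_np), rep(PA_SPECIALTY, n_pa))
  }
  providers <- data.frame(
    provider_id = sprintf("PR%05d", seq_len(sum(prac$n_providers))),
    practice_id = rep(prac$practice_id, prac$n_providers),
    area_id = rep(prac$area_id, prac$n_providers),
    specialty_code = unlist(specialties),
    stringsAsFactors = FALSE)
  providers$primary_care_taxonomy <-
    providers$specialty_code %in% c(NP_SPECIALTY, PA_SPECIALTY)

  # area-level specialists (2 each of cardiology 06, nephrology 39,
  # endocrinology 46) and misc billers (eye/lab claims), outside any practice
  areas <- unique(prac$area_id)
  spec_codes <- rep(unname(SPECIALIST_SPECIALTIES), each = 2)
  specials <- data.frame(
    provider_id = sprintf("SP%05d", seq_len(length(areas) * length(spec_codes))),
    practice_id = NA_character_,
    area_id = rep(areas, each = length(spec_codes)),
    specialty_code = rep(spec_codes, length(areas)),
    primary_care_taxonomy = FALSE,
    stringsAsFactors = FALSE)
  misc <- data.frame(
    provider_id = sprintf("MS%05d", seq_len(2 * length(areas))),
    practice_id = NA_character_,
    area_id = rep(areas, each = 2),
    specialty_code = "other",
    primary_care_taxonomy = FALSE,
    stringsAsFactors = FALSE)
  providers <- rbind(providers, specials, misc)

  ## ---- beneficiaries ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  n_pat <- n_prac * cfg$patients_per_practice
  el <- cfg$eligibility_rates
  age <- qnorm(runif(n_pat, pnorm(66, 75.1, 6.7), pnorm(102, 75.1, 6.7)),
               75.1, 6.7)
  young <- runif(n_pat) < el[["under66"]]
  age[young] <- runif(sum(young), 65, 66)
  rural_lv <- c("metropolitan", "urban", "rural")
  rurality <- sample(rural_lv, n_pat, replace = TRUE, prob = c(0.82, 0.16, 0.02))
  rurality[runif(n_pat) < el[["unknown_rurality"]]] <- "unknown"
  dx_in_year <- runif(n_pat) < cfg$diagnosed_in_measure_year_rate
  dx_date <- WINDOW_START - sample.int(3650L, n_pat, replace = TRUE)
  dx_date[dx_in_year] <- MEASURE_YEAR_START +
    (sample.int(360L, sum(dx_in_year), replace = TRUE) - 1L)
  ben <- data.frame(
    patient_id = sprintf("PT%06d", seq_len(n_pat)),
    home_practice_id = rep(prac$practice_id, each = cfg$patients_per_practice),
    area_id = rep(prac$area_id, each = cfg$patients_per_practice),
    birth_date = as.Date(round(as.numeric(MEASURE_YEAR_START) - age * 365.25),
                         origin = "1970-01-01"),
    sex = sample(c("male", "female"), n_pat, replace = TRUE,
                 prob = c(0.445, 0.555)),
    race_ethnicity = sample(c("nh_white", "black", "hispanic", "other"),
                            n_pat, replace = TRUE,
                            prob = c(0.80, 0.09, 0.06, 0.05)),
    dual_eligible = runif(n_pat) < 0.19,
    rurality = rurality,
    enrollment_complete_2014_2015 = runif(n_pat) < el[["enrollment_complete"]],
    medicare_advantage = runif(n_pat) < el[["medicare_advantage"]],
    alive_through_2015 = runif(n_pat) < el[["alive"]],
    diabetes_diagnosis_date = dx_date,
    dm_category = sample(c("controlled_no_compl", "controlled_compl",
                           "uncontrolled_no_compl", "uncontrolled_compl"),
                         n_pat, replace = TRUE,
                         prob = c(0.42, 0.26, 0.11, 0.21)),
    stringsAsFactors = FALSE)
  for (cm in names(cfg$comorbidity_prevalence))
    ben[[cm]] <- runif(n_pat) < cfg$comorbidity_prevalence[[cm]]
  ltc_flag <- runif(n_pat) < el[["ltc"]]
  snf_only_flag <- !ltc_flag & runif(n_pat) < el[["snf_billed_ltc_code"]]

  ## ---- office visits ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  # flat member vectors for vectorised uniform provider draws
  pc_prov <- providers[!is.na(providers$practice_id), ]
  memb <- split(pc_prov$provider_id, pc_prov$practice_id)
  memb <- memb[prac$practice_id]
  m_sizes <- lengths(memb)
  m_off <- cumsum(c(0L, m_sizes[-length(m_sizes)]))
  m_flat <- unlist(memb, use.names = FALSE)
  names(m_sizes) <- names(m_off) <- prac$practice_id
  sp_by_area <- split(specials$provider_id, specials$area_id)
  sp_sizes <- lengths(sp_by_area)
  sp_off <- cumsum(c(0L, sp_sizes[-length(sp_sizes)]))
  sp_flat <- unlist(sp_by_area, use.names = FALSE)
  names(sp_sizes) <- names(sp_off) <- names(sp_by_area)

  home_idx <- match(ben$home_practice_id, prac$practice_id)
  usual <- draw_member(home_idx, m_off, m_sizes, m_flat)

  visit_rows <- vector("list", 2)
  for (yr in 1:2) {
    year_start <- if (yr == 1) WINDOW_START else MEASURE_YEAR_START
    nv <- rpois(n_pat, cfg$visit_count_mean)
    pat_i <- rep(seq_len(n_pat), nv)
    total <- length(pat_i)
    u <- runif(total)
    w <- cfg$within_practice_share_rate
    cr <- cfg$cross_practice_share_rate
    kind <- ifelse(u < w, "within", ifelse(u < w + cr, "cross", "specialist"))
    prov <- character(total)

    iw <- kind == "within"
    pw <- draw_member(home_idx[pat_i[iw]], m_off, m_sizes, m_flat)
    use_usual <- runif(sum(iw)) < cfg$usual_provider_weight
    pw[use_usual] <- usual[pat_i[iw][use_usual]]
    prov[iw] <- pw

    ic <- kind == "cross"
    if (any(ic)) {
      # uniform foreign practice in the same area
      hp <- home_idx[pat_i[ic]]
      within_rank <- (hp - 1L) %% cfg$practices_per_area + 1L
      area0 <- hp - within_rank            # index of area block start - 1
      r <- sample.int(cfg$practices_per_area - 1L, sum(ic), replace = TRUE)
      foreign <- area0 + r + (r >= within_rank)
      prov[ic] <- draw_member(foreign, m_off, m_sizes, m_flat)
    }

    is <- kind == "specialist"
    if (any(is)) {
      ai <- match(ben$area_id[pat_i[is]], names(sp_sizes))
      prov[is] <- draw_member(ai, sp_off, sp_sizes, sp_flat)
    }

    cpt <- sample(codesets$office_visit_cpt, total, replace = TRUE)
    consult <- is & runif(total) < 0.3
    cpt[consult] <- sample(setdiff(codesets$specialist_visit_cpt,
                                   codesets$office_visit_cpt),
                           sum(consult), replace = TRUE)
    visit_rows[[yr]] <- data.frame(
      patient_id = ben$patient_id[pat_i],
      provider_id = prov,
      service_date = year_start + (sample.int(365L, total, replace = TRUE) - 1L),
      cpt_code = cpt,
      setting = "office",
      snf_biller = FALSE,
      stringsAsFactors = FALSE)
  }
  visits <- rbind(visit_rows[[1]], visit_rows[[2]])

  # long-term-care nursing facility claims; a separate slice is billed by
  # skilled nursing facilities and must NOT trigger the LTC exclusion
  ltc_i <- which(ltc_flag)
  snf_i <- which(snf_only_flag)
  if (length(c(ltc_i, snf_i)) > 0) {
    nfr <- data.frame(
      patient_id = ben$patient_id[c(ltc_i, snf_i)],
      provider_id = usual[c(ltc_i, snf_i)],
      service_date = MEASURE_YEAR_START +
        (sample.int(365L, length(ltc_i) + length(snf_i), replace = TRUE) - 1L),
      cpt_code = sample(codesets$nursing_facility_cpt,
                        length(ltc_i) + length(snf_i), replace = TRUE),
      setting = "facility-outpatient",
      snf_biller = rep(c(FALSE, TRUE), c(length(ltc_i), length(snf_i))),
      stringsAsFactors = FALSE)
    visits <- rbind(visits, nfr)
  }

  ## ---- latent measure outcomes -------------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  measures <- names(cfg$outcome_base_rates)
  b <- matrix(rnorm(n_prac * length(measures), 0, cfg$practice_intercept_sd),
              n_prac, length(measures),
              dimnames = list(prac$practice_id, measures))
  cx <- cbind(age10 = (age - 75) / 10,
              male = as.numeric(ben$sex == "male"),
              dual = as.numeric(ben$dual_eligible))
  xb_cov <- drop(cx %*% cfg$covariate_log_odds[colnames(cx)])
  team_i <- match(prac$team_type[home_idx], TEAM_TYPES)
  y <- matrix(FALSE, n_pat, length(measures), dimnames = list(NULL, measures))
  for (m in measures) {
    eta <- qlogis(cfg$outcome_base_rates[[m]]) +
      cfg$team_type_log_odds[m, team_i] + b[home_idx, m] + xb_cov
    y[, m] <- runif(n_pat) < plogis(eta)
  }

  ## ---- claims realising the process-of-care outcomes ----------------------
  set.seed(derive_seed(cfg$seed, 5L))
  misc_by_area <- split(misc$provider_id, misc$area_id)
  misc1 <- vapply(misc_by_area, `[`, character(1), 1L)
  emit_claims <- function(which_pat, codes) {
    n <- length(which_pat)
    if (n == 0) return(NULL)
    prov <- misc1[ben$area_id[which_pat]]
    data.frame(
      patient_id = ben$patient_id[which_pat],
      provider_id = unname(prov),
      service_date = MEASURE_YEAR_START +
        (sample.int(365L, n, replace = TRUE) - 1L),
      cpt_code = sample(codes, n, replace = TRUE),
      setting = "office",
      snf_biller = FALSE,
      stringsAsFactors = FALSE)
  }
  visits <- rbind(visits,
                  emit_claims(which(y[, "eye_exam"]), codesets$eye_exam_codes),
                  emit_claims(which(y[, "hba1c_test"]), codesets$hba1c_codes),
                  emit_claims(which(y[, "nephropathy_monitoring"]),
                              codesets$nephropathy_codes))
  visits <- visits[order(visits$patient_id, visits$service_date,
                         visits$provider_id, visits$cpt_code), ]
  rownames(visits) <- NULL

  ## ---- prescriptions ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  rx <- cfg$rx_fill_model
  supply_vals <- as.integer(names(rx$days_supply))
  gap_vals <- as.integer(names(rx$gap))
  any_fill <- runif(n_pat) < rx$any_fill_prob
  fills <- vector("list", n_pat)
  year_len <- as.integer(MEASURE_YEAR_END - MEASURE_YEAR_START) + 1L
  for (i in which(any_fill)) {
    start_floor <- if (dx_in_year[i])
      as.integer(ben$diabetes_diagnosis_date[i] - MEASURE_YEAR_START) + 1L
    else 1L
    d <- start_floor + sample.int(rx$first_fill_day_max, 1L) - 1L
    day <- integer(0); sup <- integer(0)
    while (d <= year_len) {
      s <- sample(supply_vals, 1L, prob = rx$days_supply)
      day <- c(day, d); sup <- c(sup, s)
      d <- d + s + sample(gap_vals, 1L, prob = rx$gap)
    }
    if (length(day) > 0)
      fills[[i]] <- data.frame(patient_id = ben$patient_id[i],
                               drug_class = "antidiabetic",
                               fill_date = MEASURE_YEAR_START + day - 1L,
                               days_supply = sup, stringsAsFactors = FALSE)
  }
  one_off <- function(which_pat, class, max_fills = 3L) {
    n <- length(which_pat)
    if (n == 0) return(NULL)
    k <- sample.int(max_fills, n, replace = TRUE)
    idx <- rep(which_pat, k)
    data.frame(patient_id = ben$patient_id[idx],
               drug_class = class,
               fill_date = MEASURE_YEAR_START +
                 (sample.int(330L, length(idx), replace = TRUE) - 1L),
               days_supply = sample(c(30L, 90L), length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  prescriptions <- rbind(
    do.call(rbind, fills[!vapply(fills, is.null, logical(1))]),
    one_off(which(y[, "statin_use"]), "statin"),
    one_off(which(y[, "ace_arb_use"]), "ace_arb"),
    one_off(which(y[, "high_risk_med_use"]), "high_risk", 1L))
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$fill_date,
                                       prescriptions$drug_class), ]
  rownames(prescriptions) <- NULL

  ## ---- facility stays -----------------------------------------------------
  set.seed(derive_seed(cfg$seed, 7L))
  mk_stays <- function(which_pat, stay_type, ed_charge, revenue, dx) {
    n <- length(which_pat)
    if (n == 0) return(NULL)
    data.frame(patient_id = ben$patient_id[which_pat],
               admit_date = MEASURE_YEAR_START +
                 (sample.int(365L, n, replace = TRUE) - 1L),
               stay_type = stay_type,
               ed_charge = ed_charge,
               revenue_codes = revenue,
               diagnosis_codes = dx,
               stringsAsFactors = FALSE)
  }
  ed_pat <- which(y[, "any_ed_visit"])
  ed_inpat <- ed_pat[runif(length(ed_pat)) < 0.5]
  ed_outpat <- setdiff(ed_pat, ed_inpat)
  bg <- which(runif(n_pat) < 0.10)   # background non-ED outpatient claims
  facility_stays <- rbind(
    mk_stays(ed_inpat, "inpatient",
             round(runif(length(ed_inpat), 200, 3000), 2), "",
             "I10"),
    mk_stays(ed_outpat, "outpatient", 0,
             sample(codesets$ed_revenue_codes, length(ed_outpat),
                    replace = TRUE),
             ""),
    mk_stays(which(y[, "any_preventable_hosp"]), "inpatient", 0,
             "",
             sample(codesets$preventable_hosp_dx_codes,
                    sum(y[, "any_preventable_hosp"]), replace = TRUE)),
    mk_stays(bg, "outpatient", 0, "0360", ""))
  facility_stays <- facility_stays[order(facility_stays$patient_id,
                                         facility_stays$admit_date,
                                         facility_stays$stay_type,
                                         facility_stays$revenue_codes), ]
  rownames(facility_stays) <- NULL

  ## ---- truth --------------------------------------------------------------
  truth <- list(
    provider_practice = data.frame(
      provider_id = providers$provider_id,
      true_practice_id = providers$practice_id,
      area_id = providers$area_id,
      stringsAsFactors = FALSE),
    practices = cbind(
      data.frame(practice_id = prac$practice_id, area_id = prac$area_id,
                 true_team_type = prac$team_type,
                 n_providers = prac$n_providers, stringsAsFactors = FALSE),
      as.data.frame(b)),
    patient_outcomes = cbind(
      data.frame(patient_id = ben$patient_id,
                 home_practice_id = ben$home_practice_id,
                 stringsAsFactors = FALSE),
      as.data.frame(y)),
    params = list(outcome_base_rates = cfg$outcome_base_rates,
                  team_type_log_odds = cfg$team_type_log_odds,
                  covariate_log_odds = cfg$covariate_log_odds,
                  practice_intercept_sd = cfg$practice_intercept_sd))

  bundle <- list(beneficiaries = ben, providers = providers, visits = visits,
                 prescriptions = prescriptions,
                 facility_stays = facility_stays, truth = truth,
                 config = cfg)
  class(bundle) <- "claims_bundle"
  bundle
}

#' True provider-to-practice partition of a bundle
#'
#' @param bundle a `claims_bundle`.
#' @return Named character vector mapping each practice-affiliated provider to
#'   its true practice id (area specialists and miscellaneous billers, which
#'   belong to no practice, are omitted).
#' @export
truth_partition <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  tp <- bundle$truth$provider_practice
  tp <- tp[!is.na(tp$true_practice_id), ]
  stats::setNames(tp$true_practice_id, tp$provider_id)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Synthetic claims bundle\n")
  cat(sprintf("  beneficiaries : %d\n", nrow(x$beneficiaries)))
  cat(sprintf("  providers     : %d (%d practice-affiliated)\n",
              nrow(x$providers), sum(!is.na(x$providers$practice_id))))
  cat(sprintf("  visits        : %d\n", nrow(x$visits)))
  cat(sprintf("  prescriptions : %d\n", nrow(x$prescriptions)))
  cat(sprintf("  facility stays: %d\n", nrow(x$facility_stays)))
  cat(sprintf("  practices     : %d in %d areas, seed %d\n",
              nrow(x$truth$practices),
              length(unique(x$truth$practices$area_id)), x$config$seed))
  invisible(x)
}

#' Write a claims bundle to a directory of CSV files
#'
#' One CSV per table plus `manifest.json` recording the configuration and
#' seed. Dates are written as ISO strings.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("beneficiaries", "providers", "visits", "prescriptions",
            "facility_stays")
  for (tb in tabs)
    utils::write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  utils::write.csv(bundle$truth$provider_practice,
                   file.path(dir, "truth_provider_practice.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth$practices,
                   file.path(dir, "truth_practices.csv"), row.names = FALSE)
  utils::write.csv(bundle$truth$patient_outcomes,
                   file.path(dir, "truth_patient_outcomes.csv"),
                   row.names = FALSE)
  cfg <- bundle$config
  cfg$team_type_log_odds <- as.data.frame(cfg$team_type_log_odds)
  jsonlite::write_json(list(package = "pcteams", config = unclass(cfg)),
                       file.path(dir, "manifest.json"),
                       pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a claims bundle back from a directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return A `claims_bundle` (the `config` element is the manifest's config
#'   as a plain list).
#' @export
read_bundle <- function(dir) {
  rd <- function(f, datecols = character(0)) {
    x <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    for (dc in intersect(datecols, names(x))) x[[dc]] <- as.Date(x[[dc]])
    x
  }
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(cpt_code = "character"))
  visits$service_date <- as.Date(visits$service_date)
  fs <- utils::read.csv(file.path(dir, "facility_stays.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(revenue_codes = "character",
                                       diagnosis_codes = "character"))
  fs$admit_date <- as.Date(fs$admit_date)
  fs$revenue_codes[is.na(fs$revenue_codes)] <- ""
  fs$diagnosis_codes[is.na(fs$diagnosis_codes)] <- ""
  prov <- utils::read.csv(file.path(dir, "providers.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(specialty_code = "character"))
  bundle <- list(
    beneficiaries = rd("beneficiaries.csv",
                       c("birth_date", "diabetes_diagnosis_date")),
    providers = prov,
    visits = visits,
    prescriptions = rd("prescriptions.csv", "fill_date"),
    facility_stays = fs,
    truth = list(
      provider_practice = rd("truth_provider_practice.csv"),
      practices = rd("truth_practices.csv"),
      patient_outcomes = rd("truth_patient_outcomes.csv")),
    config = jsonlite::read_json(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)$config)
  class(bundle) <- "claims_bundle"
  bundle
}
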