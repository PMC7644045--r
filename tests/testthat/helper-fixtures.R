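# Hand-built fixtures shared by the cohort tests and the acceptance suite.

# a practice_set with two included 2-provider practices
make_practice_fixture <- function() {
  practices <- data.frame(
    practice_id = c("X", "Y"), area_id = c("A1", "A1"),
    n_providers = c(2L, 2L), team_type = c("PCP", "PCP_NP"),
    modularity = c(0.5, 0.5), n_attributed = NA_integer_,
    included = TRUE, exclusion_reason = "none",
    stringsAsFactors = FALSE)
  membership <- data.frame(
    provider_id = c("X1", "X2", "Y1", "Y2"),
    practice_id = c("X", "X", "Y", "Y"), stringsAsFactors = FALSE)
  ps <- list(practices = practices, membership = membership)
  class(ps) <- "practice_set"
  ps
}

# 12 patients: 4 clean + one patient per exclusion reason of the cascade
make_cohort_fixture <- function() {
  ps <- make_practice_fixture()
  d <- function(x) as.Date(x)
  visit <- function(pat, prov, date, cpt = "99213", snf = FALSE)
    data.frame(patient_id = pat, provider_id = prov, service_date = d(date),
               cpt_code = cpt, setting = "office", snf_biller = snf,
               stringsAsFactors = FALSE)
  two_visits <- function(pat, prov = "X1")
    rbind(visit(pat, prov, "2015-02-01"), visit(pat, prov, "2015-08-01"))
  visits <- rbind(
    two_visits("p01"), two_visits("p02"), two_visits("p03", "Y1"),
    two_visits("p04"),
    # SNF-billed nursing-facility code must NOT exclude p04
    visit("p04", "X2", "2015-05-01", cpt = "99306", snf = TRUE),
    visit("p05", "X1", "2015-03-01"),                     # one visit only
    two_visits("p06", "X1"), two_visits("p06", "Y2"),     # two practices
    two_visits("p07"), two_visits("p08"), two_visits("p09"),
    two_visits("p10"), two_visits("p11"), two_visits("p12"),
    visit("p11", "X2", "2015-06-01", cpt = "99306"))      # LTC, non-SNF

  n <- 12
  ben <- data.frame(
    patient_id = sprintf("p%02d", 1:n),
    birth_date = d(rep("1945-07-15", n)),
    sex = rep(c("female", "male"), 6),
    race_ethnicity = "nh_white",
    dual_eligible = FALSE,
    rurality = "metropolitan",
    enrollment_complete_2014_2015 = TRUE,
    medicare_advantage = FALSE,
    alive_through_2015 = TRUE,
    diabetes_diagnosis_date = d("2010-01-01"),
    dm_category = "controlled_no_compl",
    stringsAsFactors = FALSE)
  ben$birth_date[ben$patient_id == "p01"] <- d("1949-01-01")  # exactly 66
  ben$enrollment_complete_2014_2015[ben$patient_id == "p07"] <- FALSE
  ben$medicare_advantage[ben$patient_id == "p08"] <- TRUE
  ben$alive_through_2015[ben$patient_id == "p09"] <- FALSE
  ben$birth_date[ben$patient_id == "p10"] <- d("1949-06-01")  # 65 on index
  ben$rurality[ben$patient_id == "p12"] <- "unknown"

  list(visits = visits, beneficiaries = ben, practice_set = ps)
}

# small, fast simulation configuration for structural tests
small_config <- function(seed = 42, ...) {
  sim_config(n_service_areas = 2, practices_per_area = 4,
             patients_per_practice = 40, seed = seed, ...)
}
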