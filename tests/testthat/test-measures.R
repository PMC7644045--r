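test_that("MCI worked examples evaluate exactly", {
  expect_equal(continuity_index(rep("a", 10)), 1.0)
  expect_equal(continuity_index(paste0("p", 1:10)), (0.1 / 10.1) / (9.1 / 10.1))
  expect_equal(continuity_index(paste0("p", 1:10)), 0.1 / 9.1)
  expect_equal(continuity_index(c("a", "a", "b", "b")), 2.1 / 3.1)
  expect_equal(continuity_index("a"), 1)           # single visit convention
  expect_true(is.na(continuity_index(character(0))))
})

test_that("MCI matches the closed-form oracle over random (k, N) and is order-invariant", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    k <- sample(1:n, 1)
    # a sequence with exactly k distinct providers over n visits
    seq <- c(paste0("d", 1:k), sample(paste0("d", 1:k), n - k, replace = TRUE))
    got <- continuity_index(seq)
    expected <- if (n == 1) 1 else (1 - k / (n + 0.1)) / (1 - 1 / (n + 0.1))
    expect_equal(got, expected)
    expect_equal(continuity_index(sample(seq)), got)   # order invariance
    expect_true(got > 0 && got <= 1)
  }
})

test_that("MCI is 1 at k = 1 and strictly decreasing in k at fixed N", {
  for (n in c(2, 5, 17)) {
    expect_equal(mmci(n, 1), 1)
    vals <- vapply(seq_len(n), function(k) mmci(n, k), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # unnormalised variant keeps the raw form
  expect_equal(mmci(10, 2, normalized = FALSE), 1 - 2 / 10.1)
})

test_that("PDC worked examples evaluate exactly", {
  ws <- as.Date("2015-01-01"); we <- as.Date("2015-12-31")
  f1 <- data.frame(fill_date = as.Date(c("2015-01-01", "2015-07-01")),
                   days_supply = c(90L, 90L))
  expect_equal(pdc(f1, ws, we), 180 / 365)
  f2 <- data.frame(fill_date = ws + c(0, 59), days_supply = c(90L, 90L))
  expect_equal(pdc(f2, ws, we), 149 / 365)
  # diagnosed mid-window: denominator runs July 1 - Dec 31
  f3 <- data.frame(fill_date = as.Date("2015-07-01"), days_supply = 92L)
  expect_equal(pdc(f3, ws, we, diagnosis_date = as.Date("2015-07-01")),
               92 / 184)
  # empty eligible window is undefined
  expect_true(is.na(pdc(f1, ws, we, diagnosis_date = as.Date("2016-02-01"))))
  expect_equal(pdc(f1[0, ], ws, we), 0)
})

test_that("PDC equals the day-by-day oracle on randomized fill sets", {
  set.seed(77)
  ws <- as.Date("2015-01-01"); we <- as.Date("2015-12-31")
  for (i in 1:300) {
    nf <- sample(0:8, 1)
    fills <- data.frame(
      fill_date = ws + sample(-20:380, nf, replace = TRUE),
      days_supply = sample(c(7L, 28L, 30L, 60L, 90L), nf, replace = TRUE))
    dx <- if (runif(1) < 0.4) ws + sample(0:364, 1) else NULL
    expect_equal(pdc(fills, ws, we, dx), oracle_pdc(fills, ws, we, dx),
                 info = paste("case", i))
  }
})

test_that("measure panel nesting and flag semantics hold on simulated data", {
  b <- simulate_claims(small_config(seed = 13))
  parts <- identify_practices(b$visits, b$providers)
  ps <- gate_and_assign(parts, b$providers)
  built <- build_cohort(b$visits, ps, b$beneficiaries)
  panel <- build_measure_panel(built$cohort, b$visits, b$prescriptions,
                               b$facility_stays, b$providers,
                               built$practice_set)
  expect_true(all(panel$visits_own_practice <= panel$visits_any_pcp))
  expect_true(all(panel$visits_any_pcp <= panel$visits_any_provider))
  has <- !is.na(panel$mci_any_provider)
  expect_true(all(panel$visits_any_provider[has] >= 1))
  expect_true(all(is.na(panel$mci_own_practice[panel$visits_own_practice == 0])))
  expect_true(all(panel$pdc_antidiabetic >= 0 & panel$pdc_antidiabetic <= 1,
                  na.rm = TRUE))
})

test_that("panel flags reproduce the planted outcome draws end to end", {
  b <- simulate_claims(small_config(seed = 19))
  parts <- identify_practices(b$visits, b$providers)
  ps <- gate_and_assign(parts, b$providers)
  built <- build_cohort(b$visits, ps, b$beneficiaries)
  panel <- build_measure_panel(built$cohort, b$visits, b$prescriptions,
                               b$facility_stays, b$providers,
                               built$practice_set)
  truth <- b$truth$patient_outcomes
  m <- merge(panel, truth, by = "patient_id")
  expect_gt(nrow(m), 100)
  expect_equal(m$eye_exam.x, m$eye_exam.y)
  expect_equal(m$hba1c_test.x, m$hba1c_test.y)
  expect_equal(m$statin_use.x, m$statin_use.y)
  expect_equal(m$high_risk_med_use.x, m$high_risk_med_use.y)
  expect_equal(m$any_ed_visit.x, m$any_ed_visit.y)
  expect_equal(m$any_preventable_hosp.x, m$any_preventable_hosp.y)
})

test_that("specialist contact requires a specialist code on a qualifying visit", {
  prov <- data.frame(provider_id = c("CARD", "PCP1"), area_id = "A1",
                     specialty_code = c("06", "08"),
                     primary_care_taxonomy = FALSE, practice_id = NA,
                     stringsAsFactors = FALSE)
  ps <- make_practice_fixture()
  cohort <- data.frame(patient_id = c("p1", "p2"), practice_id = "X",
                       team_type = "PCP", age_on_index = 70,
                       diabetes_diagnosis_date = as.Date("2010-01-01"),
                       included = TRUE, exclusion_reason = "none",
                       stringsAsFactors = FALSE)
  v <- data.frame(patient_id = c("p1", "p2"),
                  provider_id = c("CARD", "CARD"),
                  service_date = as.Date("2015-05-05"),
                  cpt_code = c("99243", "87070"),   # consult vs non-qualifying
                  setting = "office", snf_biller = FALSE,
                  stringsAsFactors = FALSE)
  empty_rx <- data.frame(patient_id = character(0), drug_class = character(0),
                         fill_date = as.Date(character(0)),
                         days_supply = integer(0))
  panel <- build_measure_panel(cohort, v, empty_rx, NULL, prov, ps)
  expect_true(panel$saw_cardiologist[panel$patient_id == "p1"])
  expect_false(panel$saw_cardiologist[panel$patient_id == "p2"])
  # zero qualifying claims: flags false, counts 0, MCI undefined
  expect_equal(panel$visits_any_provider[panel$patient_id == "p2"], 0)
  expect_true(is.na(panel$mci_any_provider[panel$patient_id == "p2"]))
  expect_false(panel$eye_exam[panel$patient_id == "p2"])
})

test_that("disabled measures report NA, not FALSE; unknown drug classes error", {
  fx <- make_cohort_fixture()
  built <- build_cohort(fx$visits, fx$practice_set, fx$beneficiaries,
                        min_patients = 1)
  cs <- codeset_config(eye_exam_codes = character(0))
  prov <- data.frame(provider_id = c("X1", "X2", "Y1", "Y2"), area_id = "A1",
                     specialty_code = "08", primary_care_taxonomy = FALSE,
                     practice_id = NA, stringsAsFactors = FALSE)
  empty_rx <- data.frame(patient_id = character(0), drug_class = character(0),
                         fill_date = as.Date(character(0)),
                         days_supply = integer(0))
  panel <- build_measure_panel(built$cohort, fx$visits, empty_rx, NULL,
                               prov, built$practice_set, codesets = cs)
  expect_true(all(is.na(panel$eye_exam)))
  expect_false(all(is.na(panel$hba1c_test)))

  bad_rx <- data.frame(patient_id = "p01", drug_class = "opioid",
                       fill_date = as.Date("2015-02-02"), days_supply = 30L,
                       stringsAsFactors = FALSE)
  expect_error(build_measure_panel(built$cohort, fx$visits, bad_rx, NULL,
                                   prov, built$practice_set), "opioid")
})

test_that("utilization flags follow the ED-charge / revenue-code / diagnosis rules", {
  cs <- codeset_config()
  stays <- data.frame(
    patient_id = c("a", "b", "c", "d", "e"),
    admit_date = as.Date("2015-06-01"),
    stay_type = c("outpatient", "inpatient", "inpatient", "outpatient",
                  "inpatient"),
    ed_charge = c(0, 0, 512.5, 0, 0),
    revenue_codes = c("0450", "", "", "0360;0371", ""),
    diagnosis_codes = c("", "", "I10", "", "I500;E1100"),
    stringsAsFactors = FALSE)
  u <- utilization_flags(stays, cs)
  expect_setequal(u$ed_patients, c("a", "c"))
  expect_setequal(u$preventable_patients, "e")
  # adding a claim never turns a flag off (monotonicity)
  u2 <- utilization_flags(rbind(stays, data.frame(
    patient_id = "b", admit_date = as.Date("2015-07-01"),
    stay_type = "outpatient", ed_charge = 0, revenue_codes = "0981",
    diagnosis_codes = "")), cs)
  expect_true(all(u$ed_patients %in% u2$ed_patients))
  expect_true("b" %in% u2$ed_patients)
})
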