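#!/usr/bin/env Rscript
# Stage 4: per-patient quality measures for the analytic cohort: process-of-
# care flags (eye exam, HbA1c, nephropathy monitoring), specialist contact,
# visit counts and Modified Continuity Index at three provider levels,
# antidiabetic proportion of days covered, medication flags, and utilization
# flags. Prints a team-type summary in the layout of a processes-of-care
# table.
#
# Usage: Rscript analysis/04_measures.R [results_dir]

library(pcteams)

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else "results/analysis"
bundle <- read_bundle(file.path(out, "bundle"))
ps <- practice_set(
  read.csv(file.path(out, "practices.csv"), stringsAsFactors = FALSE),
  read.csv(file.path(out, "practice_membership.csv"),
           stringsAsFactors = FALSE))
cohort <- read.csv(file.path(out, "cohort.csv"), stringsAsFactors = FALSE)
cohort$diabetes_diagnosis_date <- as.Date(cohort$diabetes_diagnosis_date)

panel <- build_measure_panel(cohort, bundle$visits, bundle$prescriptions,
                             bundle$facility_stays, bundle$providers, ps)
write.csv(panel, file.path(out, "measure_panel.csv"), row.names = FALSE)

m <- merge(panel, cohort[cohort$included, c("patient_id", "team_type")],
           by = "patient_id")
pct <- function(x) 100 * mean(x, na.rm = TRUE)
summ <- aggregate(
  cbind(eye_exam, hba1c_test, nephropathy_monitoring, statin_use,
        high_risk_med_use, any_ed_visit, any_preventable_hosp) ~ team_type,
  data = m, FUN = pct)
cont <- aggregate(
  cbind(visits_any_provider, mci_any_provider, mci_any_pcp,
        mci_own_practice, pdc_antidiabetic) ~ team_type,
  data = m, FUN = function(x) mean(x, na.rm = TRUE))
cat("Care processes by team type (%):\n")
print(format(summ, digits = 3), row.names = FALSE)
cat("\nVisit volume, continuity and adherence by team type:\n")
print(format(cont, digits = 3), row.names = FALSE)
write.csv(merge(summ, cont, by = "team_type"),
          file.path(out, "measures_by_team.csv"), row.names = FALSE)
cat(sprintf("\nMeasure panel written to %s\n", out))
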