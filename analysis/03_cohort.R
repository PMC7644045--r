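#!/usr/bin/env Rscript
# Stage 3: attribute diabetic patients to the identified practices (>= 2
# office visits in 2015, excluding patients split across practices) and run
# the eligibility cascade (enrollment, Medicare Advantage, survival, age 66+,
# long-term-care residence, known rurality). Practices with < 20 attributed
# diabetic patients leave the study with their patients.
#
# Usage: Rscript analysis/03_cohort.R [results_dir]

library(pcteams)

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else "results/analysis"
bundle <- read_bundle(file.path(out, "bundle"))
ps <- practice_set(
  read.csv(file.path(out, "practices.csv"), stringsAsFactors = FALSE),
  read.csv(file.path(out, "practice_membership.csv"),
           stringsAsFactors = FALSE))

built <- build_cohort(bundle$visits, ps, bundle$beneficiaries)
flow <- cohort_flow(built$cohort)
cat("Cohort flow (first-fail exclusion reasons):\n")
print(flow, row.names = FALSE)
cat(sprintf("\n%d of %d candidates enter the analytic cohort across %d practices\n",
            sum(built$cohort$included), nrow(built$cohort),
            sum(built$practice_set$practices$included)))

write.csv(built$cohort, file.path(out, "cohort.csv"), row.names = FALSE)
write.csv(flow, file.path(out, "cohort_flow.csv"), row.names = FALSE)
write.csv(built$practice_set$practices, file.path(out, "practices.csv"),
          row.names = FALSE)
cat(sprintf("Cohort tables written to %s\n", out))
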