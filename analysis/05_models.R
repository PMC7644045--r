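#!/usr/bin/env Rscript
# Stage 5: covariate balance across team types (maximum absolute standardized
# mean difference, 0.1 flag) and practice-clustered random-intercept models:
# binomial-logit for binary measures (odds ratios vs the PCP-only group),
# normal-identity for continuity/PDC, negative-binomial for visit counts.
# Reports the intraclass correlation (practice share of variance) per
# outcome.
#
# Usage: Rscript analysis/05_models.R [results_dir]

library(pcteams)

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else "results/analysis"
cohort <- read.csv(file.path(out, "cohort.csv"), stringsAsFactors = FALSE)
panel <- read.csv(file.path(out, "measure_panel.csv"),
                  stringsAsFactors = FALSE)

inc <- cohort[cohort$included, ]
d <- merge(panel, inc[, c("patient_id", "practice_id", "team_type",
                          "age_on_index", "sex", "race_ethnicity",
                          "dual_eligible", "rurality")],
           by = "patient_id")
d$age10 <- (d$age_on_index - 75) / 10
d$male <- as.numeric(d$sex == "male")
d$dual <- as.numeric(d$dual_eligible)

cat("Covariate balance across the four team types:\n")
bal <- balance_table(d, c("age_on_index", "male", "dual_eligible",
                          "race_ethnicity", "rurality"))
print(bal, row.names = FALSE)
write.csv(bal, file.path(out, "balance.csv"), row.names = FALSE)

outcomes <- c(eye_exam = "binomial_logit", hba1c_test = "binomial_logit",
              nephropathy_monitoring = "binomial_logit",
              high_risk_med_use = "binomial_logit",
              any_ed_visit = "binomial_logit",
              mci_any_pcp = "normal_identity",
              pdc_antidiabetic = "normal_identity",
              visits_any_provider = "negbin_log")
fits <- list()
for (oc in names(outcomes)) {
  d[[oc]] <- as.numeric(d[[oc]])
  fits[[oc]] <- fit_glmm(d, oc, family = outcomes[[oc]],
                         covariates = c("age10", "male", "dual"))
  cat("\n"); print(fits[[oc]])
}
results <- do.call(rbind, lapply(fits, tidy_glmm))
rownames(results) <- NULL
write.csv(results, file.path(out, "model_results.csv"), row.names = FALSE)

iccs <- data.frame(
  outcome = names(fits),
  icc_pct = vapply(fits, function(f) 100 * f$icc, numeric(1)),
  family = vapply(fits, function(f) f$family, character(1)))
cat("\nPractice share of outcome variance (ICC, %):\n")
print(format(iccs, digits = 3), row.names = FALSE)
write.csv(iccs, file.path(out, "icc_by_outcome.csv"), row.names = FALSE)
cat(sprintf("\nModel tables written to %s\n", out))
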