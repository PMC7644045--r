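#!/usr/bin/env Rscript
# Stage 1: generate the synthetic claims bundle that stands in for restricted
# Medicare data. Ten service areas, ten latent practices each (3-8 providers,
# 60 attributed diabetic patients), four team compositions, practice-level
# random intercepts (sd 0.5 logit) on every binary care measure.
#
# Usage: Rscript analysis/01_simulate.R [seed] [out_dir]

library(pcteams)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20150101L
out <- if (length(args) >= 2) args[2] else "results/analysis"

cfg <- sim_config(seed = seed)
bundle <- simulate_claims(cfg)
print(bundle)

write_bundle(bundle, file.path(out, "bundle"))
cat("\nTeam-type mix of planted practices:\n")
print(table(bundle$truth$practices$true_team_type))
cat(sprintf("\nBundle written to %s/bundle\n", out))
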