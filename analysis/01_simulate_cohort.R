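#!/usr/bin/env Rscript
# Stage 1: simulate the reference cohort (51 HC, 58 RRMS, 28 PPMS, 36 SPMS
# subjects over the packaged 115-region parcellation) and write it to disk
# in the plain-text cohort layout. Later stages read it back, so the whole
# workflow is reproducible from this artifact alone.

suppressPackageStartupMessages(library(pnms))

seed <- as.integer(Sys.getenv("PNMS_SEED", "1"))
out <- "results/cohort"
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
coh <- simulate_cohort(cfg)
write_cohort(coh, out)

man <- coh$manifest
cat("Simulated", nrow(man), "subjects at seed", seed, "\n")
print(table(man$group))
cat("\nEDSS by group (median):\n")
print(tapply(man$edss, man$group, stats::median, na.rm = TRUE))
cat("\nSDMT by group (mean):\n")
print(round(tapply(man$sdmt, man$group, mean, na.rm = TRUE), 1))
cat("\nCohort written to", out, "\n")
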