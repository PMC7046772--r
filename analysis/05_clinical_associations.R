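#!/usr/bin/env Rscript
# Stage 5: covariate-adjusted regressions of EDSS and SDMT on the
# right-thalamus / right-putamen subnetwork strengths (MS subjects only),
# plus the exploratory pairwise association matrix over all PN members.

suppressPackageStartupMessages(library(pnms))

coh <- read_cohort("results/cohort")
dir.create("results/associations", showWarnings = FALSE, recursive = TRUE)

gm_hc <- group_mean_matrix(coh, "HC")
pns <- pn_decompose(gm_hc, tau = 0.1, n_components = 2)
strengths <- lapply(pns, function(p) subnetwork_nodal_strength(coh, p))
names(strengths) <- vapply(pns, function(p) as.character(p$rank), "")

tab <- clinical_association_table(coh, strengths)
utils::write.table(tab, "results/associations/models.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Covariate-adjusted models (MS population):\n")
print(within(tab, {
  coefficient <- signif(coefficient, 3)
  ci_lower <- signif(ci_lower, 3); ci_upper <- signif(ci_upper, 3)
  p_value <- signif(p_value, 3)
}), row.names = FALSE)

am <- association_matrix(coh, strengths)
utils::write.table(
  data.frame(predictor = rownames(am), am, check.names = FALSE),
  "results/associations/association_matrix.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
ord <- order(abs(am[, "edss"]), decreasing = TRUE)
cat("\nStrongest EDSS correlates:\n")
print(round(am[ord[1:5], ], 3))
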