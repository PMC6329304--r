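#!/usr/bin/env Rscript
# Stage 5: age-adjusted univariate Cox screen of the candidate genes under
# both overall-survival clocks, BH-adjusted within each screen; then a
# Kaplan-Meier/log-rank look at the top gene.

suppressMessages(library(melscreen))
variants <- read_variants_tsv("results/variants_filtered.tsv")
clinical <- read_clinical_tsv("results/cohort/clinical.tsv")
cand <- readLines("results/candidates.txt")

mat <- collapse_to_matrix(variants, clinical$sample_id)[cand, , drop = FALSE]

for (org in c("dx", "specimen")) {
  scr <- screen_genes(mat, clinical, org)
  scr <- scr[order(scr$fdr), ]
  write.table(scr, sprintf("results/screen_%s.tsv", org), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hits <- scr[!is.na(scr$fdr) & scr$fdr <= 0.4, ]
  cat(sprintf("\nOS-%s screen: %d/%d genes at FDR <= 0.4 (%d at FDR <= 0.2)\n",
              org, nrow(hits), nrow(scr), sum(hits$fdr <= 0.2)))
  print(hits[, c("gene", "hr", "ci_low", "ci_high", "p", "fdr", "tier")],
        digits = 3)
}

scr <- read.delim("results/screen_specimen.tsv")
top <- scr$gene[1]
km <- km_logrank(clinical$os_spec_months, clinical$event, mat[top, ])
write.table(km$curves, "results/km_top_gene.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nTop gene %s: log-rank p = %.3f, unadjusted HR = %.2f (95%% CI %.2f-%.2f)\n",
            top, km$p, km$hr, km$ci_low, km$ci_high))
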