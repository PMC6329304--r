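#!/usr/bin/env Rscript
# Stage 6: RNA confirmation of DNA mutations (>75% expressed-mutation rule)
# and mutation/copy-number/expression integration for the top candidates.

suppressMessages(library(melscreen))
variants <- read_variants_tsv("results/variants_filtered.tsv")
rna <- read.delim("results/cohort/rna_evidence.tsv")
omics <- read.delim("results/cohort/omics.tsv")
cand <- readLines("results/candidates.txt")

conc <- gene_confirmation_rates(rna, variants[variants$gene %in% cand, ])
write.table(conc, "results/rna_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d candidate genes RNA-confirmed in >75%% of DNA-mutated samples:\n",
            sum(conc$passes_75), nrow(conc)))
print(conc, digits = 3)

for (g in head(conc$gene[order(-conc$fraction)], 2)) {
  integ <- integrate_mutation_cna_expression(omics[omics$gene == g, ])
  cat(sprintf("\n%s: %d samples across %d mutation/CNA/expression categories;",
              g, sum(integ$summary$n), nrow(integ$summary)))
  mut_cna <- grepl("mutated\\|definite", integ$samples$category)
  cat(sprintf(" %d mutated sample(s) with a definite copy-number alteration\n",
              sum(mut_cna)))
  write.table(integ$samples, sprintf("results/integration_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
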