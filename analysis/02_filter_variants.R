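#!/usr/bin/env Rscript
# Stage 2: quality (MAF >= 5%, MAC >= 5), artifact-flag, impact
# (HIGH/MODERATE), and panel filters, with per-step accounting.

suppressMessages(library(melscreen))
variants <- read_variants_tsv("results/cohort/variants.tsv")
panel <- default_gene_panel()$gene

casc <- run_filter_cascade(
  variants, panel = panel,
  drop_flags = c("oxog_suspect", "germline_suspect")
)
print(casc$report)
write.table(casc$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_variants_tsv(casc$variants, "results/variants_filtered.tsv")

cat(sprintf("%d of %d calls survive the cascade (%.1f%%)\n",
            nrow(casc$variants), nrow(variants),
            100 * nrow(casc$variants) / nrow(variants)))
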