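#!/usr/bin/env Rscript
# Stage 1: generate the synthetic metastatic-melanoma cohort all later
# stages consume. 356 samples, 22-gene candidate panel with planted hazard
# ratios, UV-dominated spectra, ~52% deaths.

suppressMessages(library(melscreen))
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1123)
cohort <- simulate_cohort(cfg)
print(cohort)

write_variants_tsv(cohort$variants, "results/cohort/variants.tsv")
write_variants_vcf(cohort$variants, "results/cohort/variants.vcf")
write_clinical_tsv(cohort$clinical, "results/cohort/clinical.tsv")
write.table(cohort$rna, "results/cohort/rna_evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$omics, "results/cohort/omics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Median mutation burden: %d (range %d-%d)\n",
            median(cohort$clinical$burden), min(cohort$clinical$burden),
            max(cohort$clinical$burden)))
cat(sprintf("Deceased: %d/%d (%.1f%%)\n", sum(cohort$clinical$event),
            nrow(cohort$clinical), 100 * mean(cohort$clinical$event)))
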