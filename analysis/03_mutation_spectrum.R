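#!/usr/bin/env Rscript
# Stage 3: UV-signature spectrum of the cohort, pooled and per sample, and a
# rank-sum comparison of per-sample UV fractions between deceased and living
# patients.

suppressMessages(library(melscreen))
variants <- read_variants_tsv("results/cohort/variants.tsv")
clinical <- read_clinical_tsv("results/cohort/clinical.tsv")

pooled <- summarize_spectrum(variants, "pooled")
per_sample <- summarize_spectrum(variants, "sample")
write.table(pooled, "results/spectrum_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(per_sample, "results/spectrum_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Pooled over %d mutations: C>T %.1f%%, dipyrimidine C>T %.1f%%, CC>TT %.2f%%\n",
            pooled$n_total, 100 * pooled$frac_c_to_t,
            100 * pooled$frac_c_to_t_dipyrimidine, 100 * pooled$frac_cc_to_tt))

uv <- per_sample$frac_c_to_t + per_sample$frac_cc_to_tt
dead <- clinical$event[match(per_sample$scope, clinical$sample_id)] == 1
keep <- !is.na(uv) & !is.na(dead)
cmp <- compare_spectra(uv[keep & dead], uv[keep & !dead])
cat(sprintf("Deceased vs living per-sample UV fraction: Wilcoxon p = %.3f (%s)\n",
            cmp$p, cmp$method))
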