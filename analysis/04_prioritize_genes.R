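#!/usr/bin/env Rscript
# Stage 4: collapse to the gene x sample matrix (one hit per gene per
# specimen), keep genes mutated in >= 3% of samples, and select candidates
# by the deceased-vs-alive fold statistic (x >= 1.5 or x <= 0.67).

suppressMessages(library(melscreen))
variants <- read_variants_tsv("results/variants_filtered.tsv")
clinical <- read_clinical_tsv("results/cohort/clinical.tsv")

mat <- collapse_to_matrix(variants, clinical$sample_id)
cat(sprintf("Collapsed matrix: %d genes x %d samples\n", nrow(mat), ncol(mat)))

prevalent <- prevalence_filter(mat, 0.03)
cat(sprintf("%d genes mutated in >= %d samples (3%%)\n", length(prevalent),
            ceiling(0.03 * ncol(mat))))

fold <- fold_statistic(mat[prevalent, , drop = FALSE], clinical$event == 1)
write.table(fold, "results/prioritization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cand <- fold$gene[fold$selected]
cat(sprintf("%d candidate genes pass the fold band: %s\n", length(cand),
            paste(cand, collapse = ", ")))
cat(sprintf("Carrier fraction of the candidate set: %.1f%%\n",
            100 * carrier_fraction(mat[cand, , drop = FALSE])))

burden <- association_with_burden(mat[cand, , drop = FALSE], clinical$burden)
write.table(burden, "results/association_burden.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d candidates associated with high burden at FDR < 0.1\n",
            sum(burden$fdr < 0.1, na.rm = TRUE), nrow(burden)))

vital <- association_with_label(colSums(mat[cand, , drop = FALSE]) > 0,
                               ifelse(clinical$expr_class == "immune-high",
                                      "immune-high", "other"))
cat(sprintf("Candidate carriage vs immune-high class: chi-square %.2f, p = %.3f\n",
            vital$statistic, vital$p))
writeLines(cand, "results/candidates.txt")
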