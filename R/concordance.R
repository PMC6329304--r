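#' Assess RNA read support for a DNA mutation
#'
#' Declares each variant site `INSUFFICIENT` when RNA coverage is below
#' `min_depth` (low-to-absent gene expression), `CONFIRMED` when at least
#' `min_alt` RNA reads carry the mutant allele, and `COVERED_NOT_CONFIRMED`
#' otherwise (the site is expressed but only the reference allele is seen).
#' The default thresholds (depth 8, alt reads 2) are conservative
#' read-support conventions, exposed as arguments.
#'
#' @param rna_depth RNA reads covering the site (vectorized).
#' @param rna_alt RNA reads supporting the alternate allele.
#' @param min_depth Minimum coverage to call the site assessable, default 8.
#' @param min_alt Minimum mutant reads to confirm, default 2.
#' @return Character vector in
#'   `{CONFIRMED, COVERED_NOT_CONFIRMED, INSUFFICIENT}`.
#' @export
assess_rna_support <- function(rna_depth, rna_alt, min_depth = 8, min_alt = 2) {
  if (any(rna_alt > rna_depth, na.rm = TRUE)) {
    stop_validation("rna_alt exceeds rna_depth on some record(s)")
  }
  if (any(rna_depth < 0 | rna_alt < 0, na.rm = TRUE)) {
    stop_validation("negative RNA read counts")
  }
  ifelse(rna_depth < min_depth, "INSUFFICIENT",
         ifelse(rna_alt >= min_alt, "CONFIRMED", "COVERED_NOT_CONFIRMED"))
}

#' Gene-level RNA confirmation rates and the >75% expressed-mutation rule
#'
#' For each gene, the fraction of DNA-mutated samples whose mutation is
#' confirmed by RNA reads. A sample counts as confirmed for a gene when at
#' least one of its DNA calls in the gene is `CONFIRMED`. The default
#' denominator is all samples with a DNA call in the gene, including those
#' with insufficient RNA coverage — low coverage implies low-to-absent
#' expression, which argues against the mutation being expressed; the
#' covered-only denominator is available via `denominator = "covered"`.
#' A gene passes the expressed-mutation rule when its fraction strictly
#' exceeds 0.75. Genes with zero DNA calls are excluded from the output.
#' DNA calls with no matching RNA evidence row are treated as zero-coverage
#' (`INSUFFICIENT`).
#'
#' @param rna RNA evidence table: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `rna_depth`, `rna_alt`.
#' @param dna_calls Variant table of DNA calls (needs `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`).
#' @param min_depth,min_alt Passed to [assess_rna_support()].
#' @param denominator `"dna"` (default: all DNA-mutated samples) or
#'   `"covered"` (samples with assessable RNA coverage only).
#' @return data.frame: `gene`, `n_dna`, `n_covered`, `n_confirmed`,
#'   `fraction`, `passes_75`.
#' @export
gene_confirmation_rates <- function(rna, dna_calls, min_depth = 8, min_alt = 2,
                                    denominator = c("dna", "covered")) {
  denominator <- match.arg(denominator)
  check_variants(dna_calls, required = c("sample_id", "chrom", "pos", "ref",
                                         "alt", "gene"))
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt, sep = "|")
  i <- match(key(dna_calls), key(rna))
  depth <- ifelse(is.na(i), 0L, rna$rna_depth[i])
  altr <- ifelse(is.na(i), 0L, rna$rna_alt[i])
  status <- assess_rna_support(depth, altr, min_depth, min_alt)

  per_gene <- lapply(split(seq_len(nrow(dna_calls)), dna_calls$gene), function(idx) {
    d <- dna_calls[idx, ]
    st <- status[idx]
    by_sample <- split(st, d$sample_id)
    n_dna <- length(by_sample)
    confirmed <- vapply(by_sample, function(s) any(s == "CONFIRMED"), logical(1))
    covered <- vapply(by_sample, function(s) any(s != "INSUFFICIENT"), logical(1))
    denom <- if (denominator == "dna") n_dna else sum(covered)
    frac <- if (denom > 0) sum(confirmed) / denom else NA_real_
    data.frame(
      gene = d$gene[1], n_dna = n_dna, n_covered = sum(covered),
      n_confirmed = sum(confirmed), fraction = frac,
      passes_75 = !is.na(frac) & frac > 0.75,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_gene)
  if (is.null(out)) {
    out <- data.frame(gene = character(), n_dna = integer(),
                      n_covered = integer(), n_confirmed = integer(),
                      fraction = numeric(), passes_75 = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Integrate mutation, copy number, and expression for one gene
#'
#' Labels every sample of one gene's omics profile by its mutation status,
#' copy-number state (definite alteration = GISTIC score +2 or -2;
#' everything else neutral-ish), and expression tertile computed within the
#' analyzed cohort. The resulting categories partition the cohort: every
#' sample lands in exactly one, samples missing any layer land in
#' `"incomplete"`, and the summary counts sum to the number of samples.
#'
#' @param profiles data.frame for one gene: `sample_id`, `mutated` (0/1),
#'   `gistic` (integer in -2..2), `log2_expr`.
#' @return list: `samples` (per-sample data.frame with `category`,
#'   `cna_state`, `expr_tertile`), `summary` (category counts).
#' @export
integrate_mutation_cna_expression <- function(profiles) {
  need <- c("sample_id", "mutated", "gistic", "log2_expr")
  if (!all(need %in% names(profiles))) {
    stop_validation("profiles need columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(profiles$gene)) > 1) {
    stop_validation("profiles must cover a single gene; split by gene first")
  }
  bad_g <- !is.na(profiles$gistic) & !profiles$gistic %in% -2:2
  if (any(bad_g)) stop_validation("gistic scores must lie in -2..2")

  incomplete <- is.na(profiles$mutated) | is.na(profiles$gistic) |
    is.na(profiles$log2_expr) | !is.finite(profiles$log2_expr)

  cna <- rep(NA_character_, nrow(profiles))
  cna[!incomplete] <- ifelse(profiles$gistic[!incomplete] == 2, "definite_amplification",
                        ifelse(profiles$gistic[!incomplete] == -2, "definite_deletion",
                               "no_definite_cna"))
  tert <- rep(NA_character_, nrow(profiles))
  if (any(!incomplete)) {
    e <- profiles$log2_expr[!incomplete]
    qs <- stats::quantile(e, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    tert[!incomplete] <- c("expr_low", "expr_mid", "expr_high")[
      as.integer(cut(e, breaks = c(-Inf, qs, Inf)))]
  }
  category <- ifelse(incomplete, "incomplete",
                     paste(ifelse(profiles$mutated == 1, "mutated", "wildtype"),
                           cna, tert, sep = "|"))
  samples <- data.frame(
    sample_id = profiles$sample_id, category = category,
    cna_state = cna, expr_tertile = tert, stringsAsFactors = FALSE
  )
  summary <- as.data.frame(table(category = category), stringsAsFactors = FALSE)
  names(summary) <- c("category", "n")
  list(samples = samples, summary = summary)
}
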