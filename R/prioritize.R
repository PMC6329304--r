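#' Prevalence filter on the gene-by-sample matrix
#'
#' Retains genes mutated in at least `ceiling(min_fraction * n_samples)`
#' samples. For a 356-sample cohort at 3% this gives a count threshold of 11
#' (0.03 x 356 = 10.68, rounded up). Because "at least 3%" and "more than 11
#' patients" pin different integers, the alternative strict rule
#' (`count > ceiling(...)`) is available via `rule`.
#'
#' @param matrix Binary gene x sample matrix from [collapse_to_matrix()].
#' @param min_fraction Minimum mutated-sample fraction, default 0.03.
#' @param rule `"at_least_ceiling"` (default, inclusive) or
#'   `"greater_than_ceiling"`.
#' @return Character vector of retained genes, in matrix (stable) row order.
#' @export
prevalence_filter <- function(matrix, min_fraction = 0.03,
                              rule = c("at_least_ceiling", "greater_than_ceiling")) {
  rule <- match.arg(rule)
  if (!is_scalar_number(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop_config("min_fraction must lie in (0, 1], got ", min_fraction)
  }
  if (is.null(dim(matrix)) || ncol(matrix) == 0) {
    stop_config("gene-sample matrix is empty")
  }
  threshold <- ceiling(min_fraction * ncol(matrix))
  counts <- rowSums(matrix != 0)
  keep <- if (rule == "at_least_ceiling") counts >= threshold else counts > threshold
  rownames(matrix)[keep]
}

#' Deceased-versus-alive mutation fold statistic
#'
#' For each gene, the fold `x` of the fraction of deceased patients whose
#' tumor carries a mutation in the gene over the corresponding fraction among
#' living patients:
#' \deqn{x = \frac{m_d / n_d}{m_a / n_a}}
#' Genes with `x >= upper` (more often mutated in the deceased) or
#' `x <= lower` (more often mutated in the living) are selected as candidates.
#' Vital status is the status at last follow-up; follow-up time is
#' deliberately ignored at this stage. When no living patient carries the
#' mutation but some deceased do, `x = Inf` and the gene is selected; when no
#' patient at all carries it, `x` is `NA` and the gene is not selected.
#'
#' The default band (1.5, 0.67) is asymmetric: 1/1.5 = 0.6667 < 0.67, so the
#' protective side is very slightly easier to enter than its exact
#' reciprocal.
#'
#' @param matrix Binary gene x sample matrix.
#' @param vital_status Per-sample status, aligned with `colnames(matrix)`:
#'   logical (`TRUE` = deceased) or character `"deceased"`/`"alive"`.
#' @param upper,lower Selection band bounds, defaults 1.5 and 0.67.
#' @return data.frame with one row per gene: `gene`, `n_mut_deceased`,
#'   `n_deceased`, `n_mut_alive`, `n_alive`, `x`, `selected`.
#' @export
fold_statistic <- function(matrix, vital_status, upper = 1.5, lower = 0.67) {
  if (is.character(vital_status)) {
    bad <- !vital_status %in% c("deceased", "alive")
    if (any(bad)) stop_validation("vital_status values must be 'deceased' or 'alive'")
    vital_status <- vital_status == "deceased"
  }
  vital_status <- as.logical(vital_status)
  if (length(vital_status) != ncol(matrix) || anyNA(vital_status)) {
    stop_validation("vital_status must be defined for every sample")
  }
  n_d <- sum(vital_status)
  n_a <- sum(!vital_status)
  if (n_d == 0 || n_a == 0) {
    stop_config("fold statistic undefined: cohort must contain both deceased ",
                "and living patients (", n_d, " deceased, ", n_a, " alive)")
  }
  m_d <- rowSums(matrix[, vital_status, drop = FALSE] != 0)
  m_a <- rowSums(matrix[, !vital_status, drop = FALSE] != 0)
  x <- (m_d / n_d) / (m_a / n_a)          # m_a = 0, m_d > 0 -> Inf; 0/0 -> NaN
  x[m_d == 0 & m_a == 0] <- NA_real_
  selected <- !is.na(x) & (x >= upper | x <= lower)
  data.frame(
    gene = rownames(matrix),
    n_mut_deceased = as.integer(m_d), n_deceased = n_d,
    n_mut_alive = as.integer(m_a), n_alive = n_a,
    x = x, selected = selected,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Association between mutation status and a categorical label
#'
#' Pearson chi-square test (no continuity correction) of independence between
#' a gene's mutation indicator and a per-sample categorical label such as
#' vital status or an expression-class assignment. Expected counts are
#' returned so callers can flag sparse tables; a warning is emitted when any
#' expected count falls below 5.
#'
#' @param mutated Per-sample 0/1 (or logical) mutation indicator.
#' @param labels Per-sample categorical label; levels with zero samples are
#'   dropped with a warning.
#' @return list with `statistic`, `df`, `p`, `expected`, `observed`.
#' @export
association_with_label <- function(mutated, labels) {
  mutated <- as.integer(as.logical(mutated))
  if (length(mutated) != length(labels)) {
    stop_validation("mutated and labels must have equal length")
  }
  if (!is.factor(labels)) labels <- factor(labels)
  empty <- levels(labels)[tabulate(labels, nbins = nlevels(labels)) == 0]
  if (length(empty) > 0) {
    warning("dropping empty label level(s): ", paste(empty, collapse = ", "))
    labels <- droplevels(labels)
  }
  if (nlevels(labels) < 2) {
    stop_config("need at least two label levels, got ", nlevels(labels))
  }
  tab <- table(mutated = factor(mutated, levels = 0:1), label = labels)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected count below 5 in ", sum(ht$expected < 5),
            " cell(s); chi-square approximation may be poor")
  }
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = unname(ht$p.value),
    expected = ht$expected,
    observed = tab
  )
}

#' Association between mutation status and total mutation burden
#'
#' For each gene, a two-sided Wilcoxon rank-sum test comparing total somatic
#' mutation burden between mutated and non-mutated samples, with
#' Benjamini-Hochberg adjustment across the tested genes. Genes where every
#' sample (or none) is mutated have no comparison and are reported with
#' missing p.
#'
#' @param matrix Binary gene x sample matrix.
#' @param burden Per-sample total mutation count, aligned with
#'   `colnames(matrix)`.
#' @return data.frame: `gene`, `n_mutated`, `median_burden_mut`,
#'   `median_burden_wt`, `p`, `fdr`.
#' @export
association_with_burden <- function(matrix, burden) {
  if (length(burden) != ncol(matrix) || anyNA(burden)) {
    stop_validation("burden must be defined for every sample")
  }
  rows <- lapply(rownames(matrix), function(g) {
    m <- matrix[g, ] != 0
    p <- if (all(m) || !any(m)) NA_real_ else rank_sum_test(burden[m], burden[!m])$p
    data.frame(
      gene = g, n_mutated = sum(m),
      median_burden_mut = if (any(m)) stats::median(burden[m]) else NA_real_,
      median_burden_wt = if (!all(m)) stats::median(burden[!m]) else NA_real_,
      p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p[ok])
  out
}

#' Fraction of samples carrying a mutation in any matrix gene
#'
#' The carrier fraction of a candidate gene set: the proportion of cohort
#' samples with at least one mutated gene among the matrix rows.
#'
#' @param matrix Binary gene x sample matrix (possibly subset to a gene list).
#' @return Single numeric fraction in \[0, 1\].
#' @export
carrier_fraction <- function(matrix) {
  if (is.null(dim(matrix)) || ncol(matrix) == 0) stop_config("matrix is empty")
  mean(colSums(matrix != 0) > 0)
}
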