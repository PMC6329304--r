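#' @name filter_report
#' @title Per-step filtering accounting
#'
#' @description Every filtering step returns, alongside the surviving
#' variants, a one-row report `(step, n_input, n_removed, n_output)` with the
#' invariant `n_input - n_removed = n_output`. Reports from chained steps
#' rbind into a cascade table in which each step's `n_output` equals the next
#' step's `n_input`, so the whole cascade accounting always balances.
NULL

filter_report_row <- function(step, n_input, n_output) {
  data.frame(
    step = step,
    n_input = as.integer(n_input),
    n_removed = as.integer(n_input - n_output),
    n_output = as.integer(n_output),
    stringsAsFactors = FALSE
  )
}

#' Check that a cascade report balances
#'
#' @param report data.frame of chained filter-report rows.
#' @return `TRUE` invisibly; errors if per-step conservation
#'   (`n_input - n_removed == n_output`) or chaining
#'   (`n_output[k] == n_input[k+1]`) is violated.
#' @export
check_report_conservation <- function(report) {
  stopifnot(all(c("step", "n_input", "n_removed", "n_output") %in% names(report)))
  if (!all(report$n_input - report$n_removed == report$n_output)) {
    stop_validation("filter report violates n_input - n_removed = n_output")
  }
  k <- nrow(report)
  if (k > 1 && !all(report$n_output[-k] == report$n_input[-1])) {
    stop_validation("filter report steps do not chain")
  }
  invisible(TRUE)
}

#' Quality filter on mutant allele frequency and count
#'
#' Keeps variants with sample-level mutant allele frequency (MAF, the
#' within-sample variant allele fraction) at or above `maf_min` and mutated
#' allele count (MAC, reads supporting the mutant allele) at or above
#' `mac_min`. Both thresholds are inclusive. Input order is preserved.
#'
#' @param variants Variant table (see [read_variants_tsv()] for columns).
#' @param maf_min Minimum MAF, default 0.05.
#' @param mac_min Minimum MAC, default 5.
#' @return list with `variants` (survivors) and `report` (one-row accounting).
#' @export
apply_quality_filters <- function(variants, maf_min = 0.05, mac_min = 5) {
  check_variants(variants, required = c("maf", "mac"))
  if (!is_scalar_number(maf_min) || maf_min < 0 ||
      !is_scalar_number(mac_min) || mac_min < 0) {
    stop_config("maf_min and mac_min must be nonnegative numbers")
  }
  keep <- variants$maf >= maf_min & variants$mac >= mac_min
  keep[is.na(keep)] <- FALSE
  list(
    variants = variants[keep, , drop = FALSE],
    report = filter_report_row("quality_maf_mac", nrow(variants), sum(keep))
  )
}

#' Functional-impact filter
#'
#' Keeps variants whose annotated functional impact category is in `keep`.
#' Impact categories follow the snpEff convention
#' (HIGH, MODERATE, LOW, MODIFIER); the default retains the
#' intermediate/high-impact classes.
#'
#' @inheritParams apply_quality_filters
#' @param keep Character set of impact categories to retain.
#' @return list with `variants` and `report`.
#' @export
apply_impact_filter <- function(variants, keep = c("HIGH", "MODERATE")) {
  check_variants(variants, required = "impact")
  bad <- which(is.na(variants$impact) | variants$impact == "")
  if (length(bad) > 0) {
    stop_validation("missing impact field on record(s): ",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  ok <- variants$impact %in% keep
  list(
    variants = variants[ok, , drop = FALSE],
    report = filter_report_row("impact", nrow(variants), sum(ok))
  )
}

#' Restrict variants to a gene panel
#'
#' Keeps variants in genes belonging to a curated panel (e.g. a cancer gene
#' census list). Membership is case-sensitive on canonical symbols.
#'
#' @inheritParams apply_quality_filters
#' @param panel Nonempty character vector of gene symbols.
#' @return list with `variants` and `report`.
#' @export
restrict_to_panel <- function(variants, panel) {
  check_variants(variants, required = "gene")
  if (length(panel) == 0) {
    stop_config("gene panel is empty (an empty panel is a configuration ",
                "error, distinct from a panel with no overlap)")
  }
  ok <- variants$gene %in% panel
  list(
    variants = variants[ok, , drop = FALSE],
    report = filter_report_row("panel", nrow(variants), sum(ok))
  )
}

#' Drop variants carrying suspect annotation flags
#'
#' Optional cascade step: removes variants whose `flags` field (a
#' semicolon-separated set of pass-through labels from upstream annotation,
#' e.g. `oxog_suspect`, `germline_suspect`) intersects `drop_flags`. Artifact
#' and germline annotations are consumed as labels; no re-annotation happens
#' here.
#'
#' @inheritParams apply_quality_filters
#' @param drop_flags Character vector of flag labels that disqualify a call.
#' @return list with `variants` and `report`.
#' @export
apply_flag_filter <- function(variants,
                              drop_flags = c("oxog_suspect", "germline_suspect")) {
  check_variants(variants, required = "flags")
  fl <- as.character(variants$flags)
  fl[is.na(fl)] <- ""
  fl <- strsplit(fl, ";", fixed = TRUE)
  hit <- vapply(fl, function(f) any(f %in% drop_flags), logical(1))
  list(
    variants = variants[!hit, , drop = FALSE],
    report = filter_report_row("annotation_flags", nrow(variants), sum(!hit))
  )
}

#' Run the full filtering cascade
#'
#' Chains the quality, flag, impact, and panel filters in a configurable
#' order and returns the survivors together with the balanced cascade report.
#' The step order is configurable because the intermediate ordering of
#' artifact-flag steps is a reporting choice, not a result: the quality,
#' impact, and panel predicates commute, so the surviving set is
#' order-invariant.
#'
#' @inheritParams apply_quality_filters
#' @param panel Gene panel, or `NULL` to skip the panel step.
#' @param keep_impact Impact categories to keep.
#' @param drop_flags Flags that disqualify a call, or `NULL` to skip.
#' @param order Character vector naming the steps to run, in order; subset of
#'   `c("quality", "flags", "impact", "panel")`.
#' @return list with `variants` and `report` (multi-row cascade table).
#' @export
run_filter_cascade <- function(variants,
                               panel = NULL,
                               maf_min = 0.05,
                               mac_min = 5,
                               keep_impact = c("HIGH", "MODERATE"),
                               drop_flags = NULL,
                               order = c("quality", "flags", "impact", "panel")) {
  check_variants(variants)
  order <- match.arg(order, c("quality", "flags", "impact", "panel"),
                     several.ok = TRUE)
  cur <- variants
  reports <- list()
  for (step in order) {
    res <- switch(step,
      quality = apply_quality_filters(cur, maf_min = maf_min, mac_min = mac_min),
      flags = if (is.null(drop_flags)) NULL else apply_flag_filter(cur, drop_flags),
      impact = apply_impact_filter(cur, keep = keep_impact),
      panel = if (is.null(panel)) NULL else restrict_to_panel(cur, panel)
    )
    if (is.null(res)) next
    cur <- res$variants
    reports[[length(reports) + 1L]] <- res$report
  }
  report <- do.call(rbind, reports)
  check_report_conservation(report)
  list(variants = cur, report = report)
}

#' Collapse variant calls to a binary gene-by-sample matrix
#'
#' Multiple mutations per gene per specimen are counted once: the matrix
#' entry is 1 iff the sample has at least one surviving call in the gene.
#' Only genes observed in the input appear as rows (no all-zero gene rows);
#' all requested samples appear as columns, including samples with no calls.
#'
#' @param variants Variant table with `gene` and `sample_id`.
#' @param samples Ordered character vector of all sample identifiers in the
#'   cohort. Every variant's `sample_id` must be present.
#' @return Integer 0/1 matrix, genes (sorted) x samples (as given).
#' @export
collapse_to_matrix <- function(variants, samples) {
  check_variants(variants, required = c("gene", "sample_id"))
  if (anyDuplicated(samples)) stop_validation("duplicate sample identifiers")
  unknown <- setdiff(unique(variants$sample_id), samples)
  if (length(unknown) > 0) {
    stop_validation("variant(s) with unknown sample_id: ",
                    paste(utils::head(unknown, 5), collapse = ", "))
  }
  genes <- sort(unique(variants$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(variants) > 0) {
    idx <- cbind(match(variants$gene, genes), match(variants$sample_id, samples))
    mat[idx] <- 1L
  }
  mat
}
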