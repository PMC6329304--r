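#' Build and validate a pipeline run configuration
#'
#' One object drives [run_all()]: either a `simulate` block (a
#' [simulation_config()]) or paths to existing variant/clinical/RNA tables,
#' plus all analysis thresholds and the output directory. Rerunning with the
#' same configuration and seed reproduces every output byte for byte.
#'
#' @param simulate A `simulation_config`, or `NULL` to read inputs from
#'   files.
#' @param variants_path,clinical_path,rna_path Input TSV paths (used when
#'   `simulate` is `NULL`; `variants_path` may also be a `.vcf`).
#' @param panel Gene panel character vector, or `NULL` to use the simulated
#'   candidate panel (simulate mode) / skip the panel step (file mode).
#' @param maf_min,mac_min Quality thresholds (inclusive).
#' @param keep_impact Impact categories kept by the impact filter.
#' @param drop_flags Annotation flags that disqualify a call, or `NULL`.
#' @param prevalence_min Minimum mutated-sample fraction for candidate genes.
#' @param fold_upper,fold_lower Fold-statistic selection band.
#' @param fdr_cutoffs FDR tiers for the survival screens.
#' @param rna_min_depth,rna_min_alt RNA confirmation thresholds.
#' @param time_origins Survival clocks to screen (default both).
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for simulate mode.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = NULL,
                       variants_path = NULL, clinical_path = NULL,
                       rna_path = NULL, panel = NULL,
                       maf_min = 0.05, mac_min = 5,
                       keep_impact = c("HIGH", "MODERATE"),
                       drop_flags = c("oxog_suspect", "germline_suspect"),
                       prevalence_min = 0.03,
                       fold_upper = 1.5, fold_lower = 0.67,
                       fdr_cutoffs = c(0.2, 0.4),
                       rna_min_depth = 8, rna_min_alt = 2,
                       time_origins = c("dx", "specimen"),
                       outdir = tempfile("melscreen_run_"),
                       seed = NULL) {
  if (is.null(simulate)) {
    for (p in c(variants_path, clinical_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop_config("file mode needs existing variants_path and clinical_path")
      }
    }
  } else if (!inherits(simulate, "simulation_config")) {
    stop_config("simulate must be a simulation_config or NULL")
  }
  check_fraction(prevalence_min, "prevalence_min", allow_zero = FALSE)
  time_origins <- match.arg(time_origins, c("dx", "specimen"), several.ok = TRUE)
  cfg <- list(
    simulate = simulate, variants_path = variants_path,
    clinical_path = clinical_path, rna_path = rna_path, panel = panel,
    maf_min = maf_min, mac_min = mac_min, keep_impact = keep_impact,
    drop_flags = drop_flags, prevalence_min = prevalence_min,
    fold_upper = fold_upper, fold_lower = fold_lower,
    fdr_cutoffs = fdr_cutoffs, rna_min_depth = rna_min_depth,
    rna_min_alt = rna_min_alt, time_origins = time_origins,
    outdir = outdir, seed = seed
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the whole screening pipeline
#'
#' Executes simulate/ingest, the filtering cascade, spectrum
#' characterization, prevalence + fold-statistic prioritization, the
#' age-adjusted Cox screens under each requested time origin, and RNA
#' concordance, writing every stage's table under `config$outdir` together
#' with a machine-readable `report.json` whose cascade counts always balance.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly. Side effect: TSV/JSON outputs
#'   in `config$outdir`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must come from run_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  tsv <- function(d, f) utils::write.table(d, out(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)

  ## stage 1: simulate or ingest
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    variants <- cohort$variants
    clinical <- cohort$clinical
    rna <- cohort$rna
    panel <- config$panel
    if (is.null(panel)) panel <- config$simulate$gene_panel$gene
  } else {
    variants <- if (grepl("\\.vcf(\\.gz)?$", config$variants_path)) {
      read_variants_vcf(config$variants_path)
    } else {
      read_variants_tsv(config$variants_path)
    }
    clinical <- read_clinical_tsv(config$clinical_path)
    rna <- if (is.null(config$rna_path)) NULL else
      utils::read.delim(config$rna_path, stringsAsFactors = FALSE)
    panel <- config$panel
  }
  tsv(variants, "variants_input.tsv")
  tsv(clinical, "clinical.tsv")

  ## stage 2: filtering cascade
  casc <- run_filter_cascade(
    variants, panel = panel,
    maf_min = config$maf_min, mac_min = config$mac_min,
    keep_impact = config$keep_impact, drop_flags = config$drop_flags
  )
  tsv(casc$report, "filter_report.tsv")
  tsv(casc$variants, "variants_filtered.tsv")

  ## stage 3: mutation spectrum (pre-panel calls keep the cohort-wide view)
  spec_pool <- summarize_spectrum(variants, "pooled")
  spec_sample <- summarize_spectrum(variants, "sample")
  tsv(spec_pool, "spectrum_pooled.tsv")
  tsv(spec_sample, "spectrum_per_sample.tsv")

  ## stage 4: collapse + prioritize
  mat <- collapse_to_matrix(casc$variants, clinical$sample_id)
  deceased <- clinical$event == 1
  candidates <- character(0)
  fold <- NULL
  if (nrow(mat) > 0) {
    prevalent <- prevalence_filter(mat, config$prevalence_min)
    if (length(prevalent) > 0 && sum(deceased) > 0 && sum(!deceased) > 0) {
      fold <- fold_statistic(mat[prevalent, , drop = FALSE], deceased,
                             upper = config$fold_upper, lower = config$fold_lower)
      tsv(fold, "prioritization.tsv")
      candidates <- fold$gene[fold$selected]
    }
  }

  ## stage 5: survival screens (one per time origin)
  cand_mat <- mat[candidates, , drop = FALSE]
  screens <- list()
  for (org in config$time_origins) {
    scr <- screen_genes(cand_mat, clinical, time_origin = org,
                        fdr_cutoffs = config$fdr_cutoffs)
    screens[[org]] <- scr
    tsv(scr, paste0("screen_", org, ".tsv"))
  }

  ## stage 6: burden / RNA concordance for candidates
  if (length(candidates) > 0 && "burden" %in% names(clinical)) {
    burden_assoc <- association_with_burden(cand_mat, clinical$burden)
    tsv(burden_assoc, "association_burden.tsv")
  }
  concordance <- NULL
  if (!is.null(rna) && nrow(casc$variants) > 0) {
    concordance <- gene_confirmation_rates(
      rna, casc$variants,
      min_depth = config$rna_min_depth, min_alt = config$rna_min_alt
    )
    tsv(concordance, "rna_concordance.tsv")
  }

  report <- list(
    seed = config$seed,
    n_samples = nrow(clinical),
    n_variants_input = nrow(variants),
    cascade = casc$report,
    n_variants_surviving = nrow(casc$variants),
    n_genes_collapsed = nrow(mat),
    n_genes_prevalent = if (is.null(fold)) 0L else nrow(fold),
    n_candidates = length(candidates),
    candidates = candidates,
    screens = lapply(screens, function(s) {
      list(n_genes = nrow(s), tiers = as.list(table(s$tier)))
    }),
    n_rna_confirmed_genes = if (is.null(concordance)) NA_integer_ else
      sum(concordance$passes_75)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(report)
}
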