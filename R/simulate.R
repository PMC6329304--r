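#' Default candidate gene panel for simulated cohorts
#'
#' A 22-gene melanoma panel with per-gene mutation prevalences (all below
#' 10%, most 3-6%) and planted log hazard ratios: a handful of adverse and
#' protective prognostic genes plus null genes. These defaults emulate the
#' low-prevalence, mixed-effect structure of candidate genes in metastatic
#' melanoma screening; they are synthetic settings, not estimates.
#'
#' @return data.frame with columns `gene`, `prevalence`, `log_hr`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("RAC1", "FGFR1", "CARD11", "CIITA", "SPEN", "NTRK1",
             "PDGFRB", "GNAS", "MAP2K1", "EGFR", "TSC2", "CUX1",
             "AFF3", "CNTRL", "AKAP9", "KMT2C", "PRDM16", "KDM5A",
             "STAG2", "ARID2", "FBXW7", "CDKN2A"),
    prevalence = c(0.045, 0.035, 0.040, 0.050, 0.060, 0.053,
                   0.040, 0.045, 0.035, 0.050, 0.040, 0.035,
                   0.040, 0.035, 0.060, 0.055, 0.040, 0.045,
                   0.035, 0.070, 0.035, 0.080),
    log_hr = c(log(2.2), log(2.0), log(1.9), log(0.55), log(0.55), log(1.93),
               0, 0, 0, 0, 0, 0,
               0, 0, 0, 0, 0, 0,
               0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a cohort simulation configuration
#'
#' Collects every tunable of the synthetic cohort generator with validated
#' defaults. The defaults describe a metastatic-melanoma-like cohort: 356
#' samples; overdispersed per-sample mutation burden (negative binomial,
#' median about 10, long right tail); per-sample UV-signature fraction around
#' 0.8 (Beta-distributed); low per-gene candidate prevalence with planted
#' hazard ratios; exponential survival with administrative censoring tuned so
#' about 52% of subjects die; and partial RNA expression of DNA mutations.
#'
#' @param n_samples Number of tumors/patients (>= 0).
#' @param gene_panel data.frame(gene, prevalence, log_hr): candidate genes,
#'   their per-sample mutation probabilities, and planted log hazard ratios
#'   (0 for null genes).
#' @param burden_mean,burden_dispersion Negative-binomial mean and size
#'   (dispersion) of per-sample background mutation counts; smaller size
#'   means heavier overdispersion.
#' @param uv_fraction_mean,uv_fraction_concentration Beta mean/concentration
#'   of the per-sample UV-signature fraction.
#' @param cc_tt_fraction Fraction of UV variants emitted as tandem CC>TT
#'   dinucleotide records rather than single C>T.
#' @param dipyrimidine_fraction Fraction of single-base UV C>T variants
#'   placed at a dipyrimidine site.
#' @param baseline_hazard Baseline death hazard, events per month.
#' @param target_event_fraction Fraction of subjects with an observed death;
#'   censoring is a single administrative cutoff chosen by bisection so the
#'   expected event fraction over the realized cohort hazards matches this.
#' @param age_mean,age_sd Age distribution (years), truncated below at 18.
#' @param lag_mean_months Mean diagnosis-to-specimen lag (gamma, shape 2);
#'   the two overall-survival clocks differ by this per-subject lag.
#' @param rna_expressed_prob Probability a DNA mutation is RNA-supported;
#'   a single number, or a vector named by gene for per-gene control.
#' @param rna_depth_mean,rna_depth_dispersion Negative-binomial parameters of
#'   RNA coverage at expressed/covered sites.
#' @param maf_shape1,maf_shape2 Beta parameters of the sample-level mutant
#'   allele fraction.
#' @param n_background_genes Size of the non-candidate gene name pool that
#'   absorbs the background burden.
#' @param seed Optional integer seed; identical config + seed gives
#'   byte-identical output.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 356,
                              gene_panel = default_gene_panel(),
                              burden_mean = 15,
                              burden_dispersion = 1,
                              uv_fraction_mean = 0.8,
                              uv_fraction_concentration = 25,
                              cc_tt_fraction = 0.0014,
                              dipyrimidine_fraction = 0.98,
                              baseline_hazard = 0.014,
                              target_event_fraction = 0.52,
                              age_mean = 58,
                              age_sd = 13,
                              lag_mean_months = 12,
                              rna_expressed_prob = 0.6,
                              rna_depth_mean = 40,
                              rna_depth_dispersion = 5,
                              maf_shape1 = 2,
                              maf_shape2 = 4,
                              n_background_genes = 300,
                              seed = NULL) {
  if (!is_scalar_number(n_samples) || n_samples < 0 || n_samples != round(n_samples)) {
    stop_config("n_samples must be a nonnegative integer")
  }
  if (!is.data.frame(gene_panel) ||
      !all(c("gene", "prevalence", "log_hr") %in% names(gene_panel))) {
    stop_config("gene_panel must be a data.frame(gene, prevalence, log_hr)")
  }
  if (anyDuplicated(gene_panel$gene)) stop_config("duplicate genes in panel")
  if (any(!is.finite(gene_panel$prevalence)) ||
      any(gene_panel$prevalence < 0 | gene_panel$prevalence > 1)) {
    stop_config("gene prevalences must lie in [0,1]")
  }
  if (any(!is.finite(gene_panel$log_hr))) stop_config("log_hr must be finite")
  if (!is_scalar_number(burden_mean) || burden_mean < 0) {
    stop_config("burden_mean must be >= 0")
  }
  if (!is_scalar_number(burden_dispersion) || burden_dispersion <= 0) {
    stop_config("burden_dispersion must be > 0")
  }
  check_fraction(uv_fraction_mean, "uv_fraction_mean")
  if (!is_scalar_number(uv_fraction_concentration) || uv_fraction_concentration <= 0) {
    stop_config("uv_fraction_concentration must be > 0")
  }
  check_fraction(cc_tt_fraction, "cc_tt_fraction")
  check_fraction(dipyrimidine_fraction, "dipyrimidine_fraction")
  if (!is_scalar_number(baseline_hazard) || baseline_hazard <= 0) {
    stop_config("baseline_hazard must be > 0")
  }
  check_fraction(target_event_fraction, "target_event_fraction")
  if (!is_scalar_number(age_mean) || age_mean <= 0 ||
      !is_scalar_number(age_sd) || age_sd < 0) {
    stop_config("age_mean must be > 0 and age_sd >= 0")
  }
  if (!is_scalar_number(lag_mean_months) || lag_mean_months < 0) {
    stop_config("lag_mean_months must be >= 0")
  }
  if (any(rna_expressed_prob < 0 | rna_expressed_prob > 1) ||
      anyNA(rna_expressed_prob)) {
    stop_config("rna_expressed_prob must lie in [0,1]")
  }
  if (!is_scalar_number(maf_shape1) || maf_shape1 <= 0 ||
      !is_scalar_number(maf_shape2) || maf_shape2 <= 0) {
    stop_config("maf_shape parameters must be > 0")
  }
  cfg <- list(
    n_samples = as.integer(n_samples), gene_panel = gene_panel,
    burden_mean = burden_mean, burden_dispersion = burden_dispersion,
    uv_fraction_mean = uv_fraction_mean,
    uv_fraction_concentration = uv_fraction_concentration,
    cc_tt_fraction = cc_tt_fraction,
    dipyrimidine_fraction = dipyrimidine_fraction,
    baseline_hazard = baseline_hazard,
    target_event_fraction = target_event_fraction,
    age_mean = age_mean, age_sd = age_sd,
    lag_mean_months = lag_mean_months,
    rna_expressed_prob = rna_expressed_prob,
    rna_depth_mean = rna_depth_mean,
    rna_depth_dispersion = rna_depth_dispersion,
    maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
    n_background_genes = as.integer(n_background_genes),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# Substitution classes for non-UV background variants: everything except
# C>T / G>A, so the UV fraction of the cohort is exactly the per-sample
# Bernoulli rate.
NON_UV_SUBS <- matrix(c(
  "C", "A", "C", "G", "T", "A", "T", "C", "T", "G", "A", "C"
), ncol = 2, byrow = TRUE)

draw_variant_alleles <- function(is_uv, uv_is_cctt, uv_is_dipyr, cfg) {
  n <- length(is_uv)
  ref <- alt <- c5 <- c3 <- character(n)

  uv_sgl <- which(is_uv & !uv_is_cctt)
  if (length(uv_sgl) > 0) {
    ref[uv_sgl] <- "C"
    alt[uv_sgl] <- "T"
    dip <- uv_is_dipyr[uv_sgl]
    # dipyrimidine: at least one pyrimidine neighbor; pick which side, other
    # side free. Non-dipyrimidine: both neighbors purines.
    side5 <- stats::runif(length(uv_sgl)) < 0.5
    c5[uv_sgl] <- ifelse(dip & side5, sample(PYRIMIDINES, length(uv_sgl), TRUE),
                         sample(PURINES, length(uv_sgl), TRUE))
    c3[uv_sgl] <- ifelse(dip & !side5, sample(PYRIMIDINES, length(uv_sgl), TRUE),
                         ifelse(dip, sample(c("A", "C", "G", "T"), length(uv_sgl), TRUE),
                                sample(PURINES, length(uv_sgl), TRUE)))
  }
  uv_di <- which(is_uv & uv_is_cctt)
  if (length(uv_di) > 0) {
    ref[uv_di] <- "CC"
    alt[uv_di] <- "TT"
    c5[uv_di] <- sample(c("A", "C", "G", "T"), length(uv_di), TRUE)
    c3[uv_di] <- sample(c("A", "C", "G", "T"), length(uv_di), TRUE)
  }
  bg <- which(!is_uv)
  if (length(bg) > 0) {
    pick <- sample(nrow(NON_UV_SUBS), length(bg), TRUE)
    ref[bg] <- NON_UV_SUBS[pick, 1]
    alt[bg] <- NON_UV_SUBS[pick, 2]
    c5[bg] <- sample(c("A", "C", "G", "T"), length(bg), TRUE)
    c3[bg] <- sample(c("A", "C", "G", "T"), length(bg), TRUE)
  }

  # report about half the calls on the purine strand (reverse-complemented),
  # as variant callers do; classification folds them back
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    rc2 <- function(s) chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(b)
      paste(rev(b), collapse = ""), character(1)))
    new5 <- complement_base(c3[flip])
    new3 <- complement_base(c5[flip])
    ref[flip] <- rc2(ref[flip])
    alt[flip] <- rc2(alt[flip])
    c5[flip] <- new5
    c3[flip] <- new3
  }
  data.frame(ref = ref, alt = alt, context5 = c5, context3 = c3,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic metastatic-melanoma-like cohort
#'
#' Generates, from one [simulation_config()] and one seed, every input the
#' downstream analysis consumes: per-sample somatic variant calls with
#' quality and annotation fields, a clinical table under two
#' overall-survival clocks, per-variant RNA read-support evidence, per-sample
#' gene copy-number/expression profiles, and the underlying carrier matrix.
#'
#' Draws happen in a documented fixed order from the single root seed (ages;
#' gene carriers; survival; lags; clinical labels; background burden; UV
#' fractions; variant details; RNA evidence; omics), so identical config +
#' seed reproduces byte-identical output.
#'
#' Survival: each subject's death hazard is
#' `baseline_hazard * exp(sum of planted log-HRs over carried genes)`; times
#' are exponential, censored at a single administrative cutoff chosen by
#' bisection so the expected event fraction equals the target. The
#' diagnosis clock adds a nonnegative per-subject diagnosis-to-specimen lag
#' to the specimen clock.
#'
#' @param config A `simulation_config` object.
#' @return list of class `melscreen_cohort`: `variants`, `clinical`, `rna`,
#'   `omics` (data.frames), `carriers` (gene x sample 0/1 matrix), `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 50, seed = 1))
#' head(cohort$variants)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_config("config must come from simulation_config()")
  }
  cfg <- config
  n <- cfg$n_samples
  panel <- cfg$gene_panel

  if (n == 0) {
    out <- list(
      variants = empty_variants(),
      clinical = data.frame(
        sample_id = character(), os_dx_months = numeric(),
        os_spec_months = numeric(), event = integer(), age_years = numeric(),
        stage = character(), mol_class = character(), expr_class = character(),
        burden = integer(), stringsAsFactors = FALSE
      ),
      rna = data.frame(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), gene = character(),
        rna_depth = integer(), rna_alt = integer(), stringsAsFactors = FALSE
      ),
      omics = data.frame(
        sample_id = character(), gene = character(), mutated = integer(),
        gistic = integer(), log2_expr = numeric(), stringsAsFactors = FALSE
      ),
      carriers = matrix(0L, nrow = nrow(panel), ncol = 0,
                        dimnames = list(panel$gene, NULL)),
      config = cfg
    )
    class(out) <- "melscreen_cohort"
    return(out)
  }

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## 1. ages
  age <- pmax(18, round(stats::rnorm(n, cfg$age_mean, cfg$age_sd)))

  ## 2. candidate-gene carriers
  carriers <- matrix(
    stats::rbinom(nrow(panel) * n, 1, rep(panel$prevalence, times = n)),
    nrow = nrow(panel), ncol = n, dimnames = list(panel$gene, sample_ids)
  )

  ## 3. survival under the specimen clock
  hazard <- cfg$baseline_hazard * exp(as.numeric(crossprod(carriers, panel$log_hr)))
  t_event <- stats::rexp(n, hazard)
  cutoff <- censor_cutoff(hazard, cfg$target_event_fraction)
  event <- as.integer(t_event <= cutoff)
  os_spec <- pmin(t_event, cutoff)

  ## 4. diagnosis-to-specimen lag -> diagnosis clock
  lag <- if (cfg$lag_mean_months > 0) {
    stats::rgamma(n, shape = 2, scale = cfg$lag_mean_months / 2)
  } else {
    rep(0, n)
  }
  os_dx <- os_spec + lag

  ## 5. clinical labels
  stage <- sample(c("III", "IV"), n, TRUE, prob = c(0.62, 0.38))
  mol_class <- sample(c("BRAF_hotspot", "RAS_hotspot", "NF1", "TWT"),
                      n, TRUE, prob = c(0.45, 0.28, 0.10, 0.17))
  expr_class <- sample(c("immune-high", "keratin", "MITF-low"),
                       n, TRUE, prob = c(0.30, 0.40, 0.30))

  ## 6. background burden and 7. per-sample UV fraction
  bg_count <- stats::rnbinom(n, size = cfg$burden_dispersion, mu = cfg$burden_mean)
  a <- cfg$uv_fraction_mean * cfg$uv_fraction_concentration
  b <- (1 - cfg$uv_fraction_mean) * cfg$uv_fraction_concentration
  uv_frac <- if (cfg$uv_fraction_mean %in% c(0, 1)) {
    rep(cfg$uv_fraction_mean, n)
  } else {
    stats::rbeta(n, a, b)
  }

  ## 8. variant records: one per carried candidate gene + background calls
  planted_idx <- which(carriers == 1L, arr.ind = TRUE)
  v_sample <- c(sample_ids[planted_idx[, "col"]],
                rep(sample_ids, times = bg_count))
  v_gene <- c(panel$gene[planted_idx[, "row"]],
              sample(sprintf("BG%04d", seq_len(cfg$n_background_genes)),
                     sum(bg_count), TRUE))
  v_planted <- c(rep(TRUE, nrow(planted_idx)), rep(FALSE, sum(bg_count)))
  nv <- length(v_sample)

  is_uv <- stats::rbinom(nv, 1, uv_frac[match(v_sample, sample_ids)]) == 1
  uv_is_cctt <- stats::runif(nv) < cfg$cc_tt_fraction
  uv_is_dipyr <- stats::runif(nv) < cfg$dipyrimidine_fraction
  alleles <- draw_variant_alleles(is_uv, uv_is_cctt, uv_is_dipyr, cfg)

  depth <- stats::rnbinom(nv, size = 8, mu = 80) + 20L
  true_maf <- stats::rbeta(nv, cfg$maf_shape1, cfg$maf_shape2)
  mac <- stats::rbinom(nv, depth, true_maf)
  maf <- round(mac / depth, 4)

  impact <- character(nv)
  impact[v_planted] <- sample(c("HIGH", "MODERATE"), sum(v_planted), TRUE,
                              prob = c(0.3, 0.7))
  impact[!v_planted] <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                               sum(!v_planted), TRUE,
                               prob = c(0.05, 0.35, 0.25, 0.35))
  flags <- rep("", nv)
  flg <- stats::runif(nv)
  flags[flg < 0.02] <- "oxog_suspect"
  flags[flg >= 0.02 & flg < 0.03] <- "germline_suspect"

  variants <- data.frame(
    sample_id = v_sample,
    chrom = paste0("chr", sample(1:22, nv, TRUE)),
    pos = sample.int(1e8, nv, replace = TRUE),
    ref = alleles$ref, alt = alleles$alt,
    gene = v_gene, impact = impact,
    maf = maf, mac = as.integer(mac),
    context5 = alleles$context5, context3 = alleles$context3,
    flags = flags, stringsAsFactors = FALSE
  )

  ## 9. RNA evidence, one row per DNA call
  p_expr <- if (length(cfg$rna_expressed_prob) > 1) {
    pe <- cfg$rna_expressed_prob[variants$gene]
    pe[is.na(pe)] <- mean(cfg$rna_expressed_prob)
    unname(pe)
  } else {
    rep(cfg$rna_expressed_prob, nv)
  }
  expressed <- stats::runif(nv) < p_expr
  covered_ref <- !expressed & stats::runif(nv) < 0.5   # covered but reference-only
  rna_depth <- integer(nv)
  rna_alt <- integer(nv)
  has_cov <- expressed | covered_ref
  rna_depth[has_cov] <- stats::rnbinom(sum(has_cov),
                                       size = cfg$rna_depth_dispersion,
                                       mu = cfg$rna_depth_mean) + 1L
  # expressed calls: RNA allele fraction at least the DNA fraction (expressed
  # alleles are never underrepresented here), floored at 0.2
  rna_alt[expressed] <- stats::rbinom(sum(expressed), rna_depth[expressed],
                                      pmax(true_maf[expressed], 0.2))
  rna <- data.frame(
    sample_id = variants$sample_id, chrom = variants$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    gene = variants$gene,
    rna_depth = rna_depth, rna_alt = rna_alt,
    stringsAsFactors = FALSE
  )

  ## 10. omics profiles for panel genes
  ng <- nrow(panel)
  gistic <- sample(c(-2L, -1L, 0L, 1L, 2L), ng * n, TRUE,
                   prob = c(0.02, 0.08, 0.80, 0.08, 0.02))
  omics <- data.frame(
    sample_id = rep(sample_ids, each = ng),
    gene = rep(panel$gene, times = n),
    mutated = as.integer(carriers[cbind(rep(seq_len(ng), n),
                                        rep(seq_len(n), each = ng))]),
    gistic = gistic,
    log2_expr = round(stats::rnorm(ng * n, 8 + 0.9 * gistic, 1.2), 4),
    stringsAsFactors = FALSE
  )

  clinical <- data.frame(
    sample_id = sample_ids,
    os_dx_months = round(os_dx, 3),
    os_spec_months = round(os_spec, 3),
    event = event,
    age_years = age,
    stage = stage,
    mol_class = mol_class,
    expr_class = expr_class,
    burden = as.integer(colSums(carriers) + bg_count),
    stringsAsFactors = FALSE
  )

  out <- list(variants = variants, clinical = clinical, rna = rna,
              omics = omics, carriers = carriers, config = cfg)
  class(out) <- "melscreen_cohort"
  out
}

#' @export
print.melscreen_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$clinical), "samples,",
      nrow(x$variants), "variant calls,",
      nrow(x$config$gene_panel), "panel genes\n")
  cat("Events:", sum(x$clinical$event), sprintf("(%.1f%%)",
      100 * mean(x$clinical$event)), "\n")
  invisible(x)
}
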