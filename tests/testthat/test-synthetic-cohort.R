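test_that("configuration validation rejects out-of-range values", {
  expect_error(simulation_config(n_samples = -1), class = "melscreen_config_error")
  expect_error(simulation_config(uv_fraction_mean = 1.2), class = "melscreen_config_error")
  expect_error(simulation_config(burden_mean = -3), class = "melscreen_config_error")
  expect_error(simulation_config(target_event_fraction = NaN), class = "melscreen_config_error")
  panel <- default_gene_panel()
  panel$prevalence[1] <- 2
  expect_error(simulation_config(gene_panel = panel), class = "melscreen_config_error")
})

test_that("an empty cohort yields empty tables with valid headers", {
  co <- simulate_cohort(simulation_config(n_samples = 0, seed = 1))
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$clinical), 0)
  expect_equal(nrow(co$rna), 0)
  expect_true(all(c("sample_id", "maf", "mac", "context5") %in% names(co$variants)))
  expect_true(all(c("os_dx_months", "os_spec_months", "event") %in% names(co$clinical)))
  expect_equal(ncol(co$carriers), 0)
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- simulation_config(n_samples = 80, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (tab in c("variants", "clinical", "rna", "omics")) {
    expect_identical(a[[tab]], b[[tab]])
  }
  expect_identical(a$carriers, b$carriers)
  # serialized forms agree byte for byte
  fa <- tempfile(fileext = ".tsv"); fb <- tempfile(fileext = ".tsv")
  write_variants_tsv(a$variants, fa)
  write_variants_tsv(b$variants, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)), readBin(fb, "raw", file.size(fb)))
})

test_that("pooled C>T fraction tracks the configured UV fraction", {
  co <- simulate_cohort(simulation_config(n_samples = 500, uv_fraction_mean = 0.8,
                                          seed = 1))
  s <- summarize_spectrum(co$variants, "pooled")
  # 99% binomial interval around 0.8 at the realized mutation count
  half <- qnorm(0.995) * sqrt(0.8 * 0.2 / s$n_total)
  uv_total <- s$frac_c_to_t + s$frac_cc_to_tt
  expect_gt(uv_total, 0.8 - half)
  expect_lt(uv_total, 0.8 + half)
  # the dinucleotide class stays tiny
  expect_lt(s$frac_cc_to_tt, 0.01)
})

test_that("planted prevalence and event fraction hit their targets", {
  panel <- data.frame(gene = "NTRK1", prevalence = 0.053, log_hr = log(1.93))
  cfg <- simulation_config(n_samples = 245, gene_panel = panel,
                           target_event_fraction = 0.70, seed = 7)
  co <- simulate_cohort(cfg)
  carriers <- sum(co$carriers["NTRK1", ])
  expected <- 0.053 * 245
  half <- qnorm(0.995) * sqrt(245 * 0.053 * 0.947)
  expect_gt(carriers, expected - half)
  expect_lt(carriers, expected + half)
  expect_lt(abs(mean(co$clinical$event) - 0.70), 0.05)
})

test_that("censoring controls the event fraction", {
  # at n = 1000 the +-0.05 band is a > 3 sigma statement per cohort
  for (s in 1:4) {
    cfg <- simulation_config(n_samples = 1000, target_event_fraction = 0.52,
                             seed = 100 + s)
    co <- simulate_cohort(cfg)
    expect_lt(abs(mean(co$clinical$event) - 0.52), 0.05)
  }
  # at n = 200 the control is in expectation: average over cohorts
  fr <- vapply(1:10, function(s) {
    mean(simulate_cohort(simulation_config(
      n_samples = 200, target_event_fraction = 0.52, seed = 200 + s
    ))$clinical$event)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.52), 0.02)
})

test_that("burden is overdispersed with a median near ten mutations", {
  co <- simulate_cohort(simulation_config(n_samples = 400, seed = 9))
  b <- co$clinical$burden
  expect_true(median(b) >= 8 && median(b) <= 13)
  expect_gt(var(b) / mean(b), 2)          # well above Poisson
  expect_gt(max(b), 50)                   # long right tail
})

test_that("diagnosis clock equals specimen clock plus a nonnegative lag", {
  co <- simulate_cohort(simulation_config(n_samples = 100, seed = 10))
  lag <- co$clinical$os_dx_months - co$clinical$os_spec_months
  expect_true(all(lag >= 0))
  expect_gt(mean(lag), 0)
})

test_that("null-gene screen p-values are uniform", {
  set.seed(55)
  panel <- data.frame(gene = sprintf("N%04d", 1:1000), prevalence = 0.15, log_hr = 0)
  co <- simulate_cohort(simulation_config(
    n_samples = 150, gene_panel = panel, target_event_fraction = 0.6, seed = 55
  ))
  scr <- screen_genes(co$carriers, co$clinical, "specimen", age_adjust = FALSE)
  p <- scr$p[scr$estimable]
  expect_gt(length(p), 900)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("a strongly planted gene is recovered inside its own confidence interval", {
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    panel <- data.frame(gene = "G", prevalence = 0.2, log_hr = log(3))
    co <- simulate_cohort(simulation_config(
      n_samples = 400, gene_panel = panel, target_event_fraction = 0.6,
      seed = 1000 + i
    ))
    fit <- fit_cox(co$clinical$os_spec_months, co$clinical$event,
                   co$carriers["G", ])
    if (fit$estimable && fit$ci_low <= 3 && 3 <= fit$ci_high) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})
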