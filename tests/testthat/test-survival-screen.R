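test_that("BH adjustment matches brute force and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)                       # single p unchanged
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))         # all equal unchanged
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "melscreen_validation_error")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("Cox fit recovers a large-sample hazard ratio", {
  set.seed(41)
  n <- 10000
  x <- rbinom(n, 1, 0.3)
  t <- rexp(n, 0.05 * 2^x)
  fit <- fit_cox(t, rep(1L, n), x)
  expect_true(fit$estimable)
  expect_gt(fit$hr, 1.9)
  expect_lt(fit$hr, 2.1)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_lt(fit$p, 1e-10)
})

test_that("degenerate Cox inputs are flagged unestimable, never an error", {
  t <- c(3, 5, 8, 2, 9, 4)
  expect_false(fit_cox(t, rep(0L, 6), c(1, 0, 1, 0, 1, 0))$estimable)  # no events
  allz <- fit_cox(t, rep(1L, 6), rep(0L, 6))
  expect_false(allz$estimable)
  expect_match(allz$reason, "constant")
})

test_that("Cox coefficient maximizes the Efron partial likelihood (hand dataset)", {
  # six subjects, tied event times at t = 5
  time <- c(5, 5, 8, 8, 11, 14)
  event <- c(1, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 0, 0, 1)
  fit <- fit_cox(time, event, x)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event, x = x)
  beta_grid <- grid[which.max(ll)]
  expect_equal(log(fit$hr), beta_grid, tolerance = 1e-3)
})

test_that("Efron and Breslow tie handling agree when there are no ties", {
  set.seed(43)
  n <- 120
  x <- rbinom(n, 1, 0.3)
  t <- rexp(n, 0.05 * 1.8^x)                    # continuous: no ties
  ev <- rbinom(n, 1, 0.8)
  efron <- fit_cox(t, ev, x)
  breslow <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
  expect_equal(log(efron$hr), unname(coef(breslow)), tolerance = 1e-10)
})

test_that("gene screen adjusts FDR within one origin and labels tiers", {
  set.seed(47)
  co <- simulate_cohort(simulation_config(n_samples = 250, seed = 47))
  scr <- screen_genes(co$carriers, co$clinical, "specimen")
  ok <- scr$estimable
  expect_equal(scr$fdr[ok], bh_brute_force(scr$p[ok]), tolerance = 1e-12)
  expect_true(all(scr$tier[!ok] == "unestimable"))
  expect_true(all(scr$tier[ok & scr$fdr <= 0.2] == "FDR<=0.2"))

  # identical clinical under both origins gives identical screens
  cl <- co$clinical
  cl$os_dx_months <- cl$os_spec_months
  a <- screen_genes(co$carriers, cl, "dx")
  b <- screen_genes(co$carriers, cl, "specimen")
  expect_equal(a[, setdiff(names(a), "time_origin")],
               b[, setdiff(names(b), "time_origin")])

  # empty candidate list: empty table, no failure
  empty <- screen_genes(co$carriers[character(0), , drop = FALSE], cl, "dx")
  expect_equal(nrow(empty), 0)
})

test_that("log-rank test matches the from-scratch O-E oracle and survdiff", {
  # eight subjects with a tie and censoring
  time <- c(2, 4, 4, 6, 7, 9, 12, 15)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  group <- c(1, 1, 0, 1, 0, 0, 1, 0)
  res <- km_logrank(time, event, group)
  oracle <- logrank_oracle(time, event, group)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-6)
  expect_equal(res$p, pchisq(oracle$chisq, 1, lower.tail = FALSE), tolerance = 1e-6)

  # identical time/event multisets in both groups: statistic 0, p 1
  res2 <- km_logrank(rep(c(3, 6, 9), 2), rep(c(1, 1, 0), 2), rep(c(0, 1), each = 3))
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)

  # all censored: no event contributes
  res3 <- km_logrank(c(5, 6, 7, 8), rep(0L, 4), c(0, 0, 1, 1))
  expect_equal(res3$chisq, 0)
  expect_equal(res3$p, 1)
  expect_error(km_logrank(time, event, rep(1, 8)), class = "melscreen_config_error")
})

test_that("KM curves are proper product-limit estimates", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  group <- c(0, 0, 0, 1, 1, 1)
  res <- km_logrank(time, event, group)
  g0 <- res$curves[res$curves$group == "0", ]
  expect_equal(g0$surv, c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  expect_true(all(diff(res$curves$surv[res$curves$group == "1"]) <= 0))
})

test_that("power simulation is calibrated and monotone in effect size and n", {
  null_cal <- power_by_simulation(245, 0.053, 1.0, 0.70, n_reps = 1500, seed = 61)
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lt(abs(null_cal$power - 0.05), 3 * se)

  big <- power_by_simulation(245, 0.053, 5, 0.70, n_reps = 600, seed = 62)
  expect_gt(big$power, 0.99)

  mid <- power_by_simulation(245, 0.053, 1.93, 0.70, n_reps = 600, seed = 63)
  expect_gt(big$power, mid$power)
  expect_gt(mid$power, null_cal$power)

  larger_n <- power_by_simulation(600, 0.053, 1.93, 0.70, n_reps = 600, seed = 64)
  expect_gt(larger_n$power, mid$power)

  expect_warning(power_by_simulation(100, 0.1, 2, 0.7, n_reps = 50, seed = 65),
                 "n_reps")
  expect_error(power_by_simulation(100, 0, 2, 0.7), class = "melscreen_config_error")
})

test_that("analytic Schoenfeld approximation sits near the simulation for common carriers", {
  # at prevalence 0.3 the event-overrepresentation bias is mild
  sim <- power_by_simulation(200, 0.3, 1.8, 0.7, n_reps = 1500, seed = 71)
  ana <- power_schoenfeld(200, 0.3, 1.8, 0.7)
  expect_lt(abs(sim$power - ana), 0.08)
})
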