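# Independent oracles used to check the package's statistics. Each is a
# deliberately naive from-scratch computation, kept separate from the code
# paths it verifies.

# Quadratic-time Benjamini-Hochberg step-up: adjusted p_i = min over all j
# with p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")[o]  # ranks in sorted order = 1..m
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Closed-form Pearson chi-square for a 2x2 table.
chisq_2x2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Efron partial log-likelihood for a single binary covariate, computed by
# direct summation over unique event times.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

# From-scratch log-rank statistic: sum of observed-minus-expected events in
# group 1 over event times, with the hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  list(o_minus_e = o_minus_e, var = v, chisq = chisq)
}

# Exact two-sided rank-sum p by explicit enumeration of every assignment of
# the pooled values to group A (positions, not ranks, so ties are handled by
# re-ranking each assignment's complement identically).
rank_sum_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  e_w <- nx * mean(r)
  sets <- combn(n, nx)
  ws <- apply(sets, 2, function(s) sum(r[s]))
  mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# Small helper to build variant tables in tests.
make_variants <- function(n = 1, sample_id = "S1", gene = "BRAF",
                          impact = "MODERATE", maf = 0.3, mac = 20,
                          ref = "C", alt = "T", context5 = "T", context3 = "A",
                          chrom = "chr7", pos = NULL, flags = "") {
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  data.frame(
    sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
    pos = rep_len(pos, n), ref = rep_len(ref, n), alt = rep_len(alt, n),
    gene = rep_len(gene, n), impact = rep_len(impact, n),
    maf = rep_len(maf, n), mac = rep_len(mac, n),
    context5 = rep_len(context5, n), context3 = rep_len(context3, n),
    flags = rep_len(flags, n), stringsAsFactors = FALSE
  )
}
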