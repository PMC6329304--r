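test_that("substitution classes follow the UV-signature definitions", {
  expect_equal(classify_substitution("C", "T", "T", "A")[1], "C_TO_T_DIPYRIMIDINE")
  expect_equal(classify_substitution("C", "T", "A", "G")[1], "C_TO_T_OTHER")
  # purine-strand record: G>A with 3' G is C>T with 5' C on the pyrimidine strand
  expect_equal(classify_substitution("G", "A", "A", "G")[1], "C_TO_T_DIPYRIMIDINE")
  expect_equal(classify_substitution("A", "G", "C", "C")[1], "NON_UV")
  expect_equal(classify_substitution("CC", "TT", "A", "A")[1], "CC_TO_TT")
  expect_equal(classify_substitution("GG", "AA", "A", "A")[1], "CC_TO_TT")
  expect_equal(classify_substitution("CA", "TG", "A", "A")[1], "NON_UV")
})

test_that("ambiguous bases go to NON_UV with a warning; indels are rejected", {
  expect_warning(cls <- classify_substitution("N", "T", "A", "A"))
  expect_equal(cls[1], "NON_UV")
  expect_equal(attr(cls, "n_ambiguous"), 1L)
  expect_error(classify_substitution("C", "TT", "A", "A"),
               class = "melscreen_validation_error")
  expect_error(classify_substitution("CAT", "TGC", "A", "A"),
               class = "melscreen_validation_error")
})

test_that("classification is invariant under reverse complement, exhaustively", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  subs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]          # 12 substitution types
  ctx <- expand.grid(c5 = bases, c3 = bases, stringsAsFactors = FALSE)  # 16 contexts
  for (i in seq_len(nrow(subs))) {
    for (j in seq_len(nrow(ctx))) {
      fwd <- classify_substitution(subs$ref[i], subs$alt[i], ctx$c5[j], ctx$c3[j])
      rev <- classify_substitution(comp[subs$ref[i]], comp[subs$alt[i]],
                                   comp[ctx$c3[j]], comp[ctx$c5[j]])
      expect_equal(fwd[1], rev[1],
                   label = paste(subs$ref[i], subs$alt[i], ctx$c5[j], ctx$c3[j]))
    }
  }
})

test_that("spectrum fractions count correctly and partition the classes", {
  v <- rbind(
    make_variants(6, ref = "C", alt = "T", context5 = "T"),             # dipyrimidine
    make_variants(2, ref = "C", alt = "T", context5 = "A", context3 = "G"),
    make_variants(2, ref = "A", alt = "G")
  )
  s <- summarize_spectrum(v, "pooled")
  expect_equal(s$frac_c_to_t, 0.8)
  expect_equal(s$frac_c_to_t_dipyrimidine, 0.6)
  expect_equal(s$frac_cc_to_tt, 0)
  # four classes partition the classifiable records
  expect_equal(s$frac_c_to_t + s$frac_cc_to_tt + s$frac_non_uv, 1)

  expect_equal(summarize_spectrum(make_variants(3, ref = "A", alt = "G"),
                                  "pooled")$frac_c_to_t, 0)
  cc <- summarize_spectrum(make_variants(1, ref = "CC", alt = "TT"), "pooled")
  expect_equal(cc$frac_cc_to_tt, 1)

  empty <- summarize_spectrum(make_variants(0)[0, ], "pooled")
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$frac_c_to_t))   # flagged, not silently zero
})

test_that("per-sample summaries respect sample scopes", {
  v <- rbind(
    make_variants(4, sample_id = "S1", ref = "C", alt = "T", context5 = "C"),
    make_variants(4, sample_id = "S2", ref = "T", alt = "G")
  )
  s <- summarize_spectrum(v, "sample")
  expect_equal(s$frac_c_to_t[s$scope == "S1"], 1)
  expect_equal(s$frac_c_to_t[s$scope == "S2"], 0)
})

test_that("rank-sum comparison reproduces exact and degenerate cases", {
  expect_equal(compare_spectra(c(0.5, 0.5), c(0.5, 0.5))$p, 1)  # all ties
  expect_equal(compare_spectra(c(1, 2, 3), c(4, 5, 6))$p, 0.1)  # 2 / choose(6,3)
  set.seed(3)
  g <- runif(6)
  expect_equal(compare_spectra(g, sample(g))$p, 1)              # permutation of itself
  expect_error(compare_spectra(numeric(0), c(1)), class = "melscreen_config_error")
})

test_that("exact rank-sum agrees with enumeration oracle and wilcox.test (n <= 8)", {
  pools <- list(
    c(1.2, 3.4, 0.5, 7.7, 2.2, 9.1),              # distinct, n = 6
    c(1, 1, 2, 3, 3, 3, 4),                       # heavy ties, n = 7
    c(0.1, 0.2, 0.2, 0.5, 0.9, 1.4, 1.4, 2.0)     # ties, n = 8
  )
  for (pool in pools) {
    n <- length(pool)
    for (nx in 1:(n - 1)) {
      sets <- combn(n, nx)
      for (k in seq_len(ncol(sets))) {
        x <- pool[sets[, k]]
        y <- pool[-sets[, k]]
        p_pkg <- compare_spectra(x, y)$p
        expect_equal(p_pkg, rank_sum_enumeration_oracle(x, y),
                     tolerance = 1e-12)
        if (!any(duplicated(pool))) {
          p_ref <- wilcox.test(x, y, exact = TRUE)$p.value
          expect_equal(p_pkg, p_ref, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("large-sample rank-sum path matches the tie-corrected normal reference", {
  set.seed(5)
  x <- round(rbeta(30, 4, 2), 2)
  y <- round(rbeta(25, 2, 4), 2)
  p_pkg <- compare_spectra(x, y)$p
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  expect_equal(compare_spectra(x, y)$method, "normal")
})
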