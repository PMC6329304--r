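make_matrix <- function(counts, n_samples) {
  # counts: named vector, mutated-sample count per gene
  mat <- matrix(0L, nrow = length(counts), ncol = n_samples,
                dimnames = list(names(counts), sprintf("S%04d", seq_len(n_samples))))
  for (i in seq_along(counts)) mat[i, seq_len(counts[i])] <- 1L
  mat
}

test_that("prevalence threshold is ceiling(fraction x n), inclusive", {
  mat <- make_matrix(c(A = 11, B = 10, C = 50), 356)
  kept <- prevalence_filter(mat, 0.03)
  expect_equal(kept, c("A", "C"))   # ceil(0.03*356) = 11: 11 in, 10 out
  mat2 <- make_matrix(c(A = 3, B = 2), 100)
  expect_equal(prevalence_filter(mat2, 0.03), "A")   # threshold 3
  # strict alternative shifts the boundary by one
  expect_equal(prevalence_filter(mat, 0.03, rule = "greater_than_ceiling"), "C")
  expect_error(prevalence_filter(mat, 0), class = "melscreen_config_error")
  expect_error(prevalence_filter(mat, 1.5), class = "melscreen_config_error")
})

test_that("raising the prevalence threshold never adds genes", {
  set.seed(21)
  mat <- matrix(rbinom(40 * 200, 1, 0.08), nrow = 40,
                dimnames = list(sprintf("G%02d", 1:40), sprintf("S%03d", 1:200)))
  kept <- lapply(c(0.01, 0.03, 0.05, 0.10, 0.2), function(f)
    prevalence_filter(mat, f))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("fold statistic reproduces hand arithmetic, including boundaries", {
  # 100 deceased then 100 alive
  status <- rep(c(TRUE, FALSE), each = 100)
  mat <- matrix(0L, nrow = 1, ncol = 200,
                dimnames = list("G", sprintf("S%03d", 1:200)))
  mat[1, c(1:10, 101:110)] <- 1L         # 10/100 vs 10/100
  fs <- fold_statistic(mat, status)
  expect_equal(fs$x, 1.0)
  expect_false(fs$selected)

  # cohort sizes 185 deceased / 171 alive, 20 vs 8 mutated
  status2 <- rep(c(TRUE, FALSE), c(185, 171))
  mat2 <- matrix(0L, nrow = 1, ncol = 356,
                 dimnames = list("G", sprintf("S%03d", 1:356)))
  mat2[1, c(1:20, 186:193)] <- 1L
  fs2 <- fold_statistic(mat2, status2)
  expect_equal(fs2$x, (20 / 185) / (8 / 171), tolerance = 1e-12)
  expect_equal(round(fs2$x, 2), 2.31)
  expect_true(fs2$selected)

  # mutated only among the deceased: infinite fold, selected
  mat3 <- mat2; mat3[1, ] <- 0L; mat3[1, 1:3] <- 1L
  fs3 <- fold_statistic(mat3, status2)
  expect_equal(fs3$x, Inf)
  expect_true(fs3$selected)

  # mutated nowhere: undefined, not selected
  mat4 <- mat2; mat4[1, ] <- 0L
  fs4 <- fold_statistic(mat4, status2)
  expect_true(is.na(fs4$x))
  expect_false(fs4$selected)

  expect_error(fold_statistic(mat2, rep(TRUE, 356)),
               class = "melscreen_config_error")
})

test_that("swapping deceased/alive inverts finite folds and maps the band onto itself", {
  set.seed(13)
  n <- 240
  status <- sample(c(TRUE, FALSE), n, TRUE)
  mat <- matrix(rbinom(20 * n, 1, 0.15), nrow = 20,
                dimnames = list(sprintf("G%02d", 1:20), sprintf("S%03d", 1:n)))
  a <- fold_statistic(mat, status)
  b <- fold_statistic(mat, !status)
  fin <- is.finite(a$x) & a$x > 0
  expect_equal(b$x[fin], 1 / a$x[fin], tolerance = 1e-12)
  # with the symmetric band (1.5, 1/1.5) selection is exactly preserved
  a_sym <- fold_statistic(mat, status, upper = 1.5, lower = 1 / 1.5)
  b_sym <- fold_statistic(mat, !status, upper = 1.5, lower = 1 / 1.5)
  expect_equal(a_sym$selected[fin], b_sym$selected[fin])
})

test_that("label association is the uncorrected Pearson chi-square", {
  # perfectly independent table: statistic 0, p 1
  mutated <- rep(c(1, 0), each = 20)
  labels <- rep(c("a", "b"), 20)
  res <- association_with_label(mutated, labels)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # [[30,10],[10,30]]: statistic 20 (all expected counts 20)
  mutated2 <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  labels2 <- rep(c("a", "b", "a", "b"), c(30, 10, 10, 30))
  res2 <- association_with_label(mutated2, labels2)
  expect_equal(res2$statistic, 20)
  expect_true(all(res2$expected == 20))

  expect_error(association_with_label(mutated, rep("a", 40)),
               class = "melscreen_config_error")
  expect_warning(association_with_label(mutated, factor(labels, levels = c("a", "b", "c"))),
                 "empty label level")
})

test_that("chi-square agrees with the 2x2 closed form on random tables", {
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(sample(5:60, 4, TRUE), 2)
    mutated <- rep(c(0, 0, 1, 1), as.vector(t(tab)))
    labels <- rep(c("a", "b", "a", "b"), as.vector(t(tab)))
    res <- suppressWarnings(association_with_label(mutated, labels))
    expect_equal(res$statistic,
                 chisq_2x2_closed_form(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("burden association uses exact rank-sum and BH across genes", {
  mat <- matrix(c(1, 1, 1, 0, 0, 0), nrow = 1,
                dimnames = list("G1", sprintf("S%d", 1:6)))
  burden <- c(100, 90, 80, 1, 2, 3)
  res <- association_with_burden(mat, burden)
  expect_equal(res$p, 0.1)          # exact enumeration, n = 6
  expect_equal(res$fdr, res$p)      # single gene: BH identity

  # identical burden distributions: p = 1
  mat2 <- matrix(rep(c(1, 0), each = 4), nrow = 1,
                 dimnames = list("G1", sprintf("S%d", 1:8)))
  res2 <- association_with_burden(mat2, rep(c(5, 6, 7, 8), 2))
  expect_equal(res2$p, 1)

  # degenerate gene (all samples mutated) reported as missing
  mat3 <- rbind(G1 = rep(1L, 6), G2 = c(1, 1, 0, 0, 0, 0))
  colnames(mat3) <- sprintf("S%d", 1:6)
  res3 <- association_with_burden(mat3, burden)
  expect_true(is.na(res3$p[res3$gene == "G1"]))
  expect_false(is.na(res3$p[res3$gene == "G2"]))
})

test_that("carrier fraction counts samples with any mutated candidate gene", {
  mat <- make_matrix(c(A = 150, B = 100), 356)
  expect_equal(carrier_fraction(mat), 150 / 356)   # B's carriers nest in A's here
})
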