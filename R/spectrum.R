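#' Classify substitutions into ultraviolet-signature spectrum classes
#'
#' Assigns each substitution to one of four mutually exclusive classes used to
#' characterize UV damage: `C_TO_T_DIPYRIMIDINE` (C>T where the mutated
#' pyrimidine has a pyrimidine neighbor on the pyrimidine-bearing strand),
#' `C_TO_T_OTHER` (C>T without such a neighbor), `CC_TO_TT` (tandem
#' dinucleotide change, the hallmark UV photoproduct), and `NON_UV` (all other
#' substitutions). Calls reported on the purine strand are reverse-complemented
#' first, so `G>A` is classified as `C>T` with its flanks swapped and
#' complemented.
#'
#' Records containing an ambiguous base (`N`) in ref, alt, or a flank that is
#' needed for the decision are classified `NON_UV`; the number of such records
#' is attached as attribute `n_ambiguous` and reported via a warning.
#' Insertions/deletions (ref and alt of unequal length, or length > 2) are
#' rejected: classification applies to substitutions only.
#'
#' @param ref,alt Reference and alternate alleles. Single bases, or two-base
#'   strings for dinucleotide records.
#' @param context5,context3 Single flanking bases 5' and 3' of the variant on
#'   the reported strand. May be `"N"` when unknown.
#' @return Character vector with levels
#'   `C_TO_T_DIPYRIMIDINE`, `C_TO_T_OTHER`, `CC_TO_TT`, `NON_UV`.
#' @examples
#' classify_substitution("C", "T", "T", "A")  # dipyrimidine C>T
#' classify_substitution("G", "A", "A", "G")  # purine strand; same class
#' classify_substitution("CC", "TT", "A", "A")
#' @export
classify_substitution <- function(ref, alt, context5 = "N", context3 = "N") {
  n <- max(length(ref), length(alt), length(context5), length(context3))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  c5 <- toupper(rep_len(as.character(context5), n))
  c3 <- toupper(rep_len(as.character(context3), n))

  if (any(nchar(ref) != nchar(alt)) || any(nchar(ref) > 2) || any(nchar(ref) < 1)) {
    stop_validation("classification applies to substitutions only ",
                    "(ref/alt must be equal-length strings of 1 or 2 bases)")
  }
  if (any(ref == alt)) stop_validation("ref and alt must differ")

  out <- rep("NON_UV", n)
  n_ambiguous <- 0L

  di <- nchar(ref) == 2L
  out[di & (ref == "CC" & alt == "TT" | ref == "GG" & alt == "AA")] <- "CC_TO_TT"

  si <- which(!di)
  if (length(si) > 0) {
    r <- ref[si]; a <- alt[si]; f5 <- c5[si]; f3 <- c3[si]
    bad <- !(r %in% c(PYRIMIDINES, PURINES)) | !(a %in% c(PYRIMIDINES, PURINES))
    n_ambiguous <- n_ambiguous + sum(bad)

    # fold purine-strand calls onto the pyrimidine strand
    flip <- !bad & r %in% PURINES
    if (any(flip)) {
      new5 <- complement_base(f3[flip])
      new3 <- complement_base(f5[flip])
      r[flip] <- complement_base(r[flip])
      a[flip] <- complement_base(a[flip])
      f5[flip] <- new5
      f3[flip] <- new3
    }

    ct <- !bad & r == "C" & a == "T"
    dipyr <- ct & (f5 %in% PYRIMIDINES | f3 %in% PYRIMIDINES)
    out[si[dipyr]] <- "C_TO_T_DIPYRIMIDINE"
    out[si[ct & !dipyr]] <- "C_TO_T_OTHER"
  }

  if (n_ambiguous > 0) {
    warning(n_ambiguous, " record(s) with ambiguous bases classified NON_UV")
  }
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Summarize the UV-signature mutation spectrum
#'
#' Computes, per sample or pooled over the cohort, the fraction of mutations
#' that are C>T (either C>T class), C>T at a dipyrimidine site, and tandem
#' CC>TT. CC>TT events are counted once (as one dinucleotide event), not as
#' two C>T events; `frac_c_to_t` therefore excludes them and
#' `frac_c_to_t_dipyrimidine <= frac_c_to_t` always holds. Denominator is the
#' number of classifiable variants in scope. Scopes with zero classifiable
#' variants get `NA` fractions (flagged, never silently 0).
#'
#' @param variants Variant table with columns `ref`, `alt`, `context5`,
#'   `context3` and, for `group_by = "sample"`, `sample_id`.
#' @param group_by `"pooled"` for one cohort-wide row, `"sample"` for one row
#'   per sample.
#' @return data.frame with columns `scope`, `n_total`, `frac_c_to_t`,
#'   `frac_c_to_t_dipyrimidine`, `frac_cc_to_tt`, `frac_non_uv`.
#' @export
summarize_spectrum <- function(variants, group_by = c("pooled", "sample")) {
  group_by <- match.arg(group_by)
  check_variants(variants, required = c("ref", "alt", "context5", "context3"))

  cls <- if (nrow(variants) > 0) {
    suppressWarnings(classify_substitution(
      variants$ref, variants$alt, variants$context5, variants$context3
    ))
  } else {
    character(0)
  }

  one_scope <- function(scope, k) {
    n <- length(k)
    if (n == 0) {
      return(data.frame(
        scope = scope, n_total = 0L, frac_c_to_t = NA_real_,
        frac_c_to_t_dipyrimidine = NA_real_, frac_cc_to_tt = NA_real_,
        frac_non_uv = NA_real_, stringsAsFactors = FALSE
      ))
    }
    data.frame(
      scope = scope,
      n_total = n,
      frac_c_to_t = sum(k %in% c("C_TO_T_DIPYRIMIDINE", "C_TO_T_OTHER")) / n,
      frac_c_to_t_dipyrimidine = sum(k == "C_TO_T_DIPYRIMIDINE") / n,
      frac_cc_to_tt = sum(k == "CC_TO_TT") / n,
      frac_non_uv = sum(k == "NON_UV") / n,
      stringsAsFactors = FALSE
    )
  }

  if (group_by == "pooled") {
    return(one_scope("pooled", cls))
  }
  samples <- unique(variants$sample_id)
  out <- do.call(rbind, lapply(samples, function(s) {
    one_scope(s, cls[variants$sample_id == s])
  }))
  if (is.null(out)) out <- one_scope(character(0), character(0))[0, ]
  rownames(out) <- NULL
  out
}

# Two-sided Wilcoxon rank-sum (Mann-Whitney) test. Exact permutation
# enumeration over all C(n, nx) group assignments when combined n <= 10
# (valid with ties; two-sided p = probability of a rank sum at least as far
# from its permutation mean as observed); tie-corrected normal approximation
# without continuity correction otherwise.
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop_config("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop_validation("missing values in rank-sum input")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  e_w <- nx * (n + 1) / 2
  u <- w - nx * (nx + 1) / 2

  if (n <= 10) {
    sets <- utils::combn(n, nx)
    ws <- colSums(matrix(r[sets], nrow = nx))
    p <- mean(abs(ws - e_w) >= abs(w - e_w) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - e_w) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(statistic = u, rank_sum = w, p = min(1, p), method = method)
}

#' Compare per-sample UV-signature fractions between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on per-sample spectrum
#' fractions, e.g. UV fractions of primary versus metastatic samples or of
#' retained versus filtered-out mutations. Uses exact permutation enumeration
#' for combined n <= 10 (correct in the presence of ties) and the
#' tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors of per-sample fractions.
#' @return list with `statistic` (Mann-Whitney U), `rank_sum`, `p`, `method`.
#' @examples
#' compare_spectra(c(0.9, 0.85, 0.95), c(0.2, 0.3, 0.1))
#' @export
compare_spectra <- function(group_a, group_b) {
  rank_sum_test(group_a, group_b)
}
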