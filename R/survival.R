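#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity,
#' returned in the input order. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_validation("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "BH")
}

unestimable_row <- function(gene, time_origin, n_mutated, n, reason) {
  if (length(gene) == 0) {
    return(data.frame(
      gene = character(), time_origin = character(), hr = numeric(),
      ci_low = numeric(), ci_high = numeric(), p = numeric(),
      n_mutated = integer(), n = integer(), estimable = logical(),
      reason = character(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    gene = gene, time_origin = time_origin,
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    n_mutated = as.integer(n_mutated), n = as.integer(n),
    estimable = FALSE, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Age-adjusted Cox proportional-hazards fit for one gene
#'
#' Fits a proportional-hazards model with the gene's binary mutation
#' indicator and (optionally) age as covariates, by partial-likelihood
#' maximization with Efron handling of tied event times. Reports the hazard
#' ratio for mutation carriers, its Wald 95% confidence interval from the
#' observed information, and the two-sided Wald p-value.
#'
#' Degenerate inputs (no events, constant mutation indicator) and
#' non-convergent fits produce a row flagged `estimable = FALSE` with a
#' reason, never an error. A monotone-likelihood warning from the fitter
#' (infinite coefficient drift) also flags the row, since its Wald statistics
#' are meaningless.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = death, 0 = censored).
#' @param mutation Binary mutation indicator per subject.
#' @param age Optional age covariate (years), entered linearly.
#' @param gene Gene symbol for the output row.
#' @param time_origin Label for the survival clock used (`"dx"` or
#'   `"specimen"`).
#' @return One-row data.frame: `gene`, `time_origin`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n_mutated`, `n`, `estimable`, `reason`.
#' @export
fit_cox <- function(time, event, mutation, age = NULL,
                    gene = NA_character_, time_origin = NA_character_) {
  event <- as.integer(event)
  mutation <- as.integer(mutation)
  n <- length(time)
  if (length(event) != n || length(mutation) != n ||
      (!is.null(age) && length(age) != n)) {
    stop_validation("time, event, mutation (and age) must have equal length")
  }
  if (any(time < 0, na.rm = TRUE)) stop_validation("negative follow-up time")
  n_mut <- sum(mutation)

  if (sum(event) == 0) {
    return(unestimable_row(gene, time_origin, n_mut, n, "no events"))
  }
  if (n_mut == 0 || n_mut == n) {
    return(unestimable_row(gene, time_origin, n_mut, n, "constant mutation indicator"))
  }

  dat <- data.frame(time = time, event = event, mutation = mutation)
  fml <- survival::Surv(time, event) ~ mutation
  if (!is.null(age)) {
    dat$age <- age
    fml <- survival::Surv(time, event) ~ mutation + age
  }

  flagged <- NULL
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(fml, data = dat, ties = "efron"),
      error = function(e) e
    ),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations", conditionMessage(w))) {
        flagged <<- conditionMessage(w)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    return(unestimable_row(gene, time_origin, n_mut, n, conditionMessage(fit)))
  }
  if (!is.null(flagged)) {
    return(unestimable_row(gene, time_origin, n_mut, n,
                           paste("non-convergence:", flagged)))
  }
  beta <- stats::coef(fit)[["mutation"]]
  se <- sqrt(stats::vcov(fit)["mutation", "mutation"])
  z <- beta / se
  data.frame(
    gene = gene, time_origin = time_origin,
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z)),
    n_mutated = n_mut, n = as.integer(n),
    estimable = TRUE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Gene-wise age-adjusted Cox screen under FDR control
#'
#' Runs [fit_cox()] for every gene of a candidate matrix against the chosen
#' overall-survival clock (`"dx"`: time from original diagnosis;
#' `"specimen"`: time from specimen collection), applies Benjamini-Hochberg
#' adjustment across the estimable genes within the screen, and labels each
#' row with the FDR tier it reaches. FDR is computed within one time origin;
#' the two clocks are separate screens.
#'
#' @param matrix Binary gene x sample matrix restricted to candidate genes.
#' @param clinical Clinical table with columns `sample_id`, `os_dx_months`,
#'   `os_spec_months`, `event`, `age_years`.
#' @param time_origin `"dx"` or `"specimen"`.
#' @param fdr_cutoffs Numeric tier cutoffs, default `c(0.2, 0.4)`.
#' @param age_adjust Include age as a covariate (default `TRUE`).
#' @return data.frame of [fit_cox()] rows plus `fdr` and `tier`, one row per
#'   gene; zero rows for an empty candidate matrix.
#' @export
screen_genes <- function(matrix, clinical, time_origin = c("dx", "specimen"),
                         fdr_cutoffs = c(0.2, 0.4), age_adjust = TRUE) {
  time_origin <- match.arg(time_origin)
  need <- c("sample_id", "os_dx_months", "os_spec_months", "event", "age_years")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols) > 0) {
    stop_validation("clinical table lacks: ", paste(missing_cols, collapse = ", "))
  }
  fdr_cutoffs <- sort(fdr_cutoffs)

  samples <- intersect(colnames(matrix), clinical$sample_id)
  n_drop <- ncol(matrix) - length(samples)
  if (n_drop > 0) {
    message(n_drop, " sample(s) without clinical data excluded from the screen")
  }
  cl <- clinical[match(samples, clinical$sample_id), ]
  time <- if (time_origin == "dx") cl$os_dx_months else cl$os_spec_months

  genes <- rownames(matrix)
  if (length(genes) == 0 || length(samples) == 0) {
    out <- unestimable_row(character(0), character(0), integer(0), integer(0),
                           character(0))
    out$fdr <- numeric(0)
    out$tier <- character(0)
    return(out)
  }

  rows <- lapply(genes, function(g) {
    fit_cox(time, cl$event, matrix[g, samples],
            age = if (age_adjust) cl$age_years else NULL,
            gene = g, time_origin = time_origin)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- out$estimable
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p[ok])
  out$tier <- "ns"
  for (cut in rev(fdr_cutoffs)) {
    out$tier[!is.na(out$fdr) & out$fdr <= cut] <- paste0("FDR<=", cut)
  }
  out$tier[!ok] <- "unestimable"
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves with log-rank test and reporting hazard ratio
#'
#' Product-limit survival estimates per group, the standard two-sided
#' log-rank test (chi-square, 1 df), and an unadjusted hazard ratio from a
#' single-covariate Cox fit, reported alongside for parity with forest-plot
#' style summaries. With zero events the log-rank statistic is 0 and p = 1
#' (no event time contributes).
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = death).
#' @param group Binary group indicator (e.g. mutated vs wild-type).
#' @return list: `curves` (data.frame time/n_risk/n_event/surv/group),
#'   `chisq`, `p`, `hr`, `ci_low`, `ci_high`, `n` (per-group sizes).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.integer(as.logical(group))
  if (length(unique(group)) < 2) {
    stop_config("both groups must be nonempty")
  }
  event <- as.integer(event)
  dat <- data.frame(time = time, event = event, group = group)

  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  grp_lab <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(
    group = grp_lab, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, surv = sf$surv, stringsAsFactors = FALSE
  )

  if (sum(event) == 0) {
    chisq <- 0
    p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  cox <- fit_cox(time, event, group)
  list(
    curves = curves, chisq = chisq, p = p,
    hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
    n = table(group)
  )
}
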