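---
title: "Screening somatic mutations for prognostic value in metastatic melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening somatic mutations for prognostic value in metastatic melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Metastatic melanoma genomes carry thousands of somatic mutations, the great
majority ultraviolet-induced passengers. This package implements a screening
workflow that asks which infrequently mutated genes carry prognostic
information about overall survival (OS): filter the calls hard, collapse to
gene-level presence, prioritize by a crude mortality-enrichment ratio, and
only then spend statistical power on gene-wise survival models under false
discovery rate (FDR) control. Because the cohorts this kind of analysis runs
on are controlled-access, the package ships a synthetic cohort generator that
reproduces the statistical structure each stage assumes, and every stage is
tested against it.

## The screening procedure

1. **Quality filter.** Keep calls with sample-level mutant allele frequency
   (MAF) ≥ 5% and mutant allele count (MAC) ≥ 5 reads. Both thresholds are
   inclusive; they are the defaults of `apply_quality_filters()`. Artifact
   and germline annotations (`oxog_suspect`, `germline_suspect`) arrive as
   pass-through flags and can be dropped by `apply_flag_filter()`; the
   package consumes these labels and never re-annotates.
2. **Impact filter.** Keep HIGH and MODERATE snpEff-style impact categories;
   LOW/MODIFIER calls are discarded (`apply_impact_filter()`).
3. **Panel restriction.** Keep calls in a curated cancer-gene panel
   (`restrict_to_panel()`). Each step returns a one-row accounting record,
   and `check_report_conservation()` enforces that the cascade balances:
   `n_input − n_removed = n_output`, chained across steps. The three
   predicates commute, so the surviving set is step-order invariant; the
   order only redistributes the per-step removal counts.
4. **Collapse.** `collapse_to_matrix()` counts multiple mutations per gene
   per specimen once, yielding a binary gene × sample matrix.
5. **Prevalence filter.** Keep genes mutated in at least
   `ceiling(0.03 × n)` samples (`prevalence_filter()`). For n = 356 the
   count threshold is 11. Because "at least 3%" and "more than 11 patients"
   pin different integers, the strict rule (`> ceiling`) is available via
   the `rule` argument; `ceiling` inclusive is the default.
6. **Fold statistic.** For each prevalent gene,
   `x = (m_d/n_d)/(m_a/n_a)` — the fraction of deceased patients carrying
   the gene over the corresponding fraction among the living
   (`fold_statistic()`). Genes with `x ≥ 1.5` or `x ≤ 0.67` become
   candidates. Vital status is the status at last follow-up, deliberately
   time-ignorant: this is a cheap pre-filter, not an inference step. The
   band is kept at the literal 0.67 rather than 2/3, so the protective side
   is very slightly wider than the reciprocal of the adverse side; the
   group-swap symmetry `x → 1/x` is exact only for the symmetric band
   (1.5, 1/1.5), and the tests check it there.
7. **Survival screen.** `screen_genes()` fits, per candidate gene, a Cox
   proportional-hazards model with the mutation indicator and age (linear,
   in years) as covariates, by partial-likelihood maximization with Efron
   tie handling, under each of two OS clocks: time from original diagnosis
   (`dx`) and time from specimen collection (`specimen`). P-values are
   two-sided Wald; Benjamini–Hochberg adjustment is applied across the
   genes of one screen, separately per clock, and rows are labeled by the
   FDR ≤ 0.2 / ≤ 0.4 tier they reach. Wald was chosen because the
   alternatives (score, likelihood ratio) are asymptotically equivalent and
   Wald supplies the confidence interval already being reported;
   Benjamini–Hochberg because it is the field-default FDR procedure and
   the screen's gene-level tests are approximately independent at these
   prevalences.
8. **RNA confirmation.** `assess_rna_support()` calls a DNA mutation
   RNA-confirmed when ≥ 2 RNA reads carry the mutant allele at a site with
   ≥ 8 reads of coverage; sites under 8 reads are "insufficient", which for
   an expressed-mutation question is itself evidence of low-to-absent
   expression. `gene_confirmation_rates()` applies the gene-level rule: a
   gene's mutations are considered expressed when strictly more than 75% of
   its DNA-mutated samples are confirmed. The default denominator counts
   all DNA-mutated samples (insufficient coverage counts against the
   gene); `denominator = "covered"` restricts to assessable samples.
9. **Omics integration.** `integrate_mutation_cna_expression()` labels each
   sample by mutation status, definite copy-number alteration (GISTIC score
   +2 or −2), and expression tertile computed within the analyzed cohort.
   The categories partition the cohort exhaustively; samples missing a
   layer land in an explicit "incomplete" category.

`run_all()` chains the stages from one `run_config()` and writes every
stage's table plus a JSON run report; reruns with the same configuration and
seed are byte-identical (checked by hashing in the tests).

## The synthetic cohort generator

`simulate_cohort()` draws, in a documented fixed order from one root seed:

- **Burden.** Per-sample background mutation counts are negative binomial
  (`burden_mean = 15`, `burden_dispersion = 1`), giving a median near 10
  with a long right tail (single samples over 100 mutations at cohort
  sizes of a few hundred) — the overdispersion pattern of melanoma exomes.
- **Spectrum.** Each sample gets a UV fraction from a Beta distribution
  (mean 0.8, concentration 25; the concentration sets a realistic
  per-sample spread of about ±0.08). UV variants are C>T on the
  pyrimidine strand, 98% at dipyrimidine sites, with a small fraction
  (0.0014) emitted as tandem CC→TT dinucleotide records — so the pooled
  spectrum lands near 80% C>T / 78% dipyrimidine C>T / ~0.1% CC→TT.
  Non-UV variants draw from the non-C>T substitution classes. About half
  of all records are reported on the purine strand (G>A with complemented
  flanks) to exercise strand folding. There is no 96-channel trinucleotide
  model and no signature refitting: only the three UV classes the analysis
  uses are emulated.
- **Candidate genes.** Per-gene Bernoulli carriers at configured
  prevalences (defaults 3–8%, all below 10%). Carried genes contribute one
  HIGH/MODERATE call each; background calls spread over a 300-gene filler
  pool with mixed impacts, so the impact and panel filters have real work.
- **Survival.** Subject hazard is
  `baseline_hazard × exp(Σ log-HR × carrier)`; times are exponential in
  months. Censoring is a single administrative cutoff found by bisection so
  that the *expected* event fraction over the realized cohort hazards
  equals `target_event_fraction` (default 0.52). The realized fraction is
  then binomial around the target: its standard deviation at n = 200 is
  ~0.035, so ±0.05 control per cohort is only guaranteed at larger n (the
  tests check ±0.05 per cohort at n = 1000 and the expectation at
  n = 200). A real cohort's censoring mechanism is unknown; the
  administrative cutoff is a modeling convenience, not an inference about
  it.
- **Two OS clocks.** A nonnegative gamma(2) diagnosis-to-specimen lag
  (mean 12 months) is added to the specimen clock to produce the
  diagnosis clock.
- **RNA evidence.** Each DNA call is RNA-expressed with probability
  `rna_expressed_prob` (default 0.6, scalar or per-gene); expressed calls
  get negative-binomial coverage and mutant reads at an allele fraction no
  lower than the DNA MAF (floored at 0.2); non-expressed calls split
  between covered-reference-only and zero-coverage records.
- **Omics.** GISTIC-style scores (80% neutral, 2% per definite tail) and
  log2 expression with a mild dosage effect.

What the generator does **not** emulate: mutational hotspots and codon
clustering, gene length and replication-timing effects on background rates,
correlated mutation co-occurrence, subclonality beyond the MAF draw,
non-proportional hazards, informative censoring, and real trinucleotide
context frequencies. A passing screen on synthetic cohorts therefore
demonstrates the statistics are implemented and calibrated correctly — not
that real melanoma data would yield any particular gene list.

## Statistical and numerical choices

- **Wilcoxon rank-sum** (`compare_spectra()`, `association_with_burden()`)
  uses exact permutation enumeration of all group assignments when combined
  n ≤ 10 — the two-sided p is the probability of a rank sum at least as far
  from its permutation mean as observed, a definition that remains exact
  under ties — and the tie-corrected normal approximation (no continuity
  correction) otherwise. The implementation is checked against
  `wilcox.test()` on tie-free cases and against an independent brute-force
  enumeration, including ties.
- **Chi-square** association tests are Pearson without Yates correction;
  expected counts are returned and a warning is raised when any falls
  below 5.
- **Cox fits** flag rather than fail on degenerate inputs: no events,
  constant indicator, or monotone-likelihood drift all yield an
  `estimable = FALSE` row with a reason. Tied event times use Efron's
  method; with no ties Efron and Breslow coincide (tested).
- **Power.** `power_by_simulation()` is Monte-Carlo: carriers at the stated
  prevalence, exponential survival at the stated hazard ratio,
  administrative censoring re-tuned per replicate to the target event
  fraction, rejection by two-sided Wald at level α. The baseline hazard is
  a pure time scale and cancels. Degenerate replicates count as
  non-rejections. The analytic Schoenfeld approximation
  `Φ(√(d·p(1−p))·|log HR| − z_{1−α/2})` is provided as a cross-check; for
  rare carriers it undershoots the simulation by roughly 0.05–0.10 because
  it takes the carrier fraction among *events* to be the cohort prevalence,
  while a hazard ratio near 2 overrepresents carriers among events. At the
  reference design (n = 245, prevalence 0.053, HR 1.93, 70% events) the
  simulation gives ≈ 0.58 and the approximation ≈ 0.49.
- **Problem sizes in the test suite** were chosen to make each check a
  sharp statement at interactive runtimes: 10,000 replicates for power and
  type-I calibration (Monte-Carlo SE ≈ 0.005), 100 seeded replicates for
  the planted-gene recovery rates, 1,000 null genes for the p-value
  uniformity KS test, and exhaustive enumeration wherever the space is
  finite (12 substitution types × 16 contexts; every group split at
  n ≤ 8).

## Known limitations

- MAF is the within-sample variant allele fraction; the package never
  consults population allele frequencies, and annotation (impact, panel
  membership, artifact flags) is consumed as input, never computed.
- The RNA confirmation rule is a read-count heuristic standing in for a
  joint DNA/RNA statistical caller; its thresholds (depth 8, alt 2) are
  conventions exposed as arguments, and the gene-level >75% rule is applied
  strictly (3/4 fails).
- The fold-statistic pre-filter conditions on vital status without
  follow-up time and will admit genes whose apparent enrichment reflects
  follow-up imbalance; the Cox screen downstream is the corrective.
- Proportional hazards is assumed, not tested, in the screen; the screen is
  a prioritization device, and any gene it nominates needs validation on an
  independent cohort — which, at realistic prevalences and effect sizes,
  needs to be large (see `power_by_simulation()`).
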