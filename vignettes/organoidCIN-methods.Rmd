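---
title: "Quantifying chromosomal instability in organoid cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability in organoid cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidCIN)
```

High-grade serous ovarian carcinoma is driven almost entirely by chromosomal
instability: its genomes are defined by somatic copy-number alteration rather
than recurrent point mutations. Patient-derived organoids make that
instability experimentally tractable — bulk shallow whole-genome sequencing
yields absolute copy-number profiles and signature activities per model,
single-cell DNA sequencing resolves the clonal structure within a model, and
viability screens read out the phenotype. This package implements the
quantitative layer of such a characterization: four analysis pipelines plus
synthetic-data generators that emulate each input with known ground truth.

This vignette records the models, the tunable parameters, and the reasoning
behind every design decision that the underlying procedures leave open.

## Coordinate and container conventions

All genomic coordinates are 0-based, half-open, everywhere inside the
package; the 1-based-inclusive dialect is accepted only at the segment
reader boundary (`read_segments(..., dialect = "tsv1")`) and converted on
input. A single convention eliminates off-by-one drift between modules.

Binned matrices carry missing bins as explicit `NA`, never 0: a copy number
of 0 is a real state (homozygous deletion), so missingness must be coded
out-of-band. Chromosomes sort naturally (`chr1 < chr2 < ... < chr10`), so
bin order is deterministic across files. Strand in gene annotations is read
and preserved but ignored by every computation — no procedure here is
strand-specific. Chromosome lengths are treated as input metadata (an
argument, or the extent of the supplied profile), not a built-in genome
build.

`segments_to_bins()` assigns each bin the length-weighted mean copy number
of the segments overlapping it; `rebin()` aggregates fine bins to a coarser
multiple by the mean of non-missing constituents. "Average ploidy" of a
profile is its segment-length-weighted mean copy number — the natural
definition for a segmented profile, where long segments should dominate.

## Compositional analysis of signature activities

A sample's copy-number signature activities form a composition: K
nonnegative parts summing to 1. Euclidean operations on raw activities are
misleading (an increase in one part forces decreases elsewhere), so all
comparisons run in Aitchison geometry.

* **Zero imputation** (`impute_and_close`): log-ratios are undefined at 0.
  The default rule is multiplicative replacement — entries below ε are set
  to ε and the row re-closed — with ε = 0.01 by default; an additive variant
  sits behind a flag. `imputation_robustness()` re-clusters over a sweep
  (default ε ∈ {0.001, 0.01, 0.1}) and reports pairwise cophenetic
  correlations and adjusted Rand indices of flat cuts, because any
  conclusion that survives only one ε is an artifact of the imputation.
* **Transforms**: `clr_transform` centers log-abundances by the row
  geometric mean; `ilr_transform` maps CLR onto a (K−1)-dimensional
  orthonormal (Helmert-type) basis, so Euclidean distance of ILR
  coordinates equals Aitchison distance exactly. The basis is checked for
  orthonormality and contrast structure.
* **Clustering** (`cluster_activities`): complete-linkage agglomeration on
  Aitchison distances, after imputation. Complete linkage guarantees
  monotone merge heights; ties resolve by sample index, so results are
  reproducible for a fixed input order.
* **Differential abundance** (`differential_abundance_wald`): both groups
  are ILR-transformed and modeled as uncorrelated multivariate normal.
  The statistic sums squared mean differences standardized by pooled
  per-coordinate variances (denominator ν = n_A + n_B − 2) and is referred
  to χ²(K−1). Each summand is a squared t(ν) variate with expectation
  ν/(ν−2), so the statistic is scaled by (ν−2)/ν before the comparison;
  without this finite-sample moment correction the test is
  anti-conservative at cohort-scale group sizes (true size ≈ 0.07 instead
  of ≈ 0.056 at n = 20 per group, K = 7). A `random-one-per-donor` pairing
  policy selects one sample per donor (seeded) before testing, for cohorts
  where several samples derive from one individual.

  Note that this diagonal-covariance statistic is *not* invariant to
  arbitrary rotations of the ILR basis — only a full-covariance Wald
  statistic is. It is invariant to permutations and sign flips of the basis
  rows, which the tests assert. The diagonal model is retained because with
  few observations a full K−1 × K−1 covariance cannot be estimated stably.

* **Cohort-scale tests**: segment counts are compared by a negative-binomial
  likelihood-ratio test (`segment_count_test`; null = common mean and
  dispersion, alternative = group means with common dispersion, both ML via
  `MASS::glm.nb`, χ²(1) reference); ploidy and other continuous summaries by
  `welch_t` (Welch t, Satterthwaite degrees of freedom).

## Single-cell heterogeneity and clades

Binned single-cell absolute copy number is heteroscedastic: the cross-cell
standard deviation of a bin grows with its mean. `fit_mean_sd()` captures
this with an ordinary least-squares line SD = β₀ + β₁·mean across bins
(default working resolution 500 kb; bins with fewer than two contributing
cells are dropped listwise). `excess_variance_test()` then asks, per bin,
whether the observed variance S² exceeds the clonal expectation
E(σ²) = (β₀ + β₁·mean)²: the statistic T = (n−1)S²/E(σ²) is referred to the
upper tail of χ²(n−1), with n the number of cells contributing to that bin.
A significant bin is subclonally heterogeneous; the per-sample summary is
the fraction of tested bins that are significant.

Design points worth stating explicitly:

* E(σ²) is the *square of the predicted SD* — the model predicts SD, the
  test needs a variance. Bins with nonpositive predicted SD are excluded
  and counted, not clipped: a clipped value would fabricate an expectation
  the model never made.
* The significance level and multiplicity handling for the summary fraction
  are genuinely open in the underlying procedure; the default is unadjusted
  α = 0.05 with `adjust = "holm"` and `"BH"` available. The default
  reproduces the described per-bin test literally while making the
  multiplicity choice explicit and visible.
* The mean–SD line is fitted to the same matrix being tested, including any
  heterogeneous bins. This inflates the line slightly when many bins are
  truly heterogeneous, which *depresses* false positives among clonal bins
  and leaves power at ×4 variance inflation essentially intact (recovery of
  a planted 30% heterogeneous fraction is within ±5 points at 300 cells ×
  500 bins — the scale of the recovery tests).

Clades are detected by complete-linkage hierarchical clustering of cells on
Euclidean distance of binned profiles (`detect_clades`, typically at
500 kb). The dendrogram cut is *not* defaulted: callers must give
`n_clades` or `height`, because the underlying procedure reports only
"major clades" without stating a cut rule, and guessing one silently would
bake in an interpretation. Clades with more than three cells (size ≥ 4) are
retained for comparisons. Between two retained clades,
`clade_differential_bins()` runs per-bin Welch t-tests at fine resolution
(typically 20 kb) with Holm–Bonferroni adjustment across all bins of that
one comparison — the family is the comparison, not the union of all
comparisons, so each clade pair is judged on its own evidence. The t-test
is Welch's: the underlying description says only "t-test", and equal
variances between clades is exactly what cannot be assumed here. Bins that
are constant in both clades get p = 1 and a `degenerate` flag.

## Copy number versus expression

`assign_gene_cn()` maps segmented profiles to genes. The default rule gives
each gene the copy number of the overlapping segment with the *largest
overlap* — deterministic and robust for genes straddling a breakpoint;
length-weighted mean and midpoint rules are available behind a flag for
sensitivity analysis. `size_factor_normalize()` is median-of-ratios
normalization: reference = per-gene geometric mean over samples (genes with
any zero excluded from estimation), per-sample factor = median of
count/reference ratios taken on the log scale, factors standardized to
geometric mean 1 (they are only defined up to a constant; this convention
makes renormalization exactly idempotent).

Two per-gene concordance metrics quantify dosage-driven expression:

* `lowest_k_metric`: average the expression of the k samples with the
  lowest copy number (default k = 3) and report the fraction of the
  remaining n − k samples with strictly higher expression. With 11 samples
  and k = 3 the metric lives on {0/8, …, 8/8}; 1 means every other sample
  out-expresses the low-CN tier (strong dosage signal), values near 0.5 are
  noise. It deliberately captures *monotone* association, not linearity.
  CN ties at the k-th position break by sample order — an expression-blind
  rule, so the metric cannot be inflated by peeking. "Strictly higher" is
  the literal reading; equality counts against concordance.
* `cn_expression_r2`: squared Pearson correlation of CN and expression,
  missing when either side is constant. This captures the linear component.

`metric_k_robustness()` recomputes the metric at k ∈ {2, 3, 4} and
correlates the averaged lowest-k expression values across k. On noise-free
dosage genes these correlations are near-perfect but not exactly 1 — the
k-lowest means are distinct statistics of the same draws — which is why the
tests assert > 0.99 rather than equality. Metrics are computed on
normalized counts directly (no log transform): the concordance question is
posed on the scale the normalization produces, and a caller who prefers a
variance-stabilized input can pass one.

## Drug-response pipeline

Each (compound, sample) group of a plate is processed as:

1. **Standardize** (`standardize_responses`): divide every response by the
   median of that group's control wells. Controls are kept for diagnostics
   but never fitted.
2. **Flag outliers** (`flag_outliers`): robust regression of standardized
   response on a degree-4 polynomial in log dose; wells with robust weight
   < 0.4 are excluded. The estimator is MM-type, assembled from `MASS`
   primitives: a Huber M-fit with Huber proposal-2 residual scale supplies
   the fixed scale (corrected by 1/√(1 − p/n) for fitting degrees of
   freedom); bisquare IRLS (tuning constant 4.685, 95% Gaussian efficiency)
   then runs from two starts — the Huber fit and a high-breakdown
   least-trimmed-squares fit — and the solution with the smaller bisquare
   criterion wins. The two-start scheme matters: a gross outlier at a
   high-leverage edge dose can capture a single-start fit, while the
   proposal-2 scale (rather than the far noisier MAD or small-sample
   S-scale) keeps clean plates from shedding wells. At 3% replicate noise,
   clean 8 × 3 plates keep all wells and a single ×5 outlier is flagged, and
   flagged alone, in ≥ 95% of plates — the operating point the flagging
   tests pin down.
3. **Fit the 5PL** (`fit_5pl`): least squares for
   f(x) = c + (d − c)/(1 + exp(b(ln x − ln e)))^f on retained wells, with
   ln e free (numerical conditioning), bounds |b| ≤ 50 and f ∈ (0.1, 10),
   d initialized at the lowest-dose mean, c at the highest-dose mean, e at
   the geometric-mean dose, and a multi-start grid over the sign and scale
   of b and over f. Perfectly flat plates return the degenerate constant
   curve directly (the Jacobian is singular there); pathological plates
   that defeat every start fall back to Nelder–Mead least squares flagged
   `converged = FALSE`, so one bad well pattern cannot abort a cohort run.
4. **AUC** (`compute_auc`): the integral of the fitted curve over the
   log-dose range, divided by the range width. A no-effect curve scores
   exactly 1; values above 1 occur when treated wells exceed controls.
   Normalization makes compounds with different dose ranges comparable; the
   unnormalized integral is available via `normalize = FALSE`. The default
   integration range is the observed dose extremes, overridable per call. A
   monotone-spline alternative (`compute_auc_mspline`, Hyman-filtered
   spline through dose-wise means) serves as a model-free cross-check.

`classify_sensitivity()` labels samples by mean AUC across a compound panel
relative to the cohort median (exact-median samples stay unassigned), and
`correlate_auc_pairs()` gives the Pearson correlation of AUC vectors between
paired sample sets (e.g. uncultured cells versus derived organoids).

Replicates enter the fit as individual wells, never pre-averaged: the
outlier weights are per-well, and collapsing replicates first would let one
gross well drag its dose-mean before the robust step could see it.

### Accuracy limits of the AUC

The normalized AUC is a mean over the log-dose window, so its sampling
error has a hard floor of roughly σ/√(wells) from replicate noise alone,
plus a multiplicative term from the finite control set used for
standardization (the control median of 16 wells at σ = 0.05 carries ≈ 1.6%
error that scales the whole curve). At 5% replicate noise this floor means
single-plate AUCs are reproducible to roughly ±0.02–0.03, not better; at
the 3% default, ±0.015. Plates carrying several gross outliers at adjacent
doses can additionally defeat the degree-4 robust screen (the bump looks
like curve shape), which leaves a small heavy tail of AUC errors at 10%
contamination. The end-to-end recovery test in the suite measures exactly
this behaviour; users comparing AUCs across cohorts should use replicate
plates or confidence bands rather than treating single-plate AUCs as exact.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of (parameters, seed) and returns ground
truth alongside the data.

* `gen_sc_cn`: cells apportioned to clades by deterministic
  largest-remainder rounding (exact, testable clade sizes), then shuffled;
  per-bin draws Normal(mean, ((α + β·mean)√inflation)²) with negative draws
  set to 0. Defaults α = β = 0.1 and ×4 inflation for planted heterogeneous
  bins; these are package defaults for desk-scale testing, chosen to sit in
  the regime where binned single-cell CN data visibly show the mean–SD
  trend, not measured values from any dataset. Truncation at 0 (rather than
  resampling) introduces a small mean bias near 0 that is accepted and
  documented.
* `gen_signature_cohort`: Dirichlet draws around group centers
  (concentration × center), zeros introduced per row by thresholding the
  smallest entries with a Binomial(K, zero_rate) count — mimicking
  activities reported as exactly 0 — then re-closing; an optional paired
  design derives a per-donor "derivative" sample by a CLR-scale Gaussian
  shift.
* `gen_cn_expression`: integer CN in 1..8 with a shared per-sample shift
  (sample-level correlation); dosage genes get expression
  intercept + slope·CN + noise, non-dosage genes get the same values with
  the gene's CN permuted — identical marginals, no association.
* `gen_dose_response`: 8-point half-log series (ratio 10^−0.5) from the top
  dose, technical triplicate, additive replicate noise on the standardized
  scale (default SD 0.03, a typical technical-replicate coefficient of
  variation for automated luminescent viability assays), gross outliers as
  ×scale multiplications (default ×5), control wells around the control
  level. The true AUC is computed by quadrature of the noiseless curve.

What the generators do *not* emulate: read-level noise and GC/mappability
structure of real bins, segmentation artifacts, correlated noise between
neighbouring bins, plate position effects, or signature-definition
uncertainty. Passing recovery tests on this synthetic data therefore
validates the statistical machinery — transforms, tests, robust fits,
integration — not the upstream measurement process.

The test suite's problem sizes (300 cells × 500 bins for heterogeneity
recovery, 100 cells for clade recovery, 2000-replicate calibrations for the
two tests, 200-plate batteries for the drug pipeline) were chosen as the
smallest scales at which the recovery targets are statistically meaningful.

## Known limitations

* The heterogeneous-genome fraction depends on the chosen α and adjustment;
  the default (unadjusted 0.05) matches the literal per-bin procedure and
  will differ from family-wise-controlled summaries by construction.
* The diagonal-covariance Wald test ignores correlation between ILR
  coordinates; with strongly correlated signature activities its size can
  drift from nominal.
* Single-plate AUC precision is bounded by replicate and control noise (see
  above); the pipeline quantifies drug response, it does not certify ±0.02
  accuracy at arbitrary noise.
* The clade machinery clusters on Euclidean distance of binned CN, which is
  scale-dominated by high-CN regions; it reports clonal structure, not a
  phylogeny.
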