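# Synthetic-data generators. Each is a pure function of (parameters, seed)
# and returns ground truth alongside the data so downstream stages can be
# scored without any external data.

#' Clade specification for single-cell simulation
#'
#' @param fraction proportion of cells in the clade (fractions sum to 1
#'   across clades).
#' @param base_profile per-bin mean absolute copy number.
#' @param altered_regions list of `list(from, to, offset)` bin ranges
#'   (1-based, inclusive) whose means are shifted by `offset` copies.
#' @return list of class `clade_spec`.
#' @export
clade_spec <- function(fraction, base_profile, altered_regions = list()) {
  profile <- base_profile
  for (r in altered_regions)
    profile[r$from:r$to] <- profile[r$from:r$to] + r$offset
  if (any(profile < 0)) stop_named("clade mean profile has negative entries")
  structure(list(fraction = fraction, base_profile = base_profile,
                 altered_regions = altered_regions, mean_profile = profile),
            class = "clade_spec")
}

#' Heteroscedastic noise model for single-cell copy number
#'
#' Per-bin SD grows linearly with the bin mean: `sd = alpha + beta * mean`,
#' multiplied by `sqrt(inflation)` in bins marked as truly heterogeneous.
#'
#' @param alpha SD intercept (copies).
#' @param beta SD slope (dimensionless).
#' @param inflation per-bin variance multiplier (>= 1); values > 1 mark
#'   planted heterogeneous bins.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(alpha = 0.1, beta = 0.1, inflation = 1) {
  stopifnot(alpha >= 0, beta >= 0, all(inflation >= 1))
  structure(list(alpha = alpha, beta = beta, inflation = inflation),
            class = "noise_model")
}

#' Simulate a single-cell copy-number matrix with clonal clades
#'
#' Cells are apportioned to clades by deterministic largest-remainder
#' rounding of the clade fractions and then shuffled. Cell i of clade g gets
#' in bin j a draw from Normal(mean_gj, ((alpha + beta mean_gj) *
#' sqrt(inflation_j))^2), with negative draws set to 0 (the small resulting
#' bias is accepted at this scale).
#'
#' @param n_cells number of cells (>= 2).
#' @param bins number of bins, or a bin data.frame (`chrom`,`start`,`end`).
#' @param clades list of [clade_spec]; fractions must sum to 1.
#' @param noise a [noise_model]; `inflation` is recycled over bins.
#' @param bin_size bin width in bp (used when `bins` is a count).
#' @param seed mandatory RNG seed.
#' @return list with `matrix` ([cn_bin_matrix]), `labels` (true clade of
#'   each cell) and `hetero_mask` (true heterogeneous-bin mask).
#' @export
gen_sc_cn <- function(n_cells, bins, clades, noise = noise_model(),
                      bin_size = 500000L, seed) {
  if (missing(seed)) stop_named("seed is mandatory")
  stopifnot(n_cells >= 2)
  fr <- vapply(clades, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop_named("clade fractions must sum to 1")
  if (is.numeric(bins) && length(bins) == 1) {
    n_bins <- bins
    bins <- data.frame(chrom = "chr1",
                       start = (seq_len(n_bins) - 1) * bin_size,
                       end = seq_len(n_bins) * bin_size)
  } else n_bins <- nrow(bins)
  for (cl in clades)
    if (length(cl$mean_profile) != n_bins)
      stop_named("clade profile length != number of bins")
  set.seed(seed)
  counts <- largest_remainder(n_cells, fr)
  labels <- sample(rep(seq_along(clades), counts))
  infl <- rep_len(noise$inflation, n_bins)
  vals <- matrix(0, n_cells, n_bins)
  for (g in seq_along(clades)) {
    idx <- which(labels == g)
    mu <- clades[[g]]$mean_profile
    sds <- (noise$alpha + noise$beta * mu) * sqrt(infl)
    vals[idx, ] <- matrix(rnorm(length(idx) * n_bins,
                                mean = rep(mu, each = length(idx)),
                                sd = rep(sds, each = length(idx))),
                          nrow = length(idx))
  }
  vals[vals < 0] <- 0
  rownames(vals) <- sprintf("cell%03d", seq_len(n_cells))
  list(matrix = cn_bin_matrix(vals, bins, bins$end[1] - bins$start[1]),
       labels = labels, hetero_mask = infl > 1)
}

#' Simulate a signature-activity cohort with group structure
#'
#' Rows are Dirichlet draws around per-group centers (concentration scales
#' the center). Zeros are introduced per row by thresholding the smallest
#' entries: the number of zeroed entries is Binomial(K, zero_rate) (capped at
#' K - 1), mimicking activities reported as exactly 0; rows are re-closed to
#' sum 1. An optional paired design draws, for each sample, a derivative
#' composition shifted on the CLR scale by Normal(0, pair_shift_sd^2) noise.
#'
#' @param n_per_group samples per group (recycled over groups).
#' @param group_centers groups x K matrix of center compositions.
#' @param concentration Dirichlet concentration (default 50).
#' @param zero_rate expected fraction of zeroed entries (default 0).
#' @param pair_shift_sd if non-NULL, per-coordinate SD of the CLR-scale shift
#'   used to derive a paired "derivative" sample for each "donor" sample.
#' @param seed mandatory RNG seed.
#' @return list with `activities` ([signature_activities]), `groups`, and,
#'   for a paired design, `derived` activities plus `donor` ids.
#' @export
gen_signature_cohort <- function(n_per_group, group_centers,
                                 concentration = 50, zero_rate = 0,
                                 pair_shift_sd = NULL, seed) {
  if (missing(seed)) stop_named("seed is mandatory")
  group_centers <- rbind(group_centers)
  K <- ncol(group_centers)
  if (K < 2) stop_named("need at least 2 signatures")
  if (any(abs(rowSums(group_centers) - 1) > 1e-8))
    stop_named("group centers must be compositions")
  set.seed(seed)
  n_per_group <- rep_len(n_per_group, nrow(group_centers))
  rows <- list(); groups <- integer(0)
  for (g in seq_len(nrow(group_centers))) {
    rows[[g]] <- rdirichlet(n_per_group[g], concentration * group_centers[g, ])
    groups <- c(groups, rep(g, n_per_group[g]))
  }
  acts <- do.call(rbind, rows)
  if (zero_rate > 0) {
    for (i in seq_len(nrow(acts))) {
      nz <- min(rbinom(1, K, zero_rate), K - 1)
      if (nz > 0) acts[i, order(acts[i, ])[seq_len(nz)]] <- 0
    }
    acts <- acts / rowSums(acts)
  }
  dimnames(acts) <- list(sprintf("sample%03d", seq_len(nrow(acts))),
                         paste0("s", seq_len(K)))
  out <- list(activities = signature_activities(acts), groups = groups)
  if (!is.null(pair_shift_sd)) {
    pos <- pmax(acts, 1e-6)  # zeros need a floor before going to log scale
    lg <- log(pos) - rowMeans(log(pos))
    shift <- matrix(rnorm(length(lg), 0, pair_shift_sd), nrow(lg))
    der <- exp(lg + shift)
    der <- der / rowSums(der)
    dimnames(der) <- list(sub("sample", "derived", rownames(acts)),
                          colnames(acts))
    out$derived <- signature_activities(der)
    out$donor <- rownames(acts)
  }
  out
}

#' Simulate paired gene-level copy number and expression
#'
#' Copy numbers take integer values in 1..8 with a shared per-sample shift
#' (sample-level correlation). Dosage genes have expression
#' `intercept + slope * CN + Normal(0, noise_sd^2)` clipped at 0; for
#' non-dosage genes the CN-expression pairing is broken by permuting the
#' gene's CN values, which preserves the marginal distributions.
#'
#' @param n_genes,n_samples dimensions.
#' @param dosage_fraction fraction of genes with a real dosage effect.
#' @param slope expression units per copy.
#' @param noise_sd expression noise SD.
#' @param intercept baseline expression at CN 0.
#' @param seed mandatory RNG seed.
#' @return list with `cn` (genes x samples), `expression`, `dosage_flags`.
#' @export
gen_cn_expression <- function(n_genes, n_samples, dosage_fraction = 0.3,
                              slope = 1, noise_sd = 0.3, intercept = 2,
                              seed) {
  if (missing(seed)) stop_named("seed is mandatory")
  if (dosage_fraction < 0 || dosage_fraction > 1)
    stop_named("dosage_fraction must lie in [0, 1]")
  set.seed(seed)
  gene_level <- sample(1:8, n_genes, replace = TRUE,
                       prob = c(.05, .35, .2, .15, .1, .06, .05, .04))
  sample_shift <- sample(-1:1, n_samples, replace = TRUE, prob = c(.25, .5, .25))
  cn <- outer(gene_level, sample_shift, `+`) +
    matrix(sample(-1:1, n_genes * n_samples, replace = TRUE,
                  prob = c(.2, .6, .2)), n_genes)
  cn <- pmin(pmax(cn, 1), 8)
  dosage <- rep(FALSE, n_genes)
  dosage[sample(n_genes, round(dosage_fraction * n_genes))] <- TRUE
  expr <- matrix(0, n_genes, n_samples)
  for (i in seq_len(n_genes)) {
    cni <- if (dosage[i]) cn[i, ] else sample(cn[i, ])
    expr[i, ] <- pmax(intercept + slope * cni + rnorm(n_samples, 0, noise_sd), 0)
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  sample_ids <- sprintf("PDO%02d", seq_len(n_samples))
  dimnames(cn) <- dimnames(expr) <- list(gene_ids, sample_ids)
  list(cn = cn, expression = expr, dosage_flags = stats::setNames(dosage, gene_ids))
}

#' Five-parameter log-logistic curve parameters
#'
#' `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))^f`: b slope, c lower
#' (high-dose) asymptote, d upper (low-dose) asymptote, e inflection dose
#' (uM), f asymmetry.
#'
#' @param b,c,d,e,f curve parameters; `e > 0`, `f > 0`.
#' @return list of class `fivepl_params`.
#' @export
fivepl_params <- function(b = 1.5, c = 0.1, d = 1, e = 1, f = 1.3) {
  stopifnot(e > 0, f > 0)
  structure(list(b = b, c = c, d = d, e = e, f = f), class = "fivepl_params")
}

#' Evaluate a five-parameter log-logistic curve
#' @param x dose (uM), vectorized.
#' @param params a [fivepl_params] (or plain list with b, c, d, e, f).
#' @return standardized response at each dose.
#' @export
fivepl <- function(x, params) {
  with(params, c + (d - c) / (1 + exp(b * (log(x) - log(e))))^f)
}

#' Half-log dilution series
#' @param top_dose highest dose (uM).
#' @param n_doses number of doses (default 8).
#' @return decreasing dose vector with ratio 10^-0.5 between neighbours.
#' @export
half_log_doses <- function(top_dose, n_doses = 8) {
  if (top_dose <= 0) stop_named("top_dose must be positive")
  top_dose * 10^(-0.5 * (seq_len(n_doses) - 1))
}

#' Simulate a dose-response plate
#'
#' Raw responses are `5PL(dose) * control_level` plus additive
#' Normal(0, (noise_sd * control_level)^2) replicate noise; a fraction
#' `outlier_rate` of treated wells is multiplied by `outlier_scale`.
#' Controls are drawn around `control_level`. The true normalized AUC is the
#' fine-grid integral of the noiseless curve over the log-dose range divided
#' by the range width.
#'
#' @param params [fivepl_params] of the true curve.
#' @param top_dose top of the half-log series (uM).
#' @param n_doses,n_replicates plate design (default 8 doses x 3 replicates).
#' @param noise_sd replicate noise SD on the standardized scale (default
#'   0.03, a typical technical-replicate CV for luminescent viability
#'   readouts).
#' @param outlier_rate,outlier_scale gross-outlier contamination.
#' @param n_controls number of control wells.
#' @param control_level raw readout level of untreated wells.
#' @param compound,sample identifiers written into the table.
#' @param seed mandatory RNG seed.
#' @return list with `table` (validated dose-response data.frame),
#'   `true_auc`, `outlier_mask` (per treated row) and `doses`.
#' @export
gen_dose_response <- function(params = fivepl_params(), top_dose = 30,
                              n_doses = 8, n_replicates = 3, noise_sd = 0.03,
                              outlier_rate = 0, outlier_scale = 5,
                              n_controls = 16, control_level = 100,
                              compound = "drugA", sample = "PDO01", seed) {
  if (missing(seed)) stop_named("seed is mandatory")
  doses <- half_log_doses(top_dose, n_doses)
  set.seed(seed)
  dose_col <- rep(doses, each = n_replicates)
  resp <- fivepl(dose_col, params) * control_level +
    rnorm(length(dose_col), 0, noise_sd * control_level)
  out_mask <- runif(length(dose_col)) < outlier_rate
  resp[out_mask] <- resp[out_mask] * outlier_scale
  resp <- pmax(resp, 0)
  controls <- pmax(rnorm(n_controls, control_level, noise_sd * control_level), 0)
  tab <- rbind(
    data.frame(compound = compound, sample = sample, dose_uM = dose_col,
               replicate = rep(seq_len(n_replicates), n_doses),
               response = resp, is_control = 0L),
    data.frame(compound = compound, sample = sample, dose_uM = NA_real_,
               replicate = seq_len(n_controls), response = controls,
               is_control = 1L))
  dose_response_table(tab)
  lo <- log(min(doses)); hi <- log(max(doses))
  true_auc <- stats::integrate(function(u) fivepl(exp(u), params), lo, hi,
                               subdivisions = 1000L, rel.tol = 1e-10)$value / (hi - lo)
  list(table = tab, true_auc = true_auc, outlier_mask = out_mask, doses = doses)
}

#' Simulate a segmented copy-number profile
#'
#' Contiguous, non-overlapping segments on one synthetic chromosome with
#' copy numbers drawn around a ploidy center.
#'
#' @param n_segments number of segments.
#' @param ploidy_center center of the segment CN distribution.
#' @param cn_sd SD of segment CN around the center.
#' @param mean_seg_len mean segment length (bp).
#' @param sample_id identifier.
#' @param seed mandatory RNG seed.
#' @return a [cn_profile].
#' @export
gen_segmented_profile <- function(n_segments, ploidy_center = 2.7, cn_sd = 1,
                                  mean_seg_len = 1e7, sample_id = "sim",
                                  seed) {
  if (missing(seed)) stop_named("seed is mandatory")
  set.seed(seed)
  lens <- pmax(round(rexp(n_segments, 1 / mean_seg_len)), 1e5)
  ends <- cumsum(lens)
  cn <- pmax(rnorm(n_segments, ploidy_center, cn_sd), 0)
  cn_profile(sample_id, data.frame(chrom = "chr1", start = c(0, ends[-n_segments]),
                                   end = ends, cn = cn))
}
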