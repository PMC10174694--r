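# Single-cell copy-number subclonal heterogeneity: a linear mean-SD trend
# across 500 kb bins captures the heteroscedasticity of binned absolute copy
# number; bins whose observed cross-cell variance exceeds the trend's
# prediction (chi-squared upper tail) are called subclonally heterogeneous.

#' Fit the per-bin mean-SD trend of a single-cell matrix
#'
#' Ordinary least squares of the per-bin cross-cell standard deviation on
#' the per-bin mean. Bins are excluded listwise: only cells with a value in
#' the bin contribute, and bins with fewer than 2 contributing cells are
#' dropped.
#'
#' @param mat a [cn_bin_matrix] (typically at 500 kb resolution).
#' @return object of class `mean_sd_model`: `beta0` (SD intercept, copies),
#'   `beta1` (slope), `n_cells`, `r_squared`, `n_bins` used.
#' @export
fit_mean_sd <- function(mat) {
  v <- mat$values
  if (nrow(v) < 3) stop_named("need >= 3 cells to fit the mean-SD model")
  n_per_bin <- colSums(!is.na(v))
  keep <- n_per_bin >= 2
  mu <- colMeans(v, na.rm = TRUE)[keep]
  sds <- apply(v[, keep, drop = FALSE], 2, stats::sd, na.rm = TRUE)
  if (length(mu) < 10) stop_named("need >= 10 usable bins")
  if (all(sds == 0)) stop_named("all bins constant: zero SD everywhere")
  fit <- stats::lm(sds ~ mu)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 n_cells = nrow(v),
                 r_squared = summary(fit)$r.squared,
                 n_bins = length(mu)),
            class = "mean_sd_model")
}

#' @export
print.mean_sd_model <- function(x, ...) {
  cat(sprintf("mean-SD model: sd = %.4f + %.4f * mean (R2 = %.3f, %d cells, %d bins)\n",
              x$beta0, x$beta1, x$r_squared, x$n_cells, x$n_bins))
  invisible(x)
}

#' Predict per-bin SD from a mean-SD model
#' @param object a `mean_sd_model`.
#' @param newdata numeric vector of bin means.
#' @param ... unused.
#' @return predicted SDs.
#' @export
predict.mean_sd_model <- function(object, newdata, ...) {
  object$beta0 + object$beta1 * newdata
}

#' Per-bin excess-variance test for subclonal heterogeneity
#'
#' For each bin the expected variance under clonal homogeneity is the square
#' of the model-predicted SD, `E = (beta0 + beta1 * mean)^2`. The statistic
#' `T = (n - 1) S^2 / E` (with `S^2` the observed cross-cell variance and
#' `n` the number of contributing cells) is referred to the upper tail of
#' chi-squared with `n - 1` degrees of freedom; the alternative is
#' over-dispersion (`E < S^2`). Bins with a nonpositive predicted SD are
#' excluded and reported.
#'
#' @param mat a [cn_bin_matrix] at the resolution the model was fitted on.
#' @param model a `mean_sd_model` (fitted from `mat` when NULL).
#' @param alpha significance level for the heterogeneous-fraction summary.
#' @param adjust multiplicity adjustment for that summary: `"none"`
#'   (default), `"holm"` or `"BH"`.
#' @return list of class `bin_heterogeneity`: `bins` data.frame (chrom,
#'   start, end, n, mean, s2, expected_var, statistic, p_value, p_adjusted,
#'   significant), `heterogeneous_fraction`, `n_tested`, `n_excluded`,
#'   `alpha`, `adjust`.
#' @export
excess_variance_test <- function(mat, model = NULL, alpha = 0.05,
                                 adjust = c("none", "holm", "BH")) {
  adjust <- match.arg(adjust)
  model <- model %||% fit_mean_sd(mat)
  v <- mat$values
  n_per_bin <- colSums(!is.na(v))
  mu <- colMeans(v, na.rm = TRUE)
  s2 <- apply(v, 2, stats::var, na.rm = TRUE)
  pred_sd <- predict(model, mu)
  usable <- n_per_bin >= 2 & !is.na(mu)
  pos <- usable & pred_sd > 0
  statistic <- p <- rep(NA_real_, length(mu))
  statistic[pos] <- (n_per_bin[pos] - 1) * s2[pos] / pred_sd[pos]^2
  p[pos] <- stats::pchisq(statistic[pos], df = n_per_bin[pos] - 1,
                          lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(mu))
  p_adj[pos] <- switch(adjust,
                       none = p[pos],
                       holm = holm_adjust(p[pos]),
                       BH = stats::p.adjust(p[pos], method = "BH"))
  sig <- p_adj < alpha
  bins <- data.frame(mat$bins, n = n_per_bin, mean = mu, s2 = s2,
                     expected_var = ifelse(pos, pred_sd^2, NA_real_),
                     statistic = statistic, p_value = p,
                     p_adjusted = p_adj, significant = sig)
  structure(list(bins = bins,
                 heterogeneous_fraction = mean(sig[pos]),
                 n_tested = sum(pos), n_excluded = sum(usable & !pos),
                 alpha = alpha, adjust = adjust),
            class = "bin_heterogeneity")
}

#' @export
print.bin_heterogeneity <- function(x, ...) {
  cat(sprintf("excess-variance test: %d bins tested (%d excluded), %.1f%% heterogeneous at alpha=%g (%s)\n",
              x$n_tested, x$n_excluded, 100 * x$heterogeneous_fraction,
              x$alpha, x$adjust))
  invisible(x)
}
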