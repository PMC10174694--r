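# Compositional geometry of signature-activity tables: zero imputation,
# CLR/ILR transforms, Aitchison distance, complete-linkage clustering, an
# imputation-robustness sweep, and a diagonal-covariance Wald test on ILR
# coordinates.

#' Impute zeros and re-close compositions
#'
#' Multiplicative replacement (default): entries below `epsilon` are set to
#' `epsilon` and each row is renormalized to sum 1. The additive variant adds
#' `epsilon` to every entry before re-closing.
#'
#' @param activities a [signature_activities] matrix (or plain matrix of
#'   compositions).
#' @param epsilon imputation value in (0, 0.5); default 1e-2.
#' @param method `"multiplicative"` (replace-below-epsilon) or `"additive"`.
#' @return strictly positive [signature_activities].
#' @export
impute_and_close <- function(activities, epsilon = 1e-2,
                             method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  if (epsilon <= 0 || epsilon >= 0.5) stop_named("epsilon must lie in (0, 0.5)")
  m <- unclass(as.matrix(activities))
  if (any(rowSums(m) == 0)) stop_named("row of all zeros carries no information")
  if (method == "multiplicative") m[m < epsilon] <- epsilon
  else m <- m + epsilon
  m <- m / rowSums(m)
  signature_activities(m)
}

#' Centered log-ratio transform
#'
#' `clr(x)_j = ln(x_j / g(x))` with `g` the row geometric mean; rows sum to 0.
#'
#' @param activities strictly positive compositions (impute first if zeros
#'   are present, see [impute_and_close]).
#' @return samples x K matrix of CLR coordinates.
#' @export
clr_transform <- function(activities) {
  m <- unclass(as.matrix(activities))
  if (any(m <= 0))
    stop_named("zero or negative entries: apply impute_and_close() first")
  lg <- log(m)
  lg - rowMeans(lg)
}

#' Helmert-type orthonormal ILR basis
#'
#' Rows are orthonormal contrasts, each orthogonal to the constant vector,
#' so that `ilr = clr %*% t(basis)` is an isometry of the Aitchison geometry.
#'
#' @param K number of parts.
#' @return (K-1) x K contrast matrix.
#' @export
ilr_basis <- function(K) {
  stopifnot(K >= 2)
  V <- matrix(0, K - 1, K)
  for (j in seq_len(K - 1)) {
    V[j, seq_len(j)] <- sqrt(1 / (j * (j + 1)))
    V[j, j + 1] <- -sqrt(j / (j + 1))
  }
  V
}

#' Isometric log-ratio transform
#'
#' @param activities strictly positive compositions.
#' @param basis (K-1) x K orthonormal contrast matrix; default Helmert-type
#'   from [ilr_basis]. Non-orthonormal bases are rejected.
#' @return samples x (K-1) matrix of ILR coordinates; Euclidean distances in
#'   this space equal Aitchison distances between the compositions.
#' @export
ilr_transform <- function(activities, basis = NULL) {
  m <- unclass(as.matrix(activities))
  K <- ncol(m)
  basis <- basis %||% ilr_basis(K)
  if (!all(dim(basis) == c(K - 1, K)))
    stop_named("basis must be (K-1) x K")
  gram <- basis %*% t(basis)
  if (max(abs(gram - diag(K - 1))) > 1e-8 ||
      max(abs(basis %*% rep(1, K))) > 1e-8)
    stop_named("basis is not an orthonormal contrast matrix")
  clr_transform(m) %*% t(basis)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between CLR vectors; a metric on the open simplex.
#'
#' @param a,b strictly positive compositions of equal length.
#' @return nonnegative distance.
#' @export
aitchison_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ca <- log(a) - mean(log(a))
  cb <- log(b) - mean(log(b))
  sqrt(sum((ca - cb)^2))
}

#' Pairwise Aitchison distances of an activity table
#' @param activities strictly positive compositions (rows).
#' @return a `dist` object.
#' @export
aitchison_dist <- function(activities) {
  stats::dist(clr_transform(activities))
}

#' Hierarchical clustering of signature activities in Aitchison geometry
#'
#' Imputes zeros, CLR-transforms, and clusters samples by complete-linkage
#' agglomeration on Aitchison distances. Deterministic for a given input
#' order (ties broken by sample index, as in `stats::hclust`).
#'
#' @param activities a [signature_activities] matrix.
#' @param epsilon imputation value passed to [impute_and_close].
#' @param linkage agglomeration method (default `"complete"`).
#' @param cut_k optional number of flat clusters to cut.
#' @return list of class `activity_clustering` with `hclust`, `distance`
#'   name, `linkage`, `epsilon`, and `labels` (when `cut_k` given).
#' @export
cluster_activities <- function(activities, epsilon = 1e-2,
                               linkage = "complete", cut_k = NULL) {
  if (nrow(activities) < 2) stop_named("need at least 2 samples to cluster")
  imp <- impute_and_close(activities, epsilon)
  hc <- stats::hclust(aitchison_dist(imp), method = linkage)
  out <- list(hclust = hc, distance = "aitchison", linkage = linkage,
              epsilon = epsilon,
              labels = if (!is.null(cut_k)) stats::cutree(hc, k = cut_k))
  class(out) <- "activity_clustering"
  out
}

#' @export
print.activity_clustering <- function(x, ...) {
  cat(sprintf("activity_clustering: %d samples, %s linkage on %s distance (epsilon=%g)\n",
              length(x$hclust$order), x$linkage, x$distance, x$epsilon))
  invisible(x)
}

#' Robustness of the dendrogram to the imputation value
#'
#' Re-clusters the table at each epsilon and reports, for every pair of
#' epsilons, the cophenetic correlation between dendrograms and the adjusted
#' Rand index between flat cuts at each requested k.
#'
#' @param activities a [signature_activities] matrix.
#' @param epsilons numeric vector of imputation values (>= 2 values);
#'   default `c(0.001, 0.01, 0.1)`.
#' @param ks flat-cut sizes to compare (default 2).
#' @return list with `pairs` (data.frame: eps_a, eps_b, cophenetic_cor, and
#'   one `ari_k*` column per k) and `clusterings` (one per epsilon).
#' @export
imputation_robustness <- function(activities, epsilons = c(0.001, 0.01, 0.1),
                                  ks = 2) {
  if (length(epsilons) < 2) stop_named("need at least 2 epsilons")
  cls <- lapply(epsilons, function(e) cluster_activities(activities, epsilon = e))
  coph <- lapply(cls, function(cl) stats::cophenetic(cl$hclust))
  cuts <- lapply(cls, function(cl)
    vapply(ks, function(k) stats::cutree(cl$hclust, k = k),
           integer(nrow(activities))))
  combs <- utils::combn(length(epsilons), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    row <- data.frame(eps_a = epsilons[a], eps_b = epsilons[b],
                      cophenetic_cor = stats::cor(as.vector(coph[[a]]),
                                                  as.vector(coph[[b]])))
    for (j in seq_along(ks))
      row[[paste0("ari_k", ks[j])]] <-
        mclust::adjustedRandIndex(cuts[[a]][, j], cuts[[b]][, j])
    row
  }))
  list(pairs = pairs, clusterings = cls)
}

#' Wald test for differential signature abundance between two groups
#'
#' Both groups are zero-imputed, ILR-transformed, and modeled as uncorrelated
#' multivariate normal (diagonal covariance). The statistic is
#' `sum_j delta_j^2 / (v_j (1/n_A + 1/n_B))` with `v_j` the pooled
#' per-coordinate variance (denominator `nu = n_A + n_B - 2`), scaled by the
#' finite-sample moment correction `(nu - 2) / nu` so that each squared
#' standardized difference has unit expectation under the null (a squared
#' t-variate has mean `nu / (nu - 2)`), and referred to a chi-squared
#' distribution with K - 1 degrees of freedom. Without the correction the
#' chi-squared reference is anti-conservative at small group sizes.
#'
#' The `"random-one-per-donor"` pairing policy keeps one randomly selected
#' sample per donor in each group before testing (used when several samples
#' derive from one individual).
#'
#' @param group_a,group_b activity matrices (rows = samples, same K).
#' @param epsilon imputation value.
#' @param basis optional ILR basis (the statistic is invariant to the
#'   orthonormal basis choice).
#' @param paired_policy `"none"` or `"random-one-per-donor"`.
#' @param donors_a,donors_b donor ids per row, required by the pairing policy.
#' @param seed RNG seed used by the random pairing draw.
#' @return list of class `wald_test`: `statistic`, `df`, `p_value`,
#'   `delta` (per-coordinate mean differences), `variance`, `n_a`, `n_b`.
#' @export
differential_abundance_wald <- function(group_a, group_b, epsilon = 1e-2,
                                        basis = NULL,
                                        paired_policy = c("none", "random-one-per-donor"),
                                        donors_a = NULL, donors_b = NULL,
                                        seed = NULL) {
  paired_policy <- match.arg(paired_policy)
  if (paired_policy == "random-one-per-donor") {
    if (is.null(donors_a) || is.null(donors_b))
      stop_named("pairing policy requires donor ids for both groups")
    if (!is.null(seed)) set.seed(seed)
    pick <- function(m, donors) {
      idx <- vapply(split(seq_len(nrow(m)), donors),
                    function(ix) if (length(ix) == 1) ix else sample(ix, 1), 0L)
      m[sort(idx), , drop = FALSE]
    }
    group_a <- pick(group_a, donors_a)
    group_b <- pick(group_b, donors_b)
  }
  if (nrow(group_a) < 2 || nrow(group_b) < 2)
    stop_named("each group needs >= 2 samples after pairing")
  if (ncol(group_a) != ncol(group_b)) stop_named("groups differ in K")
  K <- ncol(group_a)
  ia <- ilr_transform(impute_and_close(group_a, epsilon), basis)
  ib <- ilr_transform(impute_and_close(group_b, epsilon), basis)
  na <- nrow(ia); nb <- nrow(ib)
  delta <- colMeans(ia) - colMeans(ib)
  v <- ((na - 1) * apply(ia, 2, stats::var) +
        (nb - 1) * apply(ib, 2, stats::var)) / (na + nb - 2)
  if (any(v <= 0))
    stop_named("degenerate ILR coordinate with zero pooled variance")
  nu <- na + nb - 2
  correction <- if (nu > 2) (nu - 2) / nu else 1
  statistic <- correction * sum(delta^2 / (v * (1 / na + 1 / nb)))
  structure(list(statistic = statistic, df = K - 1,
                 p_value = stats::pchisq(statistic, K - 1, lower.tail = FALSE),
                 delta = delta, variance = v, n_a = na, n_b = nb),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald test on ILR coordinates: X2 = %.4g, df = %d, p = %.4g (n = %d vs %d)\n",
              x$statistic, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Negative-binomial likelihood-ratio test for segment counts
#'
#' Null: one NB mean and dispersion shared by both groups. Alternative:
#' group-specific means, common dispersion. Both fitted by maximum
#' likelihood (`MASS::glm.nb`); the LRT statistic is referred to chi-squared
#' with 1 degree of freedom.
#'
#' @param counts_a,counts_b positive integer segment counts (>= 2 each).
#' @return list with `statistic`, `df`, `p_value`, group means and the
#'   dispersion (theta) estimates.
#' @export
segment_count_test <- function(counts_a, counts_b) {
  y <- c(counts_a, counts_b)
  if (any(y != round(y)) || any(y <= 0))
    stop_named("segment counts must be positive integers")
  if (length(counts_a) < 2 || length(counts_b) < 2)
    stop_named("each group needs >= 2 counts")
  grp <- factor(rep(c("a", "b"), c(length(counts_a), length(counts_b))))
  fit1 <- suppressWarnings(MASS::glm.nb(y ~ grp))
  fit0 <- suppressWarnings(MASS::glm.nb(y ~ 1))
  statistic <- max(0, 2 * (as.numeric(stats::logLik(fit1)) -
                           as.numeric(stats::logLik(fit0))))
  list(statistic = statistic, df = 1L,
       p_value = stats::pchisq(statistic, 1, lower.tail = FALSE),
       mean_a = mean(counts_a), mean_b = mean(counts_b),
       theta_alt = fit1$theta, theta_null = fit0$theta)
}

#' Welch two-sample t-test
#'
#' Thin wrapper around `stats::t.test` (unequal variances, Satterthwaite
#' degrees of freedom, two-sided).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_named("each group needs >= 2 values")
  ht <- stats::t.test(a, b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
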