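# Drug-sensitivity pipeline: control-median standardization, MM-type robust
# polynomial outlier exclusion, five-parameter log-logistic fitting, and the
# normalized log-dose AUC (1 = no effect; values above 1 occur when treated
# wells exceed controls).

#' Standardize plate responses by the control median
#'
#' Within each (compound, sample) group every response is divided by the
#' median response of that group's control wells. Controls are retained
#' (flagged) for diagnostics but are not part of curve fitting.
#'
#' @param tab dose-response data.frame (see [dose_response_table]).
#' @return data.frame of treated wells with columns `compound`, `sample`,
#'   `dose_uM`, `log_dose`, `replicate`, `response` (standardized), plus a
#'   `control_median` column carrying the raw control median of the group.
#' @export
standardize_responses <- function(tab) {
  dose_response_table(tab)
  out <- lapply(split(tab, list(tab$compound, tab$sample), drop = TRUE),
    function(g) {
      ctrl <- g$response[g$is_control == 1]
      if (!length(ctrl))
        stop_named("group (%s, %s) has no control wells",
                   g$compound[1], g$sample[1])
      treated <- g[g$is_control == 0, ]
      if (!nrow(treated)) return(NULL)
      data.frame(compound = treated$compound, sample = treated$sample,
                 dose_uM = treated$dose_uM, log_dose = log(treated$dose_uM),
                 replicate = treated$replicate,
                 response = treated$response / stats::median(ctrl),
                 control_median = stats::median(ctrl))
    })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fixed-scale bisquare IRLS from a given coefficient start.
bisquare_irls <- function(X, y, beta, s, c_tune = 4.685, maxit = 200) {
  for (it in seq_len(maxit)) {
    r <- as.vector(y - X %*% beta)
    u <- pmin(abs(r / (s * c_tune)), 1)
    w <- (1 - u^2)^2
    beta_new <- stats::coef(stats::lm.wfit(X, y, w))
    if (max(abs(beta_new - beta)) < 1e-10) return(beta_new)
    beta <- beta_new
  }
  beta
}

bisquare_rho <- function(r, s, c_tune = 4.685) {
  u <- pmin(abs(r / (s * c_tune)), 1)
  sum(1 - (1 - u^2)^3)
}

#' Flag outlier wells by robust polynomial regression
#'
#' MM-type robust regression of the standardized response on a degree-4
#' polynomial in log dose: the residual scale is a Huber proposal-2
#' M-estimate from an initial Huber regression (finite-sample corrected by
#' `1/sqrt(1 - p/n)`); with that scale fixed, bisquare IRLS (tuning constant
#' 4.685, 95% Gaussian efficiency) is run from both the Huber fit and a
#' high-breakdown least-trimmed-squares fit, and the solution with the
#' smaller robust criterion is kept. Wells with final bisquare weight below
#' `weight_cutoff` (default 0.4) are flagged as outliers and excluded from
#' downstream curve fitting.
#'
#' @param points data.frame with `log_dose` and `response` columns (one
#'   (compound, sample) group, standardized).
#' @param degree polynomial degree (default 4).
#' @param weight_cutoff robust-weight exclusion threshold (default 0.4).
#' @return the input with `robust_weight` and `outlier` columns appended.
#' @export
flag_outliers <- function(points, degree = 4, weight_cutoff = 0.4) {
  y <- points$response
  lx <- points$log_dose
  n <- length(y)
  if (n < degree + 2)
    stop_named("need at least %d points for a degree-%d robust fit",
               degree + 2, degree)
  X <- stats::model.matrix(~ stats::poly(lx, degree))
  p <- ncol(X)
  huber <- MASS::rlm(X, y, psi = MASS::psi.huber,
                     scale.est = "proposal 2", method = "M", maxit = 200)
  s <- huber$s / sqrt(1 - p / n)
  starts <- list(stats::coef(huber))
  lts <- try(MASS::lqs(X, y, intercept = FALSE), silent = TRUE)
  if (!inherits(lts, "try-error")) starts <- c(starts, list(stats::coef(lts)))
  cands <- lapply(starts, function(b) bisquare_irls(X, y, b, s))
  crit <- vapply(cands, function(b) bisquare_rho(y - X %*% b, s), 0)
  beta <- cands[[which.min(crit)]]
  u <- pmin(abs(as.vector(y - X %*% beta) / (s * 4.685)), 1)
  points$robust_weight <- (1 - u^2)^2
  points$outlier <- points$robust_weight < weight_cutoff
  attr(points, "residual_scale") <- s
  points
}

#' Fit a five-parameter log-logistic curve
#'
#' Least squares fit of `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))^f`
#' to non-excluded points. Internally `ln e` is the free parameter; bounds
#' are `|b| <= 50` and `f` in (0.1, 10). Initialization sets `d` to the mean
#' response at the lowest dose, `c` at the highest dose, `e` to the
#' geometric-mean dose and `f = 1`, with multi-start over the sign of `b`.
#'
#' @param dose dose vector (uM, positive).
#' @param response standardized responses.
#' @param maxit optimizer iteration cap.
#' @return list of class `fivepl_fit`: `params` ([fivepl_params]),
#'   `converged`, `residual_scale`, `n_used`, `rss`.
#' @export
fit_5pl <- function(dose, response, maxit = 300) {
  keep <- is.finite(dose) & is.finite(response) & dose > 0
  dose <- dose[keep]; response <- response[keep]
  if (length(dose) < 6 || length(unique(dose)) < 4)
    stop_named("need >= 6 points spanning >= 4 distinct doses")
  lx <- log(dose)
  n <- length(response)

  # perfectly flat plates are unidentifiable for the optimizer but have a
  # well-defined degenerate solution: a constant curve at the common level
  if (stats::sd(response) < 1e-10) {
    lev <- mean(response)
    return(structure(list(params = fivepl_params(b = 1, c = lev, d = lev,
                                                 e = exp(mean(range(lx))),
                                                 f = 1),
                          converged = TRUE, residual_scale = 0,
                          n_used = n, rss = 0),
                     class = "fivepl_fit"))
  }

  dat <- data.frame(y = response, lx = lx)
  c0 <- mean(response[dose == max(dose)])
  d0 <- mean(response[dose == min(dose)])
  starts <- expand.grid(b = c(1, -1, 0.3, -0.3, 3, -3), f = c(1, 0.5, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(b = starts$b[i], c = c0, d = d0,
               loge = mean(range(lx)), f = starts$f[i])
    ft <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + exp(b * (lx - loge)))^f,
      data = dat, start = st,
      lower = c(-50, -Inf, -Inf, -Inf, 0.1),
      upper = c(50, Inf, Inf, Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = maxit))), silent = TRUE)
    if (!inherits(ft, "try-error") &&
        (is.null(best) || stats::deviance(ft) < stats::deviance(best)))
      best <- ft
    # the first two starts almost always suffice on clean sigmoid data;
    # the remaining grid only matters for heavily contaminated plates
    tss <- sum((response - mean(response))^2)
    if (!is.null(best) &&
        ((i >= 2 && stats::deviance(best) < 1e-3 * tss) ||
         (i >= 6 && stats::deviance(best) < 0.5 * tss)))
      break
  }
  if (!is.null(best)) {
    cf <- stats::coef(best)
    return(structure(list(params = fivepl_params(b = unname(cf["b"]),
                                                 c = unname(cf["c"]),
                                                 d = unname(cf["d"]),
                                                 e = exp(unname(cf["loge"])),
                                                 f = unname(cf["f"])),
                          converged = best$convInfo$isConv %||% TRUE,
                          residual_scale = sqrt(stats::deviance(best) /
                                                max(1, n - 5)),
                          n_used = n, rss = stats::deviance(best)),
                     class = "fivepl_fit"))
  }

  # derivative-free fallback for plates where the Jacobian is degenerate at
  # every start; flagged as non-converged
  obj <- function(p) {
    pr <- p[2] + (p[3] - p[2]) / (1 + exp(p[1] * (lx - p[4])))^exp(p[5])
    sum((response - pr)^2)
  }
  op <- stats::optim(c(1, c0, d0, mean(range(lx)), 0), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000))
  structure(list(params = fivepl_params(b = op$par[1], c = op$par[2],
                                        d = op$par[3], e = exp(op$par[4]),
                                        f = exp(op$par[5])),
                 converged = FALSE,
                 residual_scale = sqrt(op$value / max(1, n - 5)),
                 n_used = n, rss = op$value),
            class = "fivepl_fit")
}

#' @export
print.fivepl_fit <- function(x, ...) {
  with(x$params, cat(sprintf(
    "5PL fit: b=%.3g c=%.3g d=%.3g e=%.3g uM f=%.3g (n=%d, residual scale %.3g)\n",
    b, c, d, e, f, x$n_used, x$residual_scale)))
  invisible(x)
}

#' Normalized area under a fitted dose-response curve
#'
#' Integrates the expected standardized response over the log-dose range and
#' divides by the range width, so a no-effect curve scores exactly 1 and
#' values above 1 occur when treated responses exceed controls. Set
#' `normalize = FALSE` for the raw integral.
#'
#' @param fit a `fivepl_fit` (or a [fivepl_params]).
#' @param dose_min,dose_max integration range (uM, positive).
#' @param normalize divide by the log-range width (default TRUE).
#' @return list with `auc` and `dose_range`.
#' @export
compute_auc <- function(fit, dose_min, dose_max, normalize = TRUE) {
  if (!(dose_min > 0 && dose_max > dose_min))
    stop_named("need 0 < dose_min < dose_max")
  params <- if (inherits(fit, "fivepl_fit")) fit$params else fit
  lo <- log(dose_min); hi <- log(dose_max)
  val <- stats::integrate(function(u) fivepl(exp(u), params), lo, hi,
                          subdivisions = 1000L, rel.tol = 1e-9)$value
  list(auc = if (normalize) val / (hi - lo) else val,
       dose_range = c(dose_min, dose_max))
}

#' Monotone-spline AUC cross-check
#'
#' Alternative AUC from a monotone Hyman spline through the dose-wise mean
#' standardized responses, integrated on the log-dose scale. Used as a
#' model-free check on the 5PL-based estimate.
#'
#' @param points standardized, outlier-filtered points (`log_dose`,
#'   `response`).
#' @param normalize divide by the log-range width (default TRUE).
#' @return normalized AUC.
#' @export
compute_auc_mspline <- function(points, normalize = TRUE) {
  mu <- tapply(points$response, points$log_dose, mean)
  lx <- as.numeric(names(mu))
  ord <- order(lx)
  sf <- stats::splinefun(lx[ord], mu[ord], method = "hyman")
  val <- stats::integrate(sf, min(lx), max(lx), subdivisions = 1000L)$value
  if (normalize) val / diff(range(lx)) else val
}

#' Run the full drug-response pipeline on a plate table
#'
#' Standardize by control medians, flag outliers per (compound, sample)
#' group, fit the 5PL to the retained wells, and integrate the normalized
#' AUC over the observed dose range (overridable).
#'
#' @param tab dose-response data.frame.
#' @param degree,weight_cutoff outlier-flagging parameters.
#' @param range_min,range_max integration range; defaults to each group's
#'   observed dose extremes.
#' @return list with `results` (per-group data.frame: compound, sample,
#'   auc, b, c, d, e, f, n_used, n_excluded, converged) and `points` (all
#'   standardized wells with weights and flags).
#' @export
drug_auc_pipeline <- function(tab, degree = 4, weight_cutoff = 0.4,
                              range_min = NULL, range_max = NULL) {
  std <- standardize_responses(tab)
  groups <- split(std, list(std$compound, std$sample), drop = TRUE)
  pts_list <- list(); res_list <- list()
  for (g in groups) {
    g <- flag_outliers(g, degree = degree, weight_cutoff = weight_cutoff)
    kept <- g[!g$outlier, ]
    fit <- fit_5pl(kept$dose_uM, kept$response)
    lo <- range_min %||% min(g$dose_uM)
    hi <- range_max %||% max(g$dose_uM)
    auc <- compute_auc(fit, lo, hi)
    res_list[[length(res_list) + 1]] <- data.frame(
      compound = g$compound[1], sample = g$sample[1], auc = auc$auc,
      b = fit$params$b, c = fit$params$c, d = fit$params$d,
      e = fit$params$e, f = fit$params$f,
      n_used = nrow(kept), n_excluded = sum(g$outlier),
      converged = fit$converged)
    pts_list[[length(pts_list) + 1]] <- g
  }
  list(results = do.call(rbind, res_list),
       points = do.call(rbind, pts_list))
}

#' Median-split sensitivity classification
#'
#' Each sample is summarized by its mean AUC across the given compounds and
#' labeled `sensitive` when below the cohort median, `resistant` when above,
#' and `unassigned` when exactly at it.
#'
#' @param auc_table data.frame with `compound`, `sample`, `auc`.
#' @param compounds compounds to average over (default: all present).
#' @return data.frame: sample, mean_auc, label.
#' @export
classify_sensitivity <- function(auc_table, compounds = NULL) {
  compounds <- compounds %||% unique(auc_table$compound)
  sub <- auc_table[auc_table$compound %in% compounds, ]
  if (!nrow(sub)) stop_named("no AUC rows for the requested compounds")
  mean_auc <- tapply(sub$auc, sub$sample, mean)
  if (length(mean_auc) < 2) stop_named("need >= 2 samples to classify")
  med <- stats::median(mean_auc)
  out <- data.frame(sample = names(mean_auc), mean_auc = as.numeric(mean_auc),
                    label = ifelse(mean_auc < med, "sensitive",
                                   ifelse(mean_auc > med, "resistant",
                                          "unassigned")),
                    row.names = NULL)
  out[order(out$sample), ]
}

#' Pearson correlation of AUCs between paired samples
#'
#' @param auc_a,auc_b named AUC vectors (names = compounds); at least 3
#'   shared compounds required.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_auc_pairs <- function(auc_a, auc_b) {
  shared <- intersect(names(auc_a), names(auc_b))
  if (length(shared) < 3) stop_named("need >= 3 shared compounds")
  ct <- stats::cor.test(auc_a[shared], auc_b[shared], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}
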