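# Standardization, robust outlier flagging, 5PL fitting, AUC and
# classification.

clean_plate <- function(params = fivepl_params(), noise_sd = 0, seed = 51,
                        ...) {
  gen_dose_response(params, noise_sd = noise_sd, seed = seed, ...)
}

test_that("standardize_responses divides by the group control median", {
  tab <- data.frame(
    compound = "d", sample = "s",
    dose_uM = c(1, 10, NA, NA, NA),
    replicate = c(1, 1, 1, 2, 3),
    response = c(55, 30, 100, 110, 90),
    is_control = c(0, 0, 1, 1, 1))
  std <- standardize_responses(tab)
  expect_equal(std$response, c(0.55, 0.30))
  expect_equal(std$control_median[1], 100)

  # all responses at control level standardize to 1
  flat <- tab; flat$response <- 100
  expect_equal(standardize_responses(flat)$response, c(1, 1))

  # uniform rescaling of raw values cancels
  scaled <- tab; scaled$response <- tab$response * 7.3
  expect_equal(standardize_responses(scaled)$response, std$response)

  noctrl <- tab[tab$is_control == 0, ]
  expect_error(standardize_responses(noctrl), "control")
})

test_that("flag_outliers keeps clean plates and catches a gross outlier", {
  sim <- clean_plate()
  std <- standardize_responses(sim$table)
  flagged <- flag_outliers(std)
  expect_true(all(flagged$robust_weight >= 0 & flagged$robust_weight <= 1))
  expect_false(any(flagged$outlier))          # noise-free: nothing flagged

  expect_error(flag_outliers(std[1:4, ]), "at least 6")

  # single x5 outlier is flagged, and flagged alone, in >= 95% of seeds
  res <- vapply(1:200, function(seed) {
    sim <- gen_dose_response(seed = seed, outlier_rate = 0)
    std <- standardize_responses(sim$table)
    i <- ((seed * 7) %% nrow(std)) + 1
    std$response[i] <- std$response[i] * 5
    fl <- flag_outliers(std)
    c(hit = fl$outlier[i], exact = sum(fl$outlier) == 1 && fl$outlier[i])
  }, c(hit = NA, exact = NA))
  expect_gte(mean(res["hit", ]), 0.95)
  expect_gte(mean(res["exact", ]), 0.95)
})

test_that("clean noisy plates rarely lose any well", {
  res <- vapply(1:200, function(seed) {
    sim <- gen_dose_response(seed = 1000 + seed, outlier_rate = 0)
    !any(flag_outliers(standardize_responses(sim$table))$outlier)
  }, logical(1))
  expect_gte(mean(res), 0.95)
})

test_that("fit_5pl recovers noise-free parameters to 1e-3 relative", {
  true <- fivepl_params(b = 1.5, c = 0.1, d = 1, e = 1, f = 1.3)
  sim <- clean_plate(true)
  std <- standardize_responses(sim$table)
  fit <- fit_5pl(std$dose_uM, std$response)
  for (p in c("b", "c", "d", "e", "f"))
    expect_equal(fit$params[[p]], true[[p]], tolerance = 1e-3)
  expect_true(fit$converged)

  # flat data: both asymptotes at 1, AUC exactly 1
  flat <- clean_plate(fivepl_params(c = 1, d = 1))
  stdf <- standardize_responses(flat$table)
  fitf <- fit_5pl(stdf$dose_uM, stdf$response)
  expect_equal(fitf$params$c, 1, tolerance = 1e-6)
  expect_equal(fitf$params$d, 1, tolerance = 1e-6)
  expect_equal(compute_auc(fitf, 30 / 10^3.5, 30)$auc, 1, tolerance = 1e-6)

  expect_error(fit_5pl(c(1, 2, 3), c(1, 1, 1)), "6 points")
})

test_that("the 5PL nests the 4PL (f = 1) on noise-free data", {
  true4 <- fivepl_params(b = 1.2, c = 0.05, d = 1, e = 0.5, f = 1)
  sim <- clean_plate(true4)
  std <- standardize_responses(sim$table)
  fit <- fit_5pl(std$dose_uM, std$response)
  # oracle: 4PL least squares with f fixed at 1
  fit4 <- minpack.lm::nlsLM(
    y ~ c + (d - c) / (1 + exp(b * (lx - loge))),
    data = data.frame(y = std$response, lx = log(std$dose_uM)),
    start = list(b = 1, c = 0.05, d = 1, loge = 0))
  grid <- exp(seq(log(min(std$dose_uM)), log(max(std$dose_uM)), length.out = 50))
  pred5 <- fivepl(grid, fit$params)
  cf <- coef(fit4)
  pred4 <- cf["c"] + (cf["d"] - cf["c"]) /
    (1 + exp(cf["b"] * (log(grid) - cf["loge"])))
  expect_equal(pred5, unname(pred4), tolerance = 1e-4)
})

test_that("compute_auc matches a fine-grid trapezoid and can exceed 1", {
  set.seed(52)
  for (i in 1:5) {
    pars <- fivepl_params(b = runif(1, 0.5, 3), c = runif(1, 0, 0.3),
                          d = runif(1, 0.8, 1.2), e = 10^runif(1, -1, 1),
                          f = runif(1, 0.3, 3))
    auc <- compute_auc(pars, 0.01, 30)$auc
    u <- seq(log(0.01), log(30), length.out = 4000)
    y <- fivepl(exp(u), pars)
    trap <- sum(diff(u) * (head(y, -1) + tail(y, -1)) / 2) / diff(range(u))
    expect_equal(auc, trap, tolerance = 1e-3)
  }

  # treated wells above control level push the AUC above 1
  stim <- compute_auc(fivepl_params(c = 1.05, d = 1.4, e = 1), 0.01, 30)
  expect_gt(stim$auc, 1)
  expect_error(compute_auc(fivepl_params(), 10, 1), "dose_min")
})

test_that("monotone-spline AUC agrees with the 5PL AUC on clean data", {
  sim <- clean_plate()
  std <- standardize_responses(sim$table)
  auc_spline <- compute_auc_mspline(std)
  expect_equal(auc_spline, sim$true_auc, tolerance = 0.02)
})

test_that("pipeline is invariant to replicate order and raw scale", {
  sim <- gen_dose_response(seed = 53, noise_sd = 0.03)
  res1 <- drug_auc_pipeline(sim$table)$results

  set.seed(60)
  perm <- sample(nrow(sim$table))
  res2 <- drug_auc_pipeline(sim$table[perm, ])$results
  expect_equal(res1$auc, res2$auc, tolerance = 1e-6)

  scaled <- sim$table; scaled$response <- scaled$response * 11.7
  res3 <- drug_auc_pipeline(scaled)$results
  expect_equal(res1$auc, res3$auc, tolerance = 1e-6)
})

test_that("outlier flagging shields the AUC from a gross outlier", {
  sim <- gen_dose_response(seed = 54, noise_sd = 0.03)
  tab <- sim$table
  i <- which(tab$is_control == 0)[5]
  tab$response[i] <- tab$response[i] * 5
  auc_robust <- drug_auc_pipeline(tab)$results$auc
  auc_naive <- drug_auc_pipeline(tab, weight_cutoff = 0)$results$auc
  expect_lt(abs(auc_robust - sim$true_auc), abs(auc_naive - sim$true_auc))
})

test_that("classification splits at the cohort median AUC", {
  tab <- data.frame(compound = "d",
                    sample = c("a", "b", "c", "e"),
                    auc = c(0.2, 0.4, 0.8, 0.9))
  cls <- classify_sensitivity(tab)
  expect_equal(cls$label[cls$sample %in% c("a", "b")],
               c("sensitive", "sensitive"))
  expect_equal(cls$label[cls$sample %in% c("c", "e")],
               c("resistant", "resistant"))

  same <- tab; same$auc <- 0.5
  expect_true(all(classify_sensitivity(same)$label == "unassigned"))
  expect_equal(classify_sensitivity(tab[c(3, 1, 4, 2), ]), cls)
})

test_that("paired AUC correlation matches a hand computation", {
  a <- c(d1 = 0.2, d2 = 0.5, d3 = 0.8, d4 = 0.4)
  b <- c(d1 = 0.25, d2 = 0.45, d3 = 0.9, d4 = 0.35)
  res <- correlate_auc_pairs(a, b)
  expect_equal(res$r, cor(a, b))
  expect_equal(res$n, 4)
  expect_equal(correlate_auc_pairs(a, a)$r, 1)
  expect_equal(correlate_auc_pairs(a, -b)$r, -res$r)
  expect_error(correlate_auc_pairs(a[1:2], b[1:2]), "3 shared")
})
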