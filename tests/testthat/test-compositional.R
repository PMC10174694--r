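# Compositional geometry: imputation, CLR/ILR, Aitchison distance,
# clustering, robustness sweep, and the group tests.

test_that("impute_and_close replaces sub-epsilon entries and re-closes", {
  x <- signature_activities(matrix(c(0.5, 0.5, 0), 1))
  out <- impute_and_close(x, 0.01)
  expect_equal(unname(out[1, ]), c(0.5, 0.5, 0.01) / 1.01)

  y <- signature_activities(matrix(c(0.4, 0.35, 0.25), 1))
  expect_equal(unclass(impute_and_close(y, 0.01)), unclass(y),
               ignore_attr = TRUE)

  r <- random_compositions(20, 5, seed = 1)
  r[r < 0.05] <- 0
  r <- r / rowSums(r)
  expect_equal(unname(rowSums(impute_and_close(signature_activities(r)))),
               rep(1, 20))
  expect_true(all(impute_and_close(signature_activities(r)) > 0))

  expect_error(impute_and_close(matrix(c(0, 0, 0, 1, 0, 0), 2,
                                       byrow = TRUE), 0.01),
               "no information")
  expect_error(impute_and_close(x, 0.7), "epsilon")
})

test_that("clr_transform matches its defining formula", {
  u <- matrix(1 / 5, 2, 5)
  expect_equal(clr_transform(u), matrix(0, 2, 5), ignore_attr = TRUE)

  x <- c(0.5, 0.25, 0.25)
  g <- prod(x)^(1 / 3)
  expect_equal(as.vector(clr_transform(matrix(x, 1))), log(x / g))

  r <- random_compositions(50, 7, seed = 2)
  expect_equal(unname(rowSums(clr_transform(r))), rep(0, 50), tolerance = 1e-9)
  # scale invariance after closure: clr(x) == clr(lambda x / sum)
  expect_equal(clr_transform(r), clr_transform(3.7 * r / rowSums(3.7 * r)),
               tolerance = 1e-12)

  expect_error(clr_transform(matrix(c(0.5, 0.5, 0), 1)), "impute_and_close")
})

test_that("ilr_transform is an isometry of the Aitchison geometry", {
  r <- random_compositions(200, 7, seed = 3)
  il <- ilr_transform(r)
  expect_equal(ncol(il), 6)
  expect_equal(as.vector(ilr_transform(matrix(1 / 7, 1, 7))), rep(0, 6))

  for (i in 1:50) {
    a <- r[2 * i - 1, ]; b <- r[2 * i, ]
    expect_equal(sqrt(sum((il[2 * i - 1, ] - il[2 * i, ])^2)),
                 aitchison_distance(a, b), tolerance = 1e-10)
  }

  # K = 2 closed form
  x2 <- matrix(c(0.7, 0.3), 1)
  expect_equal(as.vector(ilr_transform(x2)), log(0.7 / 0.3) / sqrt(2))

  bad <- matrix(runif(12), 3, 4)
  expect_error(ilr_transform(random_compositions(2, 4), bad), "orthonormal")
})

test_that("aitchison_distance is a metric matching its brute-force definition", {
  r <- random_compositions(30, 6, seed = 4)
  expect_equal(aitchison_distance(r[1, ], r[1, ]), 0)
  for (i in 1:10) {
    a <- r[3 * i - 2, ]; b <- r[3 * i - 1, ]; c <- r[3 * i, ]
    expect_equal(aitchison_distance(a, b), brute_aitchison(a, b),
                 tolerance = 1e-12)
    expect_equal(aitchison_distance(a, b), aitchison_distance(b, a))
    expect_lte(aitchison_distance(a, c),
               aitchison_distance(a, b) + aitchison_distance(b, c) + 1e-12)
  }
})

test_that("cluster_activities recovers separated groups and is monotone", {
  dup <- signature_activities(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2),
                                    c(0.1, 0.1, 0.8)))
  cl <- cluster_activities(dup)
  expect_equal(min(cl$hclust$height), 0)          # identical samples merge at 0

  centers <- rbind(prop.table(c(10, 1, 1, 1, 1, 1, 1)),
                   prop.table(c(1, 1, 1, 10, 1, 1, 1)))
  sim <- gen_signature_cohort(15, centers, concentration = 80, seed = 5)
  cl2 <- cluster_activities(sim$activities, cut_k = 2)
  expect_equal(mclust::adjustedRandIndex(cl2$labels, sim$groups), 1)
  expect_true(all(diff(cl2$hclust$height) >= -1e-12))  # complete linkage

  expect_error(cluster_activities(sim$activities[1, , drop = FALSE]),
               "2 samples")
})

test_that("imputation robustness reports cophenetic and ARI agreement", {
  # zero-free table: imputation is a no-op, dendrograms identical
  r <- signature_activities(random_compositions(12, 5, seed = 6) * 0.8 + 0.04)
  rb <- imputation_robustness(r, epsilons = c(0.001, 0.01, 0.02), ks = 2)
  expect_equal(nrow(rb$pairs), 3)                 # all epsilon pairs
  expect_equal(rb$pairs$cophenetic_cor, rep(1, 3))

  sim <- gen_signature_cohort(12, dominant_centers(), concentration = 200,
                              zero_rate = 0.1, seed = 7)
  rb2 <- imputation_robustness(sim$activities, ks = 2)
  expect_true(all(rb2$pairs$ari_k2 == 1))
  expect_error(imputation_robustness(r, epsilons = 0.01), "2 epsilons")
})

test_that("Wald test degenerates correctly and respects permutation symmetry", {
  g <- signature_activities(random_compositions(8, 5, seed = 8))
  wt <- differential_abundance_wald(g, g)
  expect_equal(wt$statistic, 0, tolerance = 1e-12)
  expect_equal(wt$p_value, 1)
  expect_equal(wt$df, 4)

  # statistic unchanged under a row permutation of the basis
  h <- signature_activities(random_compositions(9, 5, seed = 9))
  V <- ilr_basis(5)
  wt1 <- differential_abundance_wald(g, h, basis = V)
  wt2 <- differential_abundance_wald(g, h, basis = V[c(3, 1, 4, 2), ])
  expect_equal(wt1$statistic, wt2$statistic, tolerance = 1e-12)

  # power grows with a real shift on one log-ratio coordinate
  centers <- rbind(rep(1 / 7, 7), prop.table(c(3, rep(1, 6))))
  sim <- gen_signature_cohort(30, centers, concentration = 50, seed = 10)
  wt3 <- differential_abundance_wald(sim$activities[sim$groups == 1, ],
                                     sim$activities[sim$groups == 2, ])
  expect_lt(wt3$p_value, 1e-6)
})

test_that("random-one-per-donor pairing selects one sample per donor", {
  acts <- signature_activities(random_compositions(12, 4, seed = 11))
  donors <- rep(paste0("D", 1:4), each = 3)
  wt <- differential_abundance_wald(acts[1:6, ], acts[7:12, ],
                                    paired_policy = "random-one-per-donor",
                                    donors_a = donors[1:6],
                                    donors_b = donors[7:12], seed = 1)
  expect_equal(wt$n_a, 2)   # 2 donors in each half
  expect_equal(wt$n_b, 2)
  expect_error(differential_abundance_wald(acts[1:6, ], acts[7:12, ],
                                           paired_policy = "random-one-per-donor"),
               "donor")
})

test_that("welch_t matches the textbook formula on a toy", {
  a <- c(1.1, 2.3, 3.1); b <- c(2.0, 4.5, 6.1)
  res <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  expect_equal(res$statistic, (mean(a) - mean(b)) / sqrt(se2))
  df <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$df, df)
  expect_equal(res$p_value, 2 * pt(-abs(res$statistic), df))

  swapped <- welch_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("segment-count NB LRT matches a profile-likelihood grid oracle", {
  a <- c(150, 180, 210); b <- c(160, 190, 220)
  res <- segment_count_test(a, b)

  # oracle: ML mean of an NB is the sample mean for any theta, so profile
  # the likelihood over theta on a fine grid, separately under each model
  nb_ll <- function(y, mu, theta) sum(dnbinom(y, mu = mu, size = theta, log = TRUE))
  prof <- function(lls) {
    grid <- exp(seq(log(0.5), log(5000), length.out = 20000))
    max(vapply(grid, lls, 0))
  }
  ll_null <- prof(function(th) nb_ll(c(a, b), mean(c(a, b)), th))
  ll_alt <- prof(function(th) nb_ll(a, mean(a), th) + nb_ll(b, mean(b), th))
  expect_equal(res$statistic, 2 * (ll_alt - ll_null), tolerance = 1e-4)

  ident <- segment_count_test(c(100, 120, 140), c(100, 120, 140))
  expect_lt(ident$statistic, 1e-6)
  expect_gt(ident$p_value, 0.99)

  expect_error(segment_count_test(c(1.5, 2), c(1, 2)), "integer")
})
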