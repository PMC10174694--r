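# Shared fixture builders; everything is generated in code.

toy_profile <- function(sample_id = "toy",
                        segs = data.frame(chrom = "chr1",
                                          start = c(0, 100),
                                          end = c(100, 300),
                                          cn = c(2, 5))) {
  cn_profile(sample_id, segs)
}

rdirichlet_test <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, byrow = TRUE)
  x / rowSums(x)
}

random_compositions <- function(n, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rgamma(n * K, shape = 2), n)
  x / rowSums(x)
}

# independent brute-force oracles used across tests
brute_aitchison <- function(a, b) {
  ga <- prod(a)^(1 / length(a)); gb <- prod(b)^(1 / length(b))
  sqrt(sum((log(a / ga) - log(b / gb))^2))
}

brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# Cohort emulating dominance-structured signature activities: each group is
# dominated by three signatures with the rest near zero. With the small
# activities sitting close to the imputation values, the epsilon sweep
# perturbs the geometry far less than the group separation (the sense in
# which the cohort is "well separated").
dominant_centers <- function() {
  rbind(prop.table(c(32, 32, 32, 0.33, 0.33, 0.33, 0.33)),
        prop.table(c(0.33, 0.33, 0.33, 32, 32, 32, 0.33)))
}

two_clade_sim <- function(n_cells = 100, n_bins = 500, frac = c(0.7, 0.3),
                          shift_frac = 0.2, noise_sd = 0.3, seed = 1) {
  base <- rep(2, n_bins)
  gen_sc_cn(n_cells, n_bins,
            clades = list(
              clade_spec(frac[1], base),
              clade_spec(frac[2], base,
                         list(list(from = 1, to = round(shift_frac * n_bins),
                                   offset = 1)))),
            noise = noise_model(alpha = noise_sd, beta = 0),
            seed = seed)
}
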