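# Shared fixtures: small generating truths and hand-built datasets.

# quick FA truth with mild dimensions for engine-level tests
small_truth <- function(p = 4, m = 16, k = 1, seed = 1, reps = 2,
                        rep_var = 0.2, block_var = 0) {
  j <- seq_len(p)
  L <- matrix(0, p, max(k, 1))
  if (k >= 1) L[, 1] <- 1.2 + 0.3 * (j - 1) / max(p - 1, 1)
  if (k >= 2) L[, 2] <- 0.8 * cos(2 * pi * (j - 0.5) / p)
  L <- L[, seq_len(max(k, 1)), drop = FALSE]
  if (k == 0) L <- matrix(0, p, 0)
  met_truth(
    n_env = p, n_geno = m, loadings = L,
    specific_var = 0.3 + 0.1 * (j %% 2),
    resid_var = 0.5 + 0.2 * (j %% 3),
    rep_var = rep_var, block_var = block_var,
    env_means = 10 + seq_len(p),
    env_year = rep(1L, p),
    turnover = list(`1` = seq_len(m)),
    reps = reps, block_size = 4L, trait = "t1", seed = seed
  )
}

# balanced single-environment RCBD records for lme4-level tests
rcbd_records <- function(m = 50, r = 3, s2g = 4, s2r = 0.5, s2e = 1,
                         seed = 1, env = "2015::locA") {
  set.seed(seed)
  g <- rnorm(m, 0, sqrt(s2g))
  b <- rnorm(r, 0, sqrt(s2r))
  rec <- expand.grid(genotype = sprintf("G%03d", 1:m), replicate = 1:r)
  rec$year <- 2015L
  rec$location <- sub(".*::", "", env)
  rec$environment <- env
  rec$block <- NA_integer_
  rec$trait <- "yield"
  rec$value <- g[as.integer(factor(rec$genotype))] + b[rec$replicate] +
    rnorm(nrow(rec), 0, sqrt(s2e))
  rec
}

# Table-style carotenoid group archetypes (three profile regimes: low /
# intermediate / high accumulation) used in profiling recovery tests
archetype_profiles <- function(n_per = c(8, 36, 18), noise_sd = 0.4,
                               seed = 1) {
  means <- rbind(
    c(10.5, 15.5, 4.7, 1.3, 5.0),
    c(9.1, 16.7, 6.1, 1.6, 7.0),
    c(11.3, 17.9, 6.2, 1.7, 7.3)
  )
  colnames(means) <- c("lutein", "zeaxanthin", "beta_cryptoxanthin",
                       "alpha_carotene", "beta_carotene")
  set.seed(seed)
  lab <- rep(1:3, n_per)
  X <- means[lab, ] + matrix(rnorm(length(lab) * 5, 0, noise_sd),
                             ncol = 5)
  rownames(X) <- sprintf("H%02d", seq_along(lab))
  list(X = X, labels = lab)
}
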