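test_that("Cullis heritability matches a dense PEV oracle", {
  # two balanced environments, compound model refitted densely
  recs <- do.call(rbind, lapply(1:2, function(j) {
    r <- rcbd_records(m = 12, r = 2, s2g = 9, s2r = 0.2, s2e = 1,
                      seed = j + 40, env = sprintf("2015::l%d", j))
    r$location <- sprintf("l%d", j)
    r
  }))
  ds <- met_dataset(recs)
  vc <- fit_vc(ds, "yield")
  h <- cullis_h2(vc)

  # dense mixed-model equations at the fitted variances
  rec <- ds$records
  env <- as.integer(factor(rec$environment))
  gen <- as.integer(factor(rec$genotype))
  rep_id <- as.integer(interaction(rec$environment, rec$replicate,
                                   drop = TRUE))
  cell <- (gen - 1L) * 2L + env
  n <- nrow(rec); m <- 12
  X <- matrix(1, n, 1)
  Zs <- list(
    env = outer(env, 1:2, `==`) * 1,
    gen = outer(gen, 1:m, `==`) * 1,
    rep = outer(rep_id, 1:4, `==`) * 1,
    int = outer(cell, 1:(2 * m), `==`) * 1
  )
  G <- as.matrix(Matrix::bdiag(
    vc$sigma2_environment * diag(2), vc$sigma2_hybrid * diag(m),
    vc$sigma2_replicate * diag(4), vc$sigma2_interaction * diag(2 * m)))
  sol <- dense_mme(rec$value, X, do.call(cbind, Zs), G,
                   vc$resid_var[env])
  idx <- 2 + seq_len(m)                     # genotype block within Cinv
  P <- sol$pev[idx, idx]
  a <- diag(P)
  vbar <- (m * sum(a) - sum(P)) / (m * (m - 1) / 2)
  h_oracle <- 1 - vbar / (2 * vc$sigma2_hybrid)
  expect_equal(h$h2, h_oracle, tolerance = 1e-8)
  expect_equal(h$mean_pev_diff, vbar, tolerance = 1e-8)
})

test_that("heritability limits: no noise to 1, no signal to 0, always in [0,1]", {
  # shared genotype effects in both environments, vanishing residual noise
  tr_hi <- met_truth(n_env = 2, n_geno = 10,
                     loadings = matrix(3, 2, 1),
                     specific_var = rep(1e-10, 2),
                     resid_var = rep(1e-5, 2), rep_var = 0,
                     env_means = c(10, 12), env_year = rep(1L, 2),
                     turnover = list(`1` = 1:10), reps = 2,
                     block_size = 5, trait = "yield", seed = 55)
  h1 <- cullis_h2(generate_met(tr_hi), "yield")
  expect_gt(h1$h2, 0.999)

  nosignal <- do.call(rbind, lapply(1:2, function(j) {
    r <- rcbd_records(m = 10, r = 2, s2g = 0, s2r = 0.1, s2e = 1,
                      seed = j + 60, env = sprintf("2015::l%d", j))
    r$location <- sprintf("l%d", j)
    r
  }))
  h0 <- cullis_h2(met_dataset(nosignal), "yield")
  expect_lt(h0$h2, 0.3)

  for (seed in 1:3) {
    tr <- small_truth(p = 3, m = 15, k = 1, seed = seed + 70)
    h <- cullis_h2(generate_met(tr), "t1")
    expect_gte(h$h2, 0)
    expect_lte(h$h2, 1)
  }
})

test_that("heritability is invariant to trait rescaling", {
  tr <- small_truth(p = 3, m = 20, k = 1, seed = 81)
  ds <- generate_met(tr)
  h1 <- cullis_h2(ds, "t1")
  rec <- ds$records
  rec$value <- rec$value * 7
  h2_ <- cullis_h2(met_dataset(rec), "t1")
  expect_equal(h1$h2, h2_$h2, tolerance = 1e-4)
})

test_that("balanced-design heritability approaches the classical ratio", {
  # no interaction in truth: h2 ~ s2g / (s2g + mean(s2e)/(p*r))
  p <- 2; m <- 40; r <- 3
  set.seed(91)
  tr <- met_truth(n_env = p, n_geno = m,
                  loadings = matrix(sqrt(6), p, 1),
                  specific_var = rep(1e-8, p), resid_var = rep(1.2, p),
                  rep_var = 0.05, env_means = c(9, 11),
                  env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
                  reps = r, block_size = 8, trait = "t1", seed = 91)
  ds <- generate_met(tr)
  vc <- fit_vc(ds, "t1")
  h <- cullis_h2(vc)
  s2g <- vc$sigma2_hybrid
  closed <- s2g / (s2g + vc$sigma2_interaction / p +
                     mean(vc$resid_var) / (p * r))
  expect_equal(h$h2, closed, tolerance = 0.03)
})

test_that("genetic correlation is exactly 1 for a trait against itself", {
  tr <- small_truth(p = 3, m = 12, seed = 95)
  ds <- generate_met(tr)
  g <- genetic_correlation(ds, "t1", "t1")
  expect_identical(g$r_g, 1)
})

test_that("an affine copy of a trait gives genetic correlation 1", {
  tr <- small_truth(p = 3, m = 30, seed = 96)
  ds <- generate_met(tr)
  rec2 <- ds$records
  rec2$trait <- "t2"
  rec2$value <- 3 + 2 * rec2$value
  both <- met_dataset(rbind(ds$records, rec2))
  g <- suppressWarnings(genetic_correlation(both, "t1", "t2"))
  expect_gt(g$r_g, 0.99)
})

test_that("bivariate REML recovers moderate and null correlations quickly", {
  mk <- function(trait, seed) {
    p <- 3; m <- 120
    met_truth(n_env = p, n_geno = m, loadings = matrix(sqrt(3), p, 1),
              specific_var = rep(0.3, p), resid_var = rep(0.8, p),
              rep_var = 0.1, env_means = rep(10, p),
              env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
              reps = 2, block_size = 6, trait = trait, seed = seed)
  }
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  ds <- generate_multitrait(
    multitrait_truth(list(a = mk("a", 101), b = mk("b", 101)), R))
  g <- genetic_correlation(ds, "a", "b")
  expect_identical(g$method, "bivariate_reml")
  expect_lt(abs(g$r_g - 0.8), 0.2)

  ds0 <- generate_multitrait(
    multitrait_truth(list(a = mk("a", 102), b = mk("b", 102)), diag(2)))
  g0 <- genetic_correlation(ds0, "a", "b")
  expect_lt(abs(g0$r_g), 0.25)
})

test_that("correlation matrix assembles pairwise estimates symmetrically", {
  mk <- function(trait, seed) {
    p <- 2; m <- 40
    met_truth(n_env = p, n_geno = m, loadings = matrix(sqrt(2), p, 1),
              specific_var = rep(0.3, p), resid_var = rep(0.6, p),
              rep_var = 0.05, env_means = rep(10, p),
              env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
              reps = 2, block_size = 5, trait = trait, seed = seed)
  }
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  ds <- generate_multitrait(
    multitrait_truth(list(a = mk("a", 103), b = mk("b", 103)), R))
  M <- genetic_correlation_matrix(ds)
  expect_identical(diag(M$r_g), c(a = 1, b = 1))
  expect_identical(M$r_g[1, 2], M$r_g[2, 1])
  expect_true(abs(M$r_g[1, 2]) <= 1)
})

test_that("pearson matches the textbook formula and validates input", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(2, 3, 8, 6, 12)
  out <- pearson(x, y)
  sx <- x - mean(x); sy <- y - mean(y)
  r_hand <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * pt(abs(t_hand), df = 3, lower.tail = FALSE)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p_value, p_hand, tolerance = 1e-12)
  expect_identical(pearson(x, x)$r, 1)
  expect_identical(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 5)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})
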