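test_that("engine agrees with lme4 on a shared iid-terms model", {
  set.seed(3)
  d <- expand.grid(geno = factor(sprintf("g%02d", 1:20)), rep = factor(1:3))
  d$y <- rnorm(20, 0, 2)[as.integer(d$geno)] +
    rnorm(3, 0, 1)[as.integer(d$rep)] + rnorm(nrow(d))
  f <- metfa:::.reml_fit(d$y, fixed = NULL,
                         iid = list(geno = d$geno, rep = d$rep),
                         subject = NULL)
  lm4 <- lme4::lmer(y ~ 1 + (1 | geno) + (1 | rep), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(f$loglik, as.numeric(logLik(lm4)), tolerance = 1e-6)
  expect_equal(unname(f$iid_var["geno"]), vc$vcov[vc$grp == "geno"],
               tolerance = 1e-4)
  expect_equal(unname(f$resid_var), vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-4)
})

test_that("engine log-likelihood equals the dense REML oracle at the fit", {
  tr <- small_truth(p = 3, m = 8, k = 1, seed = 4)
  ds <- generate_met(tr)
  fit <- fit_fa(ds, "t1", k = 1, use_blocks = FALSE)
  rec <- ds$records
  rec$env <- as.integer(factor(rec$environment))
  rec$geno <- as.integer(factor(rec$genotype))
  rec$rep_id <- as.integer(interaction(rec$environment, rec$replicate,
                                       drop = TRUE))
  V <- dense_fa_V(rec, p = 3, m = 8, Lambda = fit$loadings,
                  Psi = fit$specific_var, resid_var = unname(fit$resid_var),
                  rep_var = unname(fit$design_var["replicate"]))
  X <- model.matrix(~ 0 + factor(env), rec)
  expect_equal(fit$reml_loglik, dense_reml_ll(rec$value, X, V),
               tolerance = 1e-6)
})

test_that("REML log-likelihood trace is monotone non-decreasing", {
  tr <- small_truth(p = 4, m = 20, k = 2, seed = 8)
  ds <- generate_met(tr)
  fit <- fit_fa(ds, "t1", k = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("nested FA orders have non-decreasing log-likelihoods", {
  tr <- small_truth(p = 5, m = 24, k = 2, seed = 10)
  ds <- generate_met(tr)
  ll <- vapply(0:2, function(k) fit_fa(ds, "t1", k = k)$reml_loglik,
               numeric(1))
  expect_true(all(diff(ll) > -1e-4))
})

test_that("permuting environment order permutes loadings, preserves ll/Sigma", {
  tr <- small_truth(p = 4, m = 16, k = 1, seed = 12)
  ds <- generate_met(tr)
  f1 <- fit_fa(ds, "t1", k = 1, use_blocks = FALSE)
  # relabel environments to reverse their sort order
  rec <- ds$records
  map <- setNames(sprintf("2015::z%02d", rev(seq_len(4))),
                  sort(unique(rec$environment)))
  rec$environment <- unname(map[rec$environment])
  rec$location <- sub(".*::", "", rec$environment)
  f2 <- fit_fa(met_dataset(rec), "t1", k = 1, use_blocks = FALSE)
  perm <- rev(seq_len(4))   # new order is the reverse of the old
  expect_equal(f2$reml_loglik, f1$reml_loglik, tolerance = 1e-5)
  expect_equal(unname(f2$Sigma), unname(f1$Sigma[perm, perm]),
               tolerance = 1e-3)
})

test_that("diagonal-truth data yield near-zero loadings at k = 1", {
  p <- 4; m <- 500
  tr <- met_truth(n_env = p, n_geno = m, loadings = matrix(0, p, 0),
                  specific_var = rep(1.5, p), resid_var = rep(0.4, p),
                  rep_var = 0.1, env_means = rep(10, p),
                  env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
                  reps = 2, block_size = 6, trait = "t1", seed = 21)
  ds <- generate_met(tr)
  fit <- fit_fa(ds, "t1", k = 1)
  # all identifiable factor content is in the off-diagonal of Sigma: on
  # diagonal truth it must vanish (a lone-environment factor trading
  # against Psi along the flat ridge is the same Sigma), and the diagonal
  # must recover the generating specific variances
  off <- fit$Sigma[lower.tri(fit$Sigma)]
  expect_lt(mean(abs(off)), 0.1)
  expect_equal(unname(diag(fit$Sigma)), rep(1.5, p), tolerance = 0.2)
})

test_that("percent_vaf arithmetic identities hold", {
  mk <- function(L, psi) {
    structure(list(loadings = L, specific_var = psi, k = ncol(L)),
              class = "fa_fit")
  }
  expect_equal(percent_vaf(mk(cbind(c(1, 1)), c(0, 0)))$overall, 100)
  expect_equal(percent_vaf(mk(cbind(c(1, 1)), c(1, 1)))$overall, 50)
  set.seed(2)
  L <- matrix(rnorm(12), 6, 2); psi <- runif(6, 0.1, 1)
  v <- percent_vaf(mk(L, psi))
  expect_equal(sum(v$per_factor), v$overall, tolerance = 1e-10)
  expect_equal(percent_vaf(mk(matrix(0, 4, 0), rep(1, 4)))$overall, 0)
})

test_that("BLUPs solve the mixed-model equations (dense oracle)", {
  tr <- small_truth(p = 3, m = 6, k = 1, seed = 14)
  ds <- generate_met(tr)
  fit <- fit_fa(ds, "t1", k = 1, use_blocks = FALSE)
  rec <- ds$records
  rec$env <- as.integer(factor(rec$environment))
  rec$geno <- as.integer(factor(rec$genotype))
  rec$rep_id <- as.integer(interaction(rec$environment, rec$replicate,
                                       drop = TRUE))
  n <- nrow(rec); p <- 3; m <- 6
  X <- model.matrix(~ 0 + factor(env), rec)
  Zg <- matrix(0, n, m * p)
  Zg[cbind(seq_len(n), (rec$geno - 1L) * p + rec$env)] <- 1
  q <- max(rec$rep_id)
  Zr <- matrix(0, n, q)
  Zr[cbind(seq_len(n), rec$rep_id)] <- 1
  Sigma <- fit$Sigma
  G <- as.matrix(Matrix::bdiag(kronecker(diag(m), Sigma),
                               unname(fit$design_var["replicate"]) * diag(q)))
  sol <- dense_mme(rec$value, X, cbind(Zg, Zr), G, fit$resid_var[rec$env])
  u_oracle <- matrix(sol$u[seq_len(m * p)], m, p, byrow = TRUE)
  expect_equal(unname(fit$blups), u_oracle, tolerance = 1e-8)
  pb <- predict_blups(fit)
  expect_equal(unname(pb$genotype_means),
               unname(mean(fit$env_means) + rowMeans(fit$blups)),
               tolerance = 1e-12)
})

test_that("BLUPs shrink relative to raw genotype means and vanish without signal", {
  tr <- small_truth(p = 4, m = 20, k = 1, seed = 15)
  ds <- generate_met(tr)
  fit <- fit_fa(ds, "t1", k = 1)
  raw <- tapply(ds$records$value, ds$records$genotype, mean)
  expect_lt(var(predict_blups(fit)$genotype_means), var(raw) + 1e-12)

  # no genetic signal: predictions collapse toward zero
  p <- 3; m <- 30
  tr0 <- met_truth(n_env = p, n_geno = m, loadings = matrix(0, p, 0),
                   specific_var = rep(1e-6, p), resid_var = rep(1, p),
                   rep_var = 0.1, env_means = rep(5, p),
                   env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
                   reps = 2, block_size = 5, trait = "t1", seed = 16)
  ds0 <- generate_met(tr0)
  fit0 <- fit_fa(ds0, "t1", k = 0)
  # near-complete shrinkage: predictions an order of magnitude below the
  # raw genotype-mean deviations
  raw0 <- tapply(ds0$records$value, ds0$records$genotype, mean)
  expect_lt(var(as.vector(rowMeans(fit0$blups))), 0.12 * var(raw0))
  expect_lt(max(abs(fit0$blups)), 0.15)
})

test_that("FA order and dimension preconditions are enforced", {
  tr <- small_truth(p = 3, m = 8, seed = 17)
  ds <- generate_met(tr)
  expect_error(fit_fa(ds, "t1", k = 3), "smaller than")
  expect_error(fit_fa(ds, "t1", k = 4), "smaller than|between")
  expect_error(fit_fa(ds, "nope", k = 1), "no records")
})

test_that("REMLRT statistic and p-value follow the chi-square(1) reference", {
  t0 <- remlrt(-100, -100)
  expect_identical(t0$statistic, 0)
  expect_identical(t0$p_value, 1)
  t1 <- remlrt(-98.08, -100)
  expect_equal(t1$statistic, 3.84, tolerance = 1e-12)
  expect_equal(t1$p_value, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(t1$p_value - 0.05), 1e-3)
  tm <- remlrt(-98.08, -100, mixture = TRUE)
  expect_equal(tm$p_value, 0.5 * pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(remlrt(-101, -100), "below")
})

test_that("variance-component model recovers a compound-symmetry regime", {
  # constant-loading FA(1) truth == genotype main effect + iid interaction
  p <- 6; m <- 48
  set.seed(31)
  tr <- met_truth(n_env = p, n_geno = m,
                  loadings = matrix(sqrt(3), p, 1),
                  specific_var = rep(0.8, p),
                  resid_var = runif(p, 0.4, 0.9), rep_var = 0.2,
                  env_means = rnorm(p, 10, 2),
                  env_year = rep(1L, p), turnover = list(`1` = seq_len(m)),
                  reps = 2, block_size = 6, trait = "t1", seed = 31)
  ds <- generate_met(tr)
  vc <- fit_vc(ds, "t1")
  expect_lt(abs(vc$sigma2_hybrid - 3) / 3, 0.5)
  expect_lt(abs(vc$sigma2_interaction - 0.8) / 0.8, 0.5)
  expect_gt(min(vc$resid_var), 0)

  # drop-one table: the hybrid and interaction tests must be extreme here
  tab <- remlrt_table(ds, "t1", components = c("hybrid", "interaction"))
  expect_true(all(tab$tests$statistic >= 0))
  expect_lt(tab$tests$p_value[tab$tests$component == "hybrid"], 1e-6)
})

test_that("pure-noise data drive all variance components to the boundary", {
  set.seed(5)
  rec <- do.call(rbind, lapply(1:3, function(j) {
    r <- rcbd_records(m = 15, r = 2, s2g = 0, s2r = 0, s2e = 1, seed = j,
                      env = sprintf("2015::l%d", j))
    r$location <- sprintf("l%d", j)
    r
  }))
  vc <- fit_vc(met_dataset(rec), "yield")
  expect_lt(vc$sigma2_hybrid, 0.05)
  expect_lt(vc$sigma2_interaction, 0.08)
  expect_equal(mean(vc$resid_var), 1, tolerance = 0.25)
})
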