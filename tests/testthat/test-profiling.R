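test_that("PCA on exactly uncorrelated unit-variance columns gives unit eigenvalues", {
  set.seed(6)
  raw <- cbind(1, matrix(rnorm(60), 12, 5))
  Q <- qr.Q(qr(raw))[, 2:6]                 # orthonormal, mean-zero columns
  X <- Q * sqrt(11)                         # unit variance, zero correlation
  sc <- pca_scores(X)
  expect_equal(unname(attr(sc, "eigenvalues")), rep(1, 5),
               tolerance = 1e-8)
})

test_that("rank-1 data put all correlation variance on the first component", {
  set.seed(7)
  base <- rnorm(10)
  X <- outer(base, c(1, 2, 3, 4, 5)) +
    matrix(rnorm(50, 0, 1e-8), 10, 5)       # tiny jitter avoids exact ties
  sc <- pca_scores(X)
  ev <- attr(sc, "eigenvalues")
  expect_gt(ev[1], 4.999)
  expect_lt(sum(ev[-1]), 1e-3)
})

test_that("PCA scores match the dense eigen-decomposition oracle", {
  set.seed(8)
  X <- matrix(rnorm(40), 8, 5)
  sc <- pca_scores(X)
  Z <- scale(X)
  es <- eigen(cor(X), symmetric = TRUE)
  oracle <- Z %*% es$vectors
  for (j in 1:5) {
    expect_equal(abs(unname(sc[, j])), abs(unname(oracle[, j])),
                 tolerance = 1e-9)
  }
  expect_equal(unname(attr(sc, "eigenvalues")), es$values,
               tolerance = 1e-10)
  expect_error(pca_scores(cbind(X, 1)), "constant|more genotypes")
  expect_error(pca_scores(X[1:4, ]), "more genotypes")
})

test_that("PCA sign convention is deterministic", {
  set.seed(9)
  X <- matrix(rnorm(40), 8, 5)
  s1 <- pca_scores(X)
  s2 <- pca_scores(X)
  expect_identical(s1, s2)
  rot <- attr(s1, "rotation")
  for (j in 1:5) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
})

test_that("Ward clustering recovers structure and honours bounds", {
  set.seed(10)
  blobs <- rbind(matrix(rnorm(20, 0), 10, 2),
                 matrix(rnorm(20, 8), 10, 2),
                 matrix(rnorm(20, -8), 10, 2))
  lab <- ward_groups(blobs, 3)
  expect_true(same_partition(lab, rep(1:3, each = 10)))
  expect_identical(as.integer(ward_groups(blobs, nrow(blobs))),
                   seq_len(nrow(blobs)))
  expect_error(ward_groups(blobs, 0), ">= 1")
  expect_error(ward_groups(blobs, 31), "exceed")
})

test_that("Ward merges agree with the exhaustive-search oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(16), 8, 2)
    for (g in c(2, 3, 4)) {
      expect_true(same_partition(ward_groups(X, g), ward_oracle(X, g)),
                  label = sprintf("seed %d, %d groups", seed, g))
    }
  }
})

test_that("canonical discriminant analysis matches the generalized eigen oracle", {
  set.seed(11)
  X <- rbind(matrix(rnorm(20, 0), 10, 2),
             matrix(rnorm(20, 2), 10, 2),
             cbind(rnorm(10, 1), rnorm(10, 4)))
  lab <- rep(1:3, each = 10)
  cda <- canonical_discriminant(X, lab)

  f <- factor(lab)
  gm <- rowsum(sweep(X, 2, colMeans(X)), f) / as.vector(table(f))
  B <- crossprod(gm * sqrt(as.vector(table(f))))
  W <- matrix(0, 2, 2)
  for (lv in levels(f)) {
    Xi <- X[f == lv, ]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    W <- W + crossprod(Xi)
  }
  ev <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)
  expect_equal(cda$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(cda$variance_share, ev / sum(ev), tolerance = 1e-10)
  expect_equal(cda$canonical_correlations, sqrt(ev / (1 + ev)),
               tolerance = 1e-10)
  expect_equal(sum(cda$variance_share), 1, tolerance = 1e-10)
  expect_true(all(diff(cda$canonical_correlations) <= 1e-12))
  # unit pooled within-group variance of canonical scores
  sc <- cda$can_scores
  wv <- 0
  for (lv in levels(f)) {
    si <- sc[f == lv, , drop = FALSE]
    wv <- wv + crossprod(sweep(si, 2, colMeans(si)))
  }
  expect_equal(diag(wv / (30 - 3)), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("canonical discriminant agrees with an independent lda implementation", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- rbind(matrix(rnorm(24, 0), 12, 2),
             matrix(rnorm(24, 1.5), 12, 2))
  lab <- rep(1:2, each = 12)
  cda <- canonical_discriminant(X, lab)
  ld <- MASS::lda(X, grouping = lab)
  lda_scores <- predict(ld)$x[, 1]
  expect_gt(abs(cor(cda$can_scores[, 1], lda_scores)), 1 - 1e-8)
})

test_that("degenerate group layouts behave as expected", {
  set.seed(13)
  # separation only along axis 1
  X <- cbind(c(rnorm(10, 0, 0.3), rnorm(10, 6, 0.3)), rnorm(20, 0, 0.3))
  lab <- rep(1:2, each = 10)
  cda <- canonical_discriminant(X, lab)
  expect_equal(cda$variance_share[1], 1, tolerance = 1e-10)
  expect_gt(cda$canonical_correlations[1], 0.97)
  a <- cda$raw_coefficients[, 1]
  expect_gt(abs(a[1]) / sqrt(sum(a^2)), 0.99)

  # identical group means: no discrimination
  Y <- matrix(rnorm(60), 30, 2)
  Y[16:30, ] <- Y[1:15, ]                    # same points in both groups
  cda0 <- canonical_discriminant(Y, rep(1:2, each = 15))
  expect_lt(cda0$canonical_correlations[1], 1e-6)

  expect_error(canonical_discriminant(X, rep(1, 20)), "2 groups")
  expect_error(canonical_discriminant(X, c(rep(1, 19), 2)), "2 members")
})

test_that("structure correlations reproduce plain Pearson correlations", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3)
  lab <- rep(1:2, each = 10)
  V <- X[, 1:2] + matrix(rnorm(40, 0, 0.1), 20, 2)
  cda <- canonical_discriminant(X, lab, structure_vars = V)
  expect_equal(cda$structure_correlations,
               cor(V, cda$can_scores), tolerance = 1e-12)
})

test_that("group summaries report min/max/mean/se per group", {
  lab <- c(1, 1, 1, 2)
  out <- group_summary(lab, c(1, 2, 3, 5))
  g1 <- out[out$group == "1", ]
  expect_equal(g1$mean, 2)
  expect_equal(g1$se, sd(1:3) / sqrt(3))
  expect_equal(g1$se, 1 / sqrt(3), tolerance = 1e-12)
  g2 <- out[out$group == "2", ]
  expect_identical(c(g2$min, g2$max, g2$mean, g2$se), c(5, 5, 5, 0))
  expect_true(all(out$min <= out$mean & out$mean <= out$max))
})

test_that("summaries and shares are invariant to label permutation", {
  set.seed(15)
  X <- matrix(rnorm(60), 20, 3)
  lab <- rep(1:2, each = 10)
  relab <- 3 - lab
  s1 <- group_summary(lab, X)
  s2 <- group_summary(relab, X)
  m1 <- s1[s1$group == "1" & s1$variable == colnames(X)[1], "mean"]
  m2 <- s2[s2$group == "2" & s2$variable == colnames(X)[1], "mean"]
  expect_equal(m1, m2)
  c1 <- canonical_discriminant(X, lab)
  c2 <- canonical_discriminant(X, relab)
  expect_equal(c1$variance_share, c2$variance_share, tolerance = 1e-10)
  expect_equal(c1$canonical_correlations, c2$canonical_correlations,
               tolerance = 1e-10)
})

test_that("three carotenoid archetypes are recovered by PCA + Ward", {
  for (seed in 1:5) {
    arch <- archetype_profiles(seed = seed)
    sc <- pca_scores(arch$X)
    lab <- ward_groups(sc, 3)
    expect_gte(label_agreement(lab, arch$labels), 0.9)
  }
})
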