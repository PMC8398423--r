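# Independent dense-linear-algebra oracles used to cross-check the sparse
# mixed-model machinery.  Everything here is deliberately written with plain
# base-R dense operations and no shared code with the package internals.

# Restricted log-likelihood of y ~ N(X b, V), V supplied densely.
dense_reml_ll <- function(y, X, V) {
  n <- length(y)
  pf <- qr(X)$rank
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  yPy <- as.numeric(t(r) %*% Vi %*% r)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            yPy + (n - pf) * log(2 * pi))
}

# Dense mixed-model-equation solve: returns fixed effects, random-effect
# BLUPs, and the full inverse coefficient matrix (PEV blocks).
# Z is a single dense design for all random effects with joint covariance G.
dense_mme <- function(y, X, Z, G, Rdiag) {
  Rinv <- diag(1 / Rdiag, length(y))
  C11 <- t(X) %*% Rinv %*% X
  C12 <- t(X) %*% Rinv %*% Z
  C22 <- t(Z) %*% Rinv %*% Z + solve(G)
  C <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  rhs <- c(t(X) %*% Rinv %*% y, t(Z) %*% Rinv %*% y)
  Cinv <- solve(C)
  sol <- Cinv %*% rhs
  pf <- ncol(X)
  list(beta = sol[seq_len(pf)], u = sol[-seq_len(pf)],
       Cinv = Cinv, pev = Cinv[-seq_len(pf), -seq_len(pf), drop = FALSE])
}

# Dense V for the FA trial model given parameters and a record table with
# columns env (int), geno (int), rep_id (int in 1..n_repterms or 0).
dense_fa_V <- function(rec, p, m, Lambda, Psi, resid_var, rep_var = NULL) {
  n <- nrow(rec)
  Sigma <- tcrossprod(Lambda) + diag(Psi, p)
  Zg <- matrix(0, n, m * p)
  Zg[cbind(seq_len(n), (rec$geno - 1L) * p + rec$env)] <- 1
  V <- Zg %*% kronecker(diag(m), Sigma) %*% t(Zg)
  if (!is.null(rep_var) && any(rec$rep_id > 0)) {
    q <- max(rec$rep_id)
    Zr <- matrix(0, n, q)
    Zr[cbind(seq_len(n), rec$rep_id)] <- 1
    V <- V + rep_var * Zr %*% t(Zr)
  }
  V + diag(resid_var[rec$env], n)
}

# Greedy Ward agglomeration by exhaustive search over merge pairs, using the
# Lance-Williams Ward cost (increase in within-cluster sum of squares).
# Returns the partition at n_groups as an integer label vector.
ward_oracle <- function(X, n_groups) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  repeat {
    k <- length(clusters)
    if (k <= n_groups) break
    best <- c(Inf, 0L, 0L)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        na <- length(clusters[[a]]); nb <- length(clusters[[b]])
        ma <- colMeans(X[clusters[[a]], , drop = FALSE])
        mb <- colMeans(X[clusters[[b]], , drop = FALSE])
        cost <- na * nb / (na + nb) * sum((ma - mb)^2)
        if (cost < best[1] - 1e-12) best <- c(cost, a, b)
      }
    }
    a <- best[2]; b <- best[3]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
  lab
}

# Two partitions agree up to label permutation?
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(ta > 0) == max(length(unique(a)), length(unique(b)))
}

# Best label agreement between two partitions over label permutations
# (greedy on the confusion matrix; exact for well-separated partitions).
label_agreement <- function(est, truth) {
  tab <- table(est, truth)
  total <- 0
  while (length(tab) && sum(tab) > 0) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[i[1], i[2]]
    tab[i[1], ] <- 0
    tab[, i[2]] <- 0
  }
  total / length(est)
}

# Round half away from zero at `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(abs(x) * s + 0.5) / s * sign(x)
}
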