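# Internal REML engine for linear mixed models of the form
#
#   y = X tau + sum_t Z_t b_t + Z_g u + e
#
# where X holds fixed cell means (one factor or an intercept), each b_t is an
# iid random term (variance sigma2_t I), u is a "structured" random term
# indexed by subject (genotype) crossed with level (environment or trait)
# with covariance Sigma (x) I_m across levels within subject, and e has a
# heterogeneous diagonal covariance with one variance per residual group.
# Supported Sigma structures: factor-analytic "fa" (Lambda Lambda' + Psi),
# "diag", isotropic "iso", and unstructured "us".
#
# Estimation runs in two phases.  (1) A monotone EM/ECM warm start on the
# mixed-model equations: the coefficient matrix is partitioned as
# C = [C_tt C_tr; C_rt C_rr] with the "top" block holding fixed + iid
# effects and the structured block C_rr block-diagonal by subject
# (Sigma^{-1} + diag of weighted counts), so each E-step costs one small
# dense Cholesky per subject plus one Cholesky of the Schur complement;
# M-steps are closed form except for FA(k), which takes an inner
# factor-analysis EM started from the current parameters.  (2) A
# quasi-Newton (L-BFGS) polish on unconstrained parameters (log variances,
# free lower-triangle loadings, log-Cholesky for "us") with analytic REML
# gradients assembled from the same E-step byproducts:
#   d l / d theta = (m/2) tr( dSigma/dtheta . Sigma^-1 (S - Sigma) Sigma^-1 )
# for genetic-covariance parameters (S the conditional second-moment
# matrix), with matching closed forms for iid and residual variances.  EM
# alone crawls along near-flat ridges of the FA likelihood; the gradient
# phase finishes the job at a few dozen extra likelihood evaluations.

.metfa_default_control <- function() {
  list(
    max_iter   = 500L,   # total iteration cap (EM + polish accounting)
    em_iter    = 60L,    # EM warm-start iterations before the polish
    qn_maxit   = 600L,   # L-BFGS iteration cap
    rel_tol    = 1e-8,   # relative change in REML log-likelihood
    par_tol    = 1e-6,   # max-norm relative parameter change
    psi_floor  = 1e-8,   # lower bound for FA specific variances
    var_floor  = 1e-10,  # lower bound for residual / iid variances
    fa_inner   = 50L,    # inner FA-EM iterations per outer M-step
    verbose    = FALSE
  )
}

# Rotate a p x k loading matrix to the identified form with zeros in the
# upper triangle of the leading k x k block (LQ decomposition), positive
# diagonal.  Leaves Lambda Lambda' unchanged.
.lower_triangular_loadings <- function(Lambda) {
  k <- ncol(Lambda)
  if (k <= 1L) {
    if (k == 1L && sum(Lambda) < 0) Lambda <- -Lambda
    return(Lambda)
  }
  A <- Lambda[seq_len(k), , drop = FALSE]
  qrA <- qr(t(A))
  Q <- qr.Q(qrA, complete = TRUE)[, seq_len(k), drop = FALSE]
  L <- Lambda %*% Q
  s <- sign(diag(L[seq_len(k), , drop = FALSE]))
  s[s == 0] <- 1
  L <- sweep(L, 2L, s, `*`)
  L[seq_len(k), ][upper.tri(matrix(0, k, k))] <- 0
  L
}

# One run of EM for maximum-likelihood factor analysis of a covariance
# matrix S (divisor already applied): maximizes -(log|Sigma| + tr(Sigma^-1 S))
# over Sigma = Lambda Lambda' + diag(Psi).  Started from (Lambda, Psi).
.fa_mstep <- function(S, Lambda, Psi, n_iter, psi_floor) {
  k <- ncol(Lambda)
  p <- nrow(Lambda)
  for (it in seq_len(n_iter)) {
    Sigma <- tcrossprod(Lambda) + diag(Psi, p)
    delta <- solve(Sigma, Lambda)                      # p x k
    Czz <- diag(k) - crossprod(Lambda, delta) + crossprod(delta, S %*% delta)
    Cyz <- S %*% delta                                 # p x k
    Lambda_new <- Cyz %*% solve((Czz + t(Czz)) / 2)
    Psi_new <- pmax(diag(S - Lambda_new %*% t(Cyz)), psi_floor)
    conv <- max(abs(Lambda_new - Lambda)) < 1e-12 &&
      max(abs(Psi_new - Psi)) < 1e-12
    Lambda <- Lambda_new
    Psi <- Psi_new
    if (conv) break
  }
  list(Lambda = Lambda, Psi = Psi)
}

# Structure-specific M-step given the conditional second-moment matrix
# S_mat = (sum_i u_i u_i' + PEV_i) / m.
.structure_mstep <- function(struct, S_mat, control) {
  p <- nrow(S_mat)
  switch(struct$type,
    fa = {
      fit <- .fa_mstep(S_mat, struct$Lambda, struct$Psi,
                       control$fa_inner, control$psi_floor)
      struct$Lambda <- fit$Lambda
      struct$Psi <- fit$Psi
      struct$Sigma <- tcrossprod(fit$Lambda) + diag(fit$Psi, p)
    },
    diag = {
      struct$Psi <- pmax(diag(S_mat), control$psi_floor)
      struct$Sigma <- diag(struct$Psi, p)
    },
    iso = {
      struct$s2 <- max(mean(diag(S_mat)), control$var_floor)
      struct$Sigma <- diag(struct$s2, p)
    },
    us = {
      es <- eigen((S_mat + t(S_mat)) / 2, symmetric = TRUE)
      floorv <- max(mean(diag(S_mat)), 1e-8) * 1e-8
      vals <- pmax(es$values, floorv)
      struct$Sigma <- es$vectors %*% (vals * t(es$vectors))
    },
    stop("unknown structure type: ", struct$type)
  )
  struct
}

.structure_pars <- function(struct) {
  if (is.null(struct)) return(numeric(0))
  switch(struct$type,
    fa = c(struct$Lambda, struct$Psi),
    diag = struct$Psi,
    iso = struct$s2,
    us = struct$Sigma[lower.tri(struct$Sigma, diag = TRUE)]
  )
}

# Initialize the structure state from the covariance of subject x level cell
# means (pairwise-complete), falling back to a scaled identity.
.structure_init <- function(type, k, p, y, subject, level, control) {
  Mcell <- tapply(y, list(subject, level), mean)
  S0 <- NULL
  if (!is.null(dim(Mcell)) && nrow(Mcell) >= 3L) {
    S0 <- suppressWarnings(stats::cov(Mcell, use = "pairwise.complete.obs"))
    if (anyNA(S0)) S0[is.na(S0)] <- 0
  }
  base_var <- stats::var(y)
  if (!is.finite(base_var) || base_var <= 0) base_var <- 1
  if (is.null(S0)) S0 <- diag(0.5 * base_var, p)
  es <- eigen((S0 + t(S0)) / 2, symmetric = TRUE)
  vals <- pmax(es$values, 0.05 * base_var)
  S0 <- es$vectors %*% (vals * t(es$vectors))
  struct <- list(type = type, k = k)
  if (type == "fa") {
    kk <- max(k, 1L)
    L0 <- es$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(vals[seq_len(kk)]) * 0.9, kk)
    struct$Lambda <- L0
    struct$Psi <- pmax(diag(S0) - rowSums(L0^2), 0.1 * diag(S0))
    struct$Sigma <- tcrossprod(L0) + diag(struct$Psi, p)
  } else if (type == "diag") {
    struct$Psi <- pmax(diag(S0), control$psi_floor)
    struct$Sigma <- diag(struct$Psi, p)
  } else if (type == "iso") {
    struct$s2 <- max(mean(diag(S0)), control$var_floor)
    struct$Sigma <- diag(struct$s2, p)
  } else if (type == "us") {
    struct$Sigma <- S0
  }
  struct
}

# Core two-phase REML fit.  All factor arguments are factors of length n.
#
# y           numeric response
# fixed       factor of fixed-effect cells, or NULL for a global intercept
# iid         named list of factors, one iid random term each
# subject     subject factor of the structured term (or NULL for none)
# level       level factor of the structured term
# structure   list(type = "fa"|"diag"|"iso"|"us", k = integer)
# resid_group factor of residual-variance groups, or NULL (homogeneous)
# pev_block   name of one iid term whose full PEV block should be returned
# init        optional list(resid_var, iid_var, struct) of starting values
# optimizer   "em_qn" (EM warm start + L-BFGS polish, default) or "em"
.reml_fit <- function(y, fixed = NULL, iid = list(),
                      subject = NULL, level = NULL,
                      structure = list(type = "fa", k = 1L),
                      resid_group = NULL, pev_block = NULL,
                      init = NULL, control = list(),
                      optimizer = c("em_qn", "em")) {
  ctrl <- utils::modifyList(.metfa_default_control(), control)
  optimizer <- match.arg(optimizer)
  n <- length(y)
  stopifnot(n >= 2L, all(is.finite(y)))

  # ---- design bookkeeping -------------------------------------------------
  if (is.null(fixed)) {
    fixed <- factor(rep("(Intercept)", n))
  }
  fixed <- droplevels(as.factor(fixed))
  pf <- nlevels(fixed)
  iid <- lapply(iid, function(f) droplevels(as.factor(f)))
  q_iid <- vapply(iid, nlevels, integer(1))
  n_iid <- length(iid)

  has_struct <- !is.null(subject)
  if (has_struct) {
    subject <- as.factor(subject)
    level <- as.factor(level)
    m <- nlevels(subject)
    p <- nlevels(level)
    stopifnot(length(level) == n, length(subject) == n)
  } else {
    m <- 0L
    p <- 0L
  }

  if (is.null(resid_group)) {
    resid_group <- factor(rep("all", n))
  }
  resid_group <- droplevels(as.factor(resid_group))
  g_res <- nlevels(resid_group)
  ridx <- as.integer(resid_group)
  n_per_group <- tabulate(ridx, g_res)

  # top-block column layout: fixed cells, then each iid term
  offs <- c(0L, cumsum(c(pf, q_iid)))
  ptop <- pf + sum(q_iid)
  topidx <- matrix(0L, n, 1L + n_iid)
  topidx[, 1L] <- as.integer(fixed)
  if (n_iid > 0L) {
    for (t in seq_len(n_iid)) {
      topidx[, t + 1L] <- offs[t + 1L] + as.integer(iid[[t]])
    }
  }
  nt <- ncol(topidx)
  Tmat <- Matrix::sparseMatrix(
    i = rep(seq_len(n), nt), j = as.vector(topidx), x = 1,
    dims = c(n, ptop))
  iid_cols <- lapply(seq_len(n_iid),
                     function(t) (offs[t + 1L] + 1L):offs[t + 2L])

  if (has_struct) {
    li <- as.integer(level)
    si <- as.integer(subject)
    cidx <- (si - 1L) * p + li
    Zg <- Matrix::sparseMatrix(i = seq_len(n), j = cidx, x = 1,
                               dims = c(n, m * p))
    gencols <- lapply(seq_len(m), function(i) ((i - 1L) * p + 1L):(i * p))
    # static per-subject support: top columns sharing a record with subject i
    sup_list <- lapply(split(seq_len(n), factor(si, levels = seq_len(m))),
                       function(rr) sort(unique(as.vector(topidx[rr, ]))))
    rec_split <- split(seq_len(n), factor(si, levels = seq_len(m)))
  }

  # ---- E-step: everything needed for ll, M-steps, and gradients -----------
  estep <- function(resid_var, iid_var, struct) {
    w <- 1 / resid_var[ridx]
    Tw <- Tmat * sqrt(w)
    Ctt <- as.matrix(Matrix::crossprod(Tw))
    pen <- numeric(ptop)
    for (t in seq_len(n_iid)) pen[iid_cols[[t]]] <- 1 / iid_var[t]
    diag(Ctt) <- diag(Ctt) + pen
    r_top <- as.numeric(Matrix::crossprod(Tmat, w * y))
    ywy <- sum(w * y^2)

    if (has_struct) {
      Sig <- (struct$Sigma + t(struct$Sigma)) / 2
      Sig_inv <- solve(Sig)
      logdet_Sigma <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
      Ctr <- Matrix::crossprod(Tmat, (w * Zg))
      Crt <- Matrix::t(Ctr)
      d_cell <- numeric(m * p)
      dsum <- rowsum(w, cidx)
      d_cell[as.integer(rownames(dsum))] <- dsum
      r_gen <- numeric(m * p)
      rsum <- rowsum(w * y, cidx)
      r_gen[as.integer(rownames(rsum))] <- rsum

      Ainv_list <- vector("list", m)
      B_list <- vector("list", m)
      Csup_list <- vector("list", m)
      logdetA <- 0
      S_schur <- Ctt
      rhs_adj <- r_top
      for (i in seq_len(m)) {
        gi <- gencols[[i]]
        Ai <- Sig_inv
        diag(Ai) <- diag(Ai) + d_cell[gi]
        chA <- chol(Ai)
        logdetA <- logdetA + 2 * sum(log(diag(chA)))
        Ainv <- chol2inv(chA)
        Ainv_list[[i]] <- Ainv
        sup <- sup_list[[i]]
        if (length(sup)) {
          Cs <- as.matrix(Crt[gi, sup, drop = FALSE])
          Csup_list[[i]] <- Cs
          Bi <- Ainv %*% Cs
          B_list[[i]] <- Bi
          S_schur[sup, sup] <- S_schur[sup, sup] - crossprod(Cs, Bi)
          rhs_adj[sup] <- rhs_adj[sup] -
            as.numeric(crossprod(Cs, Ainv %*% r_gen[gi]))
        }
      }
      chS <- chol(S_schur)
      logdetS <- 2 * sum(log(diag(chS)))
      Sinv <- chol2inv(chS)
      t_hat <- as.numeric(Sinv %*% rhs_adj)

      u_mat <- matrix(0, m, p)
      pev_arr <- array(0, c(p, p, m))
      S_mat <- matrix(0, p, p)
      uru <- 0
      for (i in seq_len(m)) {
        gi <- gencols[[i]]
        sup <- sup_list[[i]]
        if (length(sup)) {
          ui <- Ainv_list[[i]] %*%
            (r_gen[gi] - Csup_list[[i]] %*% t_hat[sup])
          pev <- Ainv_list[[i]] +
            B_list[[i]] %*% Sinv[sup, sup, drop = FALSE] %*% t(B_list[[i]])
        } else {
          ui <- Ainv_list[[i]] %*% r_gen[gi]
          pev <- Ainv_list[[i]]
        }
        ui <- as.numeric(ui)
        u_mat[i, ] <- ui
        pev_arr[, , i] <- pev
        S_mat <- S_mat + tcrossprod(ui) + pev
        uru <- uru + sum(ui * r_gen[gi])
      }
      S_mat <- S_mat / m

      yPy <- ywy - sum(t_hat * r_top) - uru
      logdetC <- logdetA + logdetS
      logdetG_struct <- m * logdet_Sigma
    } else {
      Sig_inv <- NULL
      chS <- chol(Ctt)
      logdetS <- 2 * sum(log(diag(chS)))
      Sinv <- chol2inv(chS)
      t_hat <- as.numeric(Sinv %*% r_top)
      yPy <- ywy - sum(t_hat * r_top)
      logdetC <- logdetS
      logdetG_struct <- 0
      u_mat <- NULL; pev_arr <- NULL; S_mat <- NULL
    }

    logdetR <- sum(n_per_group * log(resid_var))
    logdetG_iid <- if (n_iid) sum(q_iid * log(iid_var)) else 0
    ll <- -0.5 * (logdetR + logdetG_iid + logdetG_struct + logdetC +
                    yPy + (n - pf) * log(2 * pi))

    # conditional residuals and per-record variance corrections
    fit_top <- t_hat[topidx[, 1L]]
    if (n_iid > 0L) {
      for (t in seq_len(n_iid)) fit_top <- fit_top + t_hat[topidx[, t + 1L]]
    }
    ehat <- y - fit_top
    if (has_struct) ehat <- ehat - u_mat[cbind(si, li)]
    v_rec <- numeric(n)
    for (a in seq_len(nt)) {
      for (b in seq_len(nt)) {
        v_rec <- v_rec + Sinv[cbind(topidx[, a], topidx[, b])]
      }
    }
    if (has_struct) {
      v_rec <- v_rec + pev_arr[cbind(li, li, si)]
      for (i in seq_len(m)) {
        rr <- rec_split[[i]]
        if (!length(rr)) next
        sup <- sup_list[[i]]
        Mi <- B_list[[i]] %*% Sinv[sup, , drop = FALSE]
        for (a in seq_len(nt)) {
          v_rec[rr] <- v_rec[rr] - 2 * Mi[cbind(li[rr], topidx[rr, a])]
        }
      }
    }
    ssq_group <- as.numeric(rowsum(ehat^2 + v_rec, ridx))
    wsq_group <- as.numeric(rowsum((ehat^2 + v_rec) * w, ridx))
    SSb <- SSpev <- numeric(n_iid)
    for (t in seq_len(n_iid)) {
      J <- iid_cols[[t]]
      SSb[t] <- sum(t_hat[J]^2)
      SSpev[t] <- sum(diag(Sinv)[J])
    }

    list(ll = ll, t_hat = t_hat, Sinv = Sinv, Sig_inv = Sig_inv,
         u_mat = u_mat, pev_arr = pev_arr, S_mat = S_mat,
         ssq_group = ssq_group, wsq_group = wsq_group,
         SSb = SSb, SSpev = SSpev)
  }

  # ---- starting values ----------------------------------------------------
  vtot <- stats::var(y)
  if (!is.finite(vtot) || vtot <= 0) vtot <- 1
  resid_var <- if (!is.null(init$resid_var)) {
    rep_len(init$resid_var, g_res)
  } else {
    rv <- vapply(seq_len(g_res), function(g) {
      v <- stats::var(y[ridx == g])
      if (!is.finite(v) || v <= 0) 0.5 * vtot else 0.5 * v
    }, numeric(1))
    rv
  }
  resid_var <- pmax(resid_var, ctrl$var_floor)
  iid_var <- if (!is.null(init$iid_var)) {
    rep_len(init$iid_var, n_iid)
  } else {
    rep(0.1 * vtot, n_iid)
  }
  iid_var <- pmax(iid_var, ctrl$var_floor)
  struct <- NULL
  if (has_struct) {
    struct <- if (!is.null(init$struct)) {
      init$struct
    } else {
      .structure_init(structure$type, structure$k %||% 1L, p, y,
                      subject, level, ctrl)
    }
  }

  par_vec <- function() c(resid_var, iid_var, .structure_pars(struct))

  # ---- phase 1: monotone EM warm start ------------------------------------
  ll_trace <- numeric(0)
  ll_old <- -Inf
  par_old <- par_vec()
  converged <- FALSE
  iter_done <- 0L
  es <- NULL
  em_budget <- if (optimizer == "em") ctrl$max_iter else
    min(ctrl$em_iter, ctrl$max_iter)

  em_update <- function(es) {
    if (n_iid > 0L) {
      for (t in seq_len(n_iid)) {
        iid_var[t] <<- max((es$SSb[t] + es$SSpev[t]) / q_iid[t],
                           ctrl$var_floor)
      }
    }
    resid_var <<- pmax(es$ssq_group / n_per_group, ctrl$var_floor)
    if (has_struct) {
      struct <<- .structure_mstep(struct, es$S_mat, ctrl)
    }
  }

  for (iter in seq_len(em_budget)) {
    iter_done <- iter
    es <- estep(resid_var, iid_var, struct)
    ll_trace <- c(ll_trace, es$ll)
    if (ctrl$verbose) message(sprintf("EM %3d  REML ll = %.8f", iter, es$ll))
    par_new <- par_vec()
    if (iter > 1L) {
      dll <- es$ll - ll_old
      dpar <- max(abs(par_new - par_old) / (1 + abs(par_old)))
      if (abs(dll) < ctrl$rel_tol * (1 + abs(ll_old)) &&
          dpar < ctrl$par_tol) {
        converged <- TRUE
        break
      }
    }
    ll_old <- es$ll
    par_old <- par_new
    em_update(es)
  }

  # ---- phase 2: quasi-Newton polish with analytic gradients ---------------
  if (!converged && optimizer == "em_qn") {
    if (has_struct && struct$type == "fa") {
      struct$Lambda <- .lower_triangular_loadings(struct$Lambda)
      struct$Sigma <- tcrossprod(struct$Lambda) + diag(struct$Psi, p)
    }
    if (has_struct && struct$type == "us") {
      struct$chol <- t(chol(struct$Sigma + diag(1e-10 * mean(diag(struct$Sigma)), p)))
    }
    free_lam <- if (has_struct && struct$type == "fa" && struct$k >= 1) {
      which(row(struct$Lambda) >= col(struct$Lambda))
    } else integer(0)

    pack <- function() {
      th <- c(log(resid_var), log(iid_var))
      if (has_struct) {
        th <- c(th, switch(struct$type,
          fa = c(struct$Lambda[free_lam], log(struct$Psi)),
          diag = log(struct$Psi),
          iso = log(struct$s2),
          us = {
            L <- struct$chol
            c(log(diag(L)), L[lower.tri(L)])
          }))
      }
      th
    }
    unpack <- function(th) {
      rv <- exp(th[seq_len(g_res)])
      iv <- if (n_iid) exp(th[g_res + seq_len(n_iid)]) else numeric(0)
      st <- struct
      if (has_struct) {
        rest <- th[-seq_len(g_res + n_iid)]
        if (st$type == "fa") {
          L <- matrix(0, p, st$k)
          L[free_lam] <- rest[seq_along(free_lam)]
          st$Lambda <- L
          st$Psi <- exp(rest[length(free_lam) + seq_len(p)])
          st$Sigma <- tcrossprod(L) + diag(st$Psi, p)
        } else if (st$type == "diag") {
          st$Psi <- exp(rest)
          st$Sigma <- diag(st$Psi, p)
        } else if (st$type == "iso") {
          st$s2 <- exp(rest)
          st$Sigma <- diag(st$s2, p)
        } else if (st$type == "us") {
          L <- matrix(0, p, p)
          diag(L) <- exp(rest[seq_len(p)])
          L[lower.tri(L)] <- rest[-seq_len(p)]
          st$chol <- L
          st$Sigma <- tcrossprod(L)
        }
      }
      list(rv = rv, iv = iv, st = st)
    }
    grad_unc <- function(pp, es) {
      g <- -0.5 * (n_per_group - es$wsq_group)        # d ll / d log resid
      if (n_iid) {
        g <- c(g, -0.5 * (q_iid - (es$SSb + es$SSpev) / pp$iv))
      }
      if (has_struct) {
        K <- pp$st$Sig_inv_tmp %*% (es$S_mat - pp$st$Sigma) %*%
          pp$st$Sig_inv_tmp
        g <- c(g, switch(pp$st$type,
          fa = {
            GL <- m * (K %*% pp$st$Lambda)
            c(GL[free_lam], 0.5 * m * diag(K) * pp$st$Psi)
          },
          diag = 0.5 * m * diag(K) * pp$st$Psi,
          iso = 0.5 * m * sum(diag(K)) * pp$st$s2,
          us = {
            GL <- m * (K %*% pp$st$chol)
            c(diag(GL) * diag(pp$st$chol), GL[lower.tri(GL)])
          }))
      }
      g
    }
    cache <- new.env(parent = emptyenv())
    eval_at <- function(th) {
      if (!is.null(cache$th) && identical(th, cache$th)) return(cache$res)
      pp <- unpack(th)
      es_ <- tryCatch(estep(pp$rv, pp$iv, pp$st), error = function(e) NULL)
      cache$th <- th
      cache$res <- list(pp = pp, es = es_)
      cache$res
    }
    negll <- function(th) {
      r <- eval_at(th)
      if (is.null(r$es) || !is.finite(r$es$ll)) return(1e10)
      -r$es$ll
    }
    neggr <- function(th) {
      r <- eval_at(th)
      if (is.null(r$es)) return(rep(0, length(th)))
      pp <- r$pp
      pp$st$Sig_inv_tmp <- r$es$Sig_inv
      -grad_unc(pp, r$es)
    }
    th0 <- pack()
    # box constraints mirror the EM floors so the two phases share one
    # feasible region
    lower <- rep(log(ctrl$var_floor), g_res + n_iid)
    if (has_struct) {
      lower <- c(lower, switch(struct$type,
        fa = c(rep(-Inf, length(free_lam)), rep(log(ctrl$psi_floor), p)),
        diag = rep(log(ctrl$psi_floor), p),
        iso = log(ctrl$var_floor),
        us = c(rep(0.5 * log(ctrl$var_floor), p),
               rep(-Inf, p * (p - 1) / 2))))
    }
    opt <- tryCatch(
      stats::optim(th0, negll, neggr, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = ctrl$qn_maxit, factr = 1e7,
                                  pgtol = 1e-4)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value >= ll_old) {
      pp <- unpack(opt$par)
      resid_var <- pp$rv
      if (n_iid) iid_var <- pp$iv
      struct <- pp$st
      iter_done <- iter_done + opt$counts[1]
      # L-BFGS met its function-change / projected-gradient tolerances
      if (opt$convergence == 0) converged <- TRUE
    }
    es <- estep(resid_var, iid_var, struct)
    ll_trace <- c(ll_trace, es$ll)
    # convergence assessment: one trial EM step from the polished point;
    # the fit has converged when it moves neither the likelihood nor the
    # parameters beyond the tolerances
    keep <- list(rv = resid_var, iv = iid_var, st = struct)
    ll_here <- es$ll
    par_here <- par_vec()
    em_update(es)
    es2 <- estep(resid_var, iid_var, struct)
    dll <- es2$ll - ll_here
    dpar <- max(abs(par_vec() - par_here) / (1 + abs(par_here)))
    if (abs(dll) < ctrl$rel_tol * (1 + abs(ll_here)) && dpar < ctrl$par_tol) {
      converged <- TRUE
    }
    if (es2$ll >= ll_here) {
      es <- es2
      ll_trace <- c(ll_trace, es2$ll)
      iter_done <- iter_done + 1L
    } else {
      resid_var <- keep$rv
      iid_var <- keep$iv
      struct <- keep$st
    }
  }
  if (is.null(es)) es <- estep(resid_var, iid_var, struct)

  # ---- assemble output ----------------------------------------------------
  ll <- es$ll
  t_hat <- es$t_hat
  out <- list(
    fixed_effects = stats::setNames(t_hat[seq_len(pf)], levels(fixed)),
    iid_var = stats::setNames(iid_var, names(iid)),
    resid_var = stats::setNames(resid_var, levels(resid_group)),
    loglik = ll, loglik_trace = ll_trace,
    converged = converged, iterations = iter_done,
    n = n, n_fixed = pf
  )
  if (has_struct) {
    u_mat <- es$u_mat
    pev_arr <- es$pev_arr
    rownames(u_mat) <- levels(subject)
    colnames(u_mat) <- levels(level)
    dimnames(pev_arr) <- list(levels(level), levels(level), levels(subject))
    out$subjects <- levels(subject)
    out$levels <- levels(level)
    out$Sigma <- struct$Sigma
    out$struct <- struct
    if (struct$type == "fa") {
      out$Lambda <- .lower_triangular_loadings(struct$Lambda)
      out$Psi <- struct$Psi
    }
    out$u <- u_mat
    out$u_pev <- pev_arr
  }
  if (!is.null(pev_block)) {
    t <- match(pev_block, names(iid))
    if (is.na(t)) stop("pev_block must name an iid term")
    J <- iid_cols[[t]]
    blk <- es$Sinv[J, J, drop = FALSE]
    dimnames(blk) <- list(levels(iid[[t]]), levels(iid[[t]]))
    out$pev_iid_block <- blk
    out$iid_blup <- stats::setNames(t_hat[J], levels(iid[[t]]))
  }
  if (n_iid > 0L) {
    out$iid_effects <- lapply(seq_len(n_iid), function(t) {
      stats::setNames(t_hat[iid_cols[[t]]], levels(iid[[t]]))
    })
    names(out$iid_effects) <- names(iid)
  }
  # internal auxiliaries (gradient ingredients) for diagnostics and tests
  out$.aux <- list(S_mat = es$S_mat, wsq_group = es$wsq_group,
                   SSb = es$SSb, SSpev = es$SSpev, Sig_inv = es$Sig_inv,
                   n_per_group = n_per_group, q_iid = q_iid, m = m)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
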