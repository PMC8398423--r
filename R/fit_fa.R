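#' Fit a factor-analytic mixed model to a multi-environment trial
#'
#' Fits, by REML, the linear mixed model
#' \deqn{y = X\tau + Z_g u_g + Z_\eta u_\eta + e}
#' where \eqn{\tau} holds fixed environment means, \eqn{u_g} the
#' genotype-within-environment effects with factor-analytic covariance
#' \eqn{\Sigma \otimes I_m}, \eqn{\Sigma = \Lambda\Lambda' + \Psi}
#' (\eqn{\Lambda} a `p x k` loading matrix with the upper triangle of its
#' leading block fixed at zero for identifiability, \eqn{\Psi} diagonal
#' specific variances), \eqn{u_\eta} replicate- and block-within-environment
#' design effects with diagonal covariance, and \eqn{e} residuals with one
#' variance per environment.  `k = 0` reduces \eqn{\Sigma} to
#' `diag(\eqn{\Psi})`.
#'
#' Estimation is a monotone EM-REML algorithm on the mixed-model equations
#' (see the package vignette); the fit is flagged converged only when both
#' the relative log-likelihood change and the max-norm parameter change drop
#' below their tolerances.
#'
#' @param dataset a screened [met_dataset()] (see [screen_environments()]).
#' @param trait trait to analyse.
#' @param k factor-analytic order, 0 to 3 (and `< p`).
#' @param use_blocks include the incomplete-block term when block codes are
#'   present.
#' @param control optional list overriding EM controls (`max_iter`,
#'   `rel_tol`, `par_tol`, `psi_floor`, `var_floor`, `fa_inner`).
#' @param init optional starting values (`resid_var`, `iid_var`, `struct`).
#' @return An object of class `fa_fit` with elements `loadings`,
#'   `specific_var`, `resid_var`, `design_var`, `Sigma`, `reml_loglik`,
#'   `loglik_trace`, `converged`, `iterations`, `env_means`, `blups`
#'   (`m x p` predicted genotype-by-environment effects, shrunken
#'   predictions for cells a genotype was never tested in), `scores`
#'   (`m x k` predicted factor scores), `lack_of_fit` (`m x p` predicted
#'   lack-of-fit effects), and `genotype_means` (trait-scale genotype
#'   predictions).
#' @seealso [percent_vaf()], [predict_blups()], [rotate()]
#' @export
fit_fa <- function(dataset, trait, k = 2L, use_blocks = TRUE,
                   control = list(), init = NULL) {
  stopifnot(inherits(dataset, "met_dataset"))
  rec <- dataset$records
  rec <- rec[rec$trait == trait & !is.na(rec$value), , drop = FALSE]
  if (!nrow(rec)) stop("no records for trait '", trait, "'")
  env <- factor(rec$environment)
  geno <- factor(rec$genotype)
  p <- nlevels(env)
  m <- nlevels(geno)
  k <- as.integer(k)
  if (p < 2L) stop("need at least 2 environments for a combined fit")
  if (k >= p) stop("FA order k must be smaller than the number of environments")
  if (k < 0L || k > 3L) stop("FA order k must be between 0 and 3")
  n_per_env <- tapply(rec$genotype, env, function(g) length(unique(g)))
  if (any(n_per_env < 2L)) {
    stop("every environment must contain at least 2 genotypes")
  }

  iid <- list(replicate = interaction(env, rec$replicate, drop = TRUE))
  if (use_blocks && any(!is.na(rec$block))) {
    blk <- interaction(env, rec$replicate, rec$block, drop = TRUE)
    if (nlevels(blk) > nlevels(iid$replicate)) iid$block <- blk
  }

  structure_spec <- if (k == 0L) list(type = "diag") else list(type = "fa", k = k)
  fit <- .reml_fit(rec$value, fixed = env, iid = iid,
                   subject = geno, level = env,
                   structure = structure_spec, resid_group = env,
                   init = init, control = control)

  U <- fit$u
  if (k > 0L) {
    Lam <- fit$Lambda
    F_sc <- U %*% solve(fit$Sigma, Lam)      # E[f | y] = Lambda' Sigma^-1 u
    Delta <- U - F_sc %*% t(Lam)
  } else {
    Lam <- matrix(0, p, 0)
    F_sc <- matrix(0, m, 0)
    Delta <- U
  }
  rownames(F_sc) <- rownames(U)

  design_var <- fit$iid_var
  out <- structure(list(
    trait = trait, k = k, m = m, p = p,
    environments = levels(env), genotypes = levels(geno),
    loadings = Lam,
    specific_var = stats::setNames(if (k > 0L) fit$Psi else fit$struct$Psi,
                                   levels(env)),
    resid_var = fit$resid_var,
    design_var = design_var,
    Sigma = fit$Sigma,
    env_means = fit$fixed_effects,
    reml_loglik = fit$loglik,
    loglik_trace = fit$loglik_trace,
    converged = fit$converged,
    iterations = fit$iterations,
    blups = U,
    scores = F_sc,
    lack_of_fit = Delta,
    genotype_means = stats::setNames(
      mean(fit$fixed_effects) + rowMeans(U), rownames(U)),
    u_pev = fit$u_pev
  ), class = "fa_fit")
  out
}

#' @export
print.fa_fit <- function(x, ...) {
  vaf <- percent_vaf(x)
  cat(sprintf(
    "fa_fit: FA(%d) REML fit, trait '%s', %d genotypes x %d environments\n",
    x$k, x$trait, x$m, x$p))
  cat(sprintf("  REML log-likelihood %.4f (%s in %d iterations)\n",
              x$reml_loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  %%VAF overall %.1f%%%s\n", vaf$overall,
              if (x$k > 0)
                paste0(" (per factor: ",
                       paste(sprintf("%.1f", vaf$per_factor), collapse = ", "),
                       ")")
              else ""))
  invisible(x)
}

#' Percentage of genotype-by-environment variance explained by the factors
#'
#' Overall share: \eqn{100\,\mathrm{tr}(\Lambda\Lambda')/
#' \mathrm{tr}(\Lambda\Lambda' + \Psi)}.  Per-factor shares come from the
#' principal-component rotation of the loadings (singular values of
#' \eqn{\Lambda}), and sum exactly to the overall share.
#'
#' @param fit an [fa_fit()] object.
#' @return list with `overall` (percentage) and `per_factor` (length-`k`
#'   vector of percentages).
#' @export
percent_vaf <- function(fit) {
  stopifnot(inherits(fit, "fa_fit"))
  tot <- sum(fit$loadings^2) + sum(fit$specific_var)
  if (fit$k == 0L || tot <= 0) {
    return(list(overall = 0, per_factor = numeric(0)))
  }
  d2 <- svd(fit$loadings, nu = 0, nv = 0)$d^2
  list(overall = 100 * sum(fit$loadings^2) / tot,
       per_factor = 100 * d2 / tot)
}

#' Genotype-by-environment BLUPs and genotype means
#'
#' Returns the solutions of the mixed-model equations at the REML estimates:
#' the `m x p` matrix of predicted genotype-by-environment effects (complete,
#' with shrunken predictions for environment cells a genotype was never
#' tested in) and the trait-scale genotype means (grand environment mean plus
#' the genotype's mean predicted effect).
#'
#' @param fit an [fa_fit()] object.
#' @return list with `blups` (`m x p`) and `genotype_means` (named vector).
#' @export
predict_blups <- function(fit) {
  stopifnot(inherits(fit, "fa_fit"))
  list(blups = fit$blups, genotype_means = fit$genotype_means)
}

#' REML likelihood-ratio test
#'
#' Compares a full and a reduced (one variance component dropped) REML fit:
#' the statistic is twice the log-likelihood difference, clipped at zero, and
#' the p-value is computed from a chi-square with one degree of freedom.
#' Because the null value of a variance lies on the boundary of its
#' parameter space, the chi-square(1) reference is conservative; the
#' `mixture` option uses the 50:50 mixture of chi-square(0) and
#' chi-square(1) instead.
#'
#' @param loglik_full,loglik_reduced REML log-likelihoods of the nested fits
#'   (fitted to the same data with the same fixed effects).
#' @param mixture use the boundary mixture reference distribution.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
remlrt <- function(loglik_full, loglik_reduced, mixture = FALSE) {
  if (loglik_full < loglik_reduced - 1e-4) {
    warning("full model log-likelihood is below the reduced model's; ",
            "check convergence")
  }
  stat <- max(0, 2 * (loglik_full - loglik_reduced))
  p <- if (mixture) {
    0.5 * (stat <= 0) + 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = min(p, 1), df = 1)
}
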