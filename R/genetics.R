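#' Cullis heritability for unbalanced trials
#'
#' Generalized heritability on a BLUP basis,
#' \deqn{H^2 = 1 - \bar v_\Delta / (2\,\hat\sigma^2_g),}
#' where \eqn{\bar v_\Delta} is the mean prediction-error variance of a
#' difference between two genotype BLUPs, taken over all genotype pairs from
#' the mixed-model equations.  Unlike the classical ratio
#' \eqn{\sigma^2_g/(\sigma^2_g + \sigma^2_e/r)} it remains valid when the
#' trial is unbalanced (genotype turnover, unequal replication, missing
#' environments); in a perfectly balanced design the two coincide.
#'
#' The genotype variance and prediction-error variances come from the
#' compound all-random model of [fit_vc()] (genotype + environment +
#' genotype-by-environment + replicate, heterogeneous residuals).
#'
#' @param dataset a screened [met_dataset()], or a ready [fit_vc()] object.
#' @param trait trait name (ignored when `dataset` is already a `vc_fit`).
#' @param use_blocks,control passed to [fit_vc()].
#' @return list with `trait`, `h2` (in `[0, 1]`), `mean_pev_diff`,
#'   `sigma2_g`.
#' @export
cullis_h2 <- function(dataset, trait = NULL, use_blocks = FALSE,
                      control = list()) {
  fit <- if (inherits(dataset, "vc_fit")) {
    dataset
  } else {
    stopifnot(inherits(dataset, "met_dataset"))
    fit_vc(dataset, trait, use_blocks = use_blocks, control = control)
  }
  P <- fit$hybrid_pev
  if (is.null(P)) stop("fit lacks the hybrid prediction-error block")
  m <- nrow(P)
  if (m < 2L) stop("need at least 2 genotypes")
  a <- diag(P)
  # mean over pairs i<j of PEV(u_i - u_j) = a_i + a_j - 2 P_ij
  vbar <- (m * sum(a) - sum(P)) / (m * (m - 1) / 2)
  s2g <- fit$sigma2_hybrid
  h2 <- if (!is.finite(s2g) || s2g <= 1e-9 * max(mean(a), 1e-300)) {
    0
  } else {
    max(0, min(1, 1 - vbar / (2 * s2g)))
  }
  list(trait = fit$trait, h2 = h2, mean_pev_diff = vbar, sigma2_g = s2g)
}

#' Genetic correlation between two traits
#'
#' REML estimate of the genotypic correlation from a bivariate mixed model:
#' genotype main effects for the two traits with an unstructured 2x2
#' covariance, trait-by-environment cells as fixed means, and independent
#' residual variances per trait per environment.  The estimate is clipped to
#' `[-1, 1]`.  If the bivariate fit fails or does not converge, the function
#' falls back to the Pearson correlation of the per-trait genotype BLUPs
#' from two univariate [fit_vc()] models and flags it in the method tag.
#'
#' @param dataset a [met_dataset()] with both traits on overlapping
#'   genotypes.
#' @param traitA,traitB trait names.
#' @param control EM control overrides.
#' @return list with `traitA`, `traitB`, `r_g`, `method`
#'   (`"bivariate_reml"` or `"blup_correlation"`), and the genotype
#'   covariance matrix `Sigma_g` when available.
#' @export
genetic_correlation <- function(dataset, traitA, traitB, control = list()) {
  stopifnot(inherits(dataset, "met_dataset"))
  if (identical(traitA, traitB)) {
    return(list(traitA = traitA, traitB = traitB, r_g = 1,
                method = "identity", Sigma_g = NULL))
  }
  rec <- dataset$records
  rec <- rec[rec$trait %in% c(traitA, traitB) & !is.na(rec$value), ,
             drop = FALSE]
  gA <- unique(rec$genotype[rec$trait == traitA])
  gB <- unique(rec$genotype[rec$trait == traitB])
  common <- intersect(gA, gB)
  if (length(common) < 3L) stop("traits share fewer than 3 genotypes")
  rec <- rec[rec$genotype %in% common, , drop = FALSE]
  tr <- factor(rec$trait, levels = c(traitA, traitB))
  env <- factor(rec$environment)
  geno <- factor(rec$genotype)
  cells <- interaction(tr, env, drop = TRUE)

  biv <- tryCatch(
    .reml_fit(rec$value, fixed = cells, iid = list(),
              subject = geno, level = tr,
              structure = list(type = "us"), resid_group = cells,
              control = control),
    error = function(e) NULL)
  if (!is.null(biv)) {
    Sg <- biv$Sigma
    denom <- sqrt(Sg[1, 1] * Sg[2, 2])
    if (is.finite(denom) && denom > 0) {
      r <- Sg[1, 2] / denom
      if (abs(r) > 1) {
        warning("genetic correlation clipped to the [-1, 1] boundary")
        r <- sign(r)
      }
      return(list(traitA = traitA, traitB = traitB, r_g = r,
                  method = "bivariate_reml", Sigma_g = Sg))
    }
  }
  # fallback: correlation of per-trait hybrid BLUPs
  ds2 <- met_dataset(rec)
  bA <- fit_vc(ds2, traitA, control = control)$hybrid_blups
  bB <- fit_vc(ds2, traitB, control = control)$hybrid_blups
  shared <- intersect(names(bA), names(bB))
  r <- stats::cor(bA[shared], bB[shared])
  warning("bivariate REML unavailable; using BLUP correlation fallback")
  list(traitA = traitA, traitB = traitB, r_g = max(-1, min(1, r)),
       method = "blup_correlation", Sigma_g = NULL)
}

#' Pairwise genetic correlation matrix
#'
#' @param dataset a [met_dataset()].
#' @param traits trait names (default: all traits in the dataset).
#' @param control EM control overrides.
#' @return list with `r_g` (symmetric matrix, unit diagonal) and `method`
#'   (matrix of method tags).
#' @export
genetic_correlation_matrix <- function(dataset, traits = NULL,
                                       control = list()) {
  stopifnot(inherits(dataset, "met_dataset"))
  if (is.null(traits)) traits <- dataset$traits
  t_ <- length(traits)
  R <- diag(1, t_)
  M <- matrix("identity", t_, t_)
  dimnames(R) <- dimnames(M) <- list(traits, traits)
  if (t_ >= 2L) {
    for (i in seq_len(t_ - 1L)) {
      for (j in (i + 1L):t_) {
        g <- genetic_correlation(dataset, traits[i], traits[j],
                                 control = control)
        R[i, j] <- R[j, i] <- g$r_g
        M[i, j] <- M[j, i] <- g$method
      }
    }
  }
  list(r_g = R, method = M)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value; a thin,
#' validated wrapper used for the simple correlation analyses
#' (trait-vs-slope, slope-vs-slope).
#'
#' @param x,y numeric vectors of equal length (`n >= 3`), finite values.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
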