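#' Principal-component rotation of a factor-analytic fit
#'
#' REML loadings of an FA(k) model are only identified up to rotation.  For
#' interpretation they are rotated to the principal-component solution: with
#' \eqn{\Lambda = U D V'} (singular value decomposition), the rotated
#' loadings are \eqn{\Lambda^* = U D} and the scores are co-rotated as
#' \eqn{f^* = V' f}, so the latent regression \eqn{u_g = \Lambda f + \delta}
#' is preserved exactly while the rotated factors are orthogonal, ordered by
#' non-increasing explained variance, and the first factor carries the
#' largest share.  Each rotated loading column is sign-fixed so that its sum
#' over environments is positive, making a positive slope mean "responds
#' positively to better environments".  A genotype's rotated scores are its
#' latent regression slopes on the environment loadings — the stability
#' measure of the analysis.
#'
#' @param fit a converged [fit_fa()] result with `k >= 1`.
#' @return An object of class `stability_result`: `rotated_loadings`
#'   (`p x k`), `slopes` (`m x k` latent regression slopes),
#'   `percent_vaf` (per rotated factor), `responsiveness` (labels from
#'   [classify()] at the default threshold), `slope_threshold`.
#' @export
rotate <- function(fit) {
  stopifnot(inherits(fit, "fa_fit"))
  if (fit$k < 1L) stop("rotation needs a factor-analytic order k >= 1")
  if (!fit$converged) {
    warning("rotating a fit that did not meet the convergence tolerances")
  }
  sv <- svd(fit$loadings)
  L <- sv$u %*% diag(sv$d, fit$k)
  G <- fit$scores %*% sv$v
  s <- sign(colSums(L))
  s[s == 0] <- 1
  L <- sweep(L, 2L, s, `*`)
  G <- sweep(G, 2L, s, `*`)
  rownames(L) <- fit$environments
  rownames(G) <- fit$genotypes
  colnames(L) <- colnames(G) <- paste0("FA", seq_len(fit$k))
  tot <- sum(fit$loadings^2) + sum(fit$specific_var)
  out <- structure(list(
    trait = fit$trait, k = fit$k,
    rotated_loadings = L, slopes = G,
    percent_vaf = 100 * sv$d^2 / tot,
    slope_threshold = NULL, responsiveness = NULL
  ), class = "stability_result")
  out$slope_threshold <- 0.25 * apply(G, 2L, stats::sd)
  out$responsiveness <- classify(out)$responsiveness
  out
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "stability_result: trait '%s', %d factors, %d genotypes\n",
    x$trait, x$k, nrow(x$slopes)))
  cat(sprintf("  %%VAF per rotated factor: %s\n",
              paste(sprintf("%.1f", x$percent_vaf), collapse = ", ")))
  invisible(x)
}

#' Classify genotype responsiveness from latent regression slopes
#'
#' A genotype's slope for a factor is labelled `near-zero` when its absolute
#' value is below the threshold (minimal response to the environments loading
#' on that factor), otherwise `positive` or `negative` by sign.  The default
#' threshold is a quarter of the slope standard deviation within each factor.
#'
#' @param result a [rotate()] output.
#' @param threshold non-negative scalar, or vector (one per factor); `NULL`
#'   uses `0.25 * sd(slopes)` per factor.
#' @return `result` with updated `responsiveness` (an `m x k` character
#'   matrix) and `slope_threshold`.
#' @export
classify <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "stability_result"))
  if (is.null(threshold)) {
    threshold <- 0.25 * apply(result$slopes, 2L, stats::sd)
  }
  if (any(threshold < 0)) stop("threshold must be >= 0")
  threshold <- rep_len(threshold, result$k)
  lab <- result$slopes
  lab[] <- "near-zero"
  for (r in seq_len(result$k)) {
    s <- result$slopes[, r]
    lab[abs(s) >= threshold[r] & s > 0, r] <- "positive"
    lab[abs(s) >= threshold[r] & s < 0, r] <- "negative"
    if (threshold[r] == 0) {
      lab[s > 0, r] <- "positive"
      lab[s < 0, r] <- "negative"
      lab[s == 0, r] <- "near-zero"
    }
  }
  result$responsiveness <- lab
  result$slope_threshold <- threshold
  result
}

#' Correlate latent regression slopes with genotype-level values
#'
#' Pearson correlation (with two-sided p-value) of each factor's latent
#' regression slopes against a genotype-level vector — a trait mean, or the
#' matching factor's slopes of another trait's stability result — aligning
#' genotypes by name.
#'
#' @param result a [rotate()] output.
#' @param values named numeric vector (names = genotypes), or another
#'   `stability_result` whose factor-by-factor slopes are used.
#' @return data.frame with columns `factor`, `r`, `p_value`, `n`.
#' @export
slope_correlations <- function(result, values) {
  stopifnot(inherits(result, "stability_result"))
  G <- result$slopes
  if (inherits(values, "stability_result")) {
    H <- values$slopes
    common <- intersect(rownames(G), rownames(H))
    if (length(common) < 3L) stop("need at least 3 shared genotypes")
    kk <- min(ncol(G), ncol(H))
    rows <- lapply(seq_len(kk), function(r) {
      ct <- stats::cor.test(G[common, r], H[common, r])
      data.frame(factor = colnames(G)[r], r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(common))
    })
    return(do.call(rbind, rows))
  }
  v <- values
  if (is.null(names(v))) {
    if (length(v) != nrow(G)) stop("unnamed values must match genotype count")
    names(v) <- rownames(G)
  }
  common <- intersect(rownames(G), names(v))
  if (length(common) < 3L) stop("need at least 3 shared genotypes")
  rows <- lapply(seq_len(ncol(G)), function(r) {
    ct <- stats::cor.test(G[common, r], v[common])
    data.frame(factor = colnames(G)[r], r = unname(ct$estimate),
               p_value = ct$p.value, n = length(common))
  })
  do.call(rbind, rows)
}
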