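#' Principal-component scores of genotype BLUPs
#'
#' Standardizes the columns (PCA on the correlation matrix) and returns the
#' principal-component scores, ordered by non-increasing eigenvalue, with a
#' deterministic sign convention: within each component the loading of
#' largest magnitude is made positive.
#'
#' @param blup_matrix numeric `m x q` matrix (genotypes in rows, e.g. the
#'   five carotenoid BLUPs); `m > q`, no constant column.
#' @return `m x q` score matrix with attributes `eigenvalues` and
#'   `rotation`.
#' @export
pca_scores <- function(blup_matrix) {
  X <- as.matrix(blup_matrix)
  if (nrow(X) <= ncol(X)) stop("need more genotypes than variables")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  sc <- sweep(pc$x, 2L, flip, `*`)
  rownames(sc) <- rownames(X)
  attr(sc, "eigenvalues") <- pc$sdev^2
  attr(sc, "rotation") <- rot
  sc
}

#' Ward hierarchical clustering of genotypes
#'
#' Agglomerative clustering on Euclidean distances minimizing the Ward
#' increase in within-cluster sum of squares at each merge
#' (`hclust(method = "ward.D2")`), cut at `n_groups`.
#'
#' @param pc_scores numeric matrix of coordinates (genotypes in rows).
#' @param n_groups number of groups to cut the tree at (default 3).
#' @return Integer vector of group labels (named by genotype) with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
ward_groups <- function(pc_scores, n_groups = 3L) {
  X <- as.matrix(pc_scores)
  if (n_groups < 1L) stop("n_groups must be >= 1")
  if (n_groups > nrow(X)) stop("n_groups cannot exceed the number of genotypes")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_groups)
  names(labels) <- rownames(X)
  attr(labels, "tree") <- hc
  labels
}

#' Canonical discriminant analysis of genotype groups
#'
#' Linear discriminant functions maximizing the between-group to
#' within-group scatter ratio: the generalized eigen-problem
#' \eqn{B a = \rho W a} with between-group SSCP \eqn{B} and pooled
#' within-group SSCP \eqn{W}.  Raw coefficients are scaled so canonical
#' scores have unit pooled within-group variance.  Canonical correlations
#' are \eqn{\sqrt{\rho_l / (1 + \rho_l)}}; the variance share of each
#' function is its eigenvalue over the eigenvalue total.  Structure
#' correlations — the Pearson correlations of the original variables (e.g.
#' carotenoid BLUPs) with the canonical scores — identify the variables
#' driving each function.
#'
#' @param pc_scores numeric `m x q` matrix fed to the discriminant analysis
#'   (typically all principal-component scores).
#' @param labels group labels, length `m`, at least 2 groups of `>= 2`.
#' @param structure_vars optional `m x v` matrix of original variables for
#'   the structure-correlation table (defaults to `pc_scores`).
#' @return An object of class `group_assignment`: `labels`, `can_scores`
#'   (`m x (g-1)`), `raw_coefficients`, `canonical_correlations`,
#'   `variance_share` (sums to 1), `eigenvalues`,
#'   `structure_correlations`, `group_means`.
#' @export
canonical_discriminant <- function(pc_scores, labels,
                                   structure_vars = NULL) {
  X <- as.matrix(pc_scores)
  f <- factor(labels)
  if (length(f) != nrow(X)) stop("labels must match the rows of pc_scores")
  g <- nlevels(f)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(f) < 2L)) stop("every group needs at least 2 members")
  m <- nrow(X); q <- ncol(X)

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  gm <- rowsum(Xc, f) / as.vector(table(f))
  W <- matrix(0, q, q)
  for (lv in levels(f)) {
    Xi <- Xc[f == lv, , drop = FALSE]
    Xi <- sweep(Xi, 2L, colMeans(Xi))
    W <- W + crossprod(Xi)
  }
  # B = sum_k n_k (xbar_k - xbar)(xbar_k - xbar)'
  B <- crossprod(gm * sqrt(as.vector(table(f))))

  if (rcond(W) < 1e-12) {
    warning("within-group scatter near-singular; regularizing diagonal")
    W <- W + diag(1e-8 * sum(diag(W)) / q, q)
  }
  cW <- chol(W)
  Mid <- backsolve(cW, t(backsolve(cW, t(B), transpose = TRUE)),
                   transpose = TRUE)
  es <- eigen((Mid + t(Mid)) / 2, symmetric = TRUE)
  nf <- min(g - 1L, q)
  rho <- pmax(es$values[seq_len(nf)], 0)
  A <- backsolve(cW, es$vectors[, seq_len(nf), drop = FALSE])
  # scale: unit pooled within-group variance of scores
  sc <- sqrt(diag(t(A) %*% (W / (m - g)) %*% A))
  A <- sweep(A, 2L, sc, `/`)
  # deterministic sign: largest-magnitude raw coefficient positive
  flip <- vapply(seq_len(nf), function(j) {
    v <- A[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  A <- sweep(A, 2L, flip, `*`)
  scores <- Xc %*% A
  colnames(scores) <- colnames(A) <- paste0("CAN", seq_len(nf))
  rownames(A) <- colnames(X)
  rownames(scores) <- rownames(X)

  sv <- if (is.null(structure_vars)) X else as.matrix(structure_vars)
  struc <- stats::cor(sv, scores)

  share <- if (sum(rho) > 0) rho / sum(rho) else rep(NA_real_, nf)
  structure(list(
    labels = stats::setNames(as.integer(f), rownames(X)),
    can_scores = scores,
    raw_coefficients = A,
    eigenvalues = rho,
    canonical_correlations = sqrt(rho / (1 + rho)),
    variance_share = share,
    structure_correlations = struc,
    group_means = rowsum(X, f) / as.vector(table(f))
  ), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: %d genotypes in %d groups\n",
              length(x$labels), length(unique(x$labels))))
  cat("  variance share per canonical function:",
      paste(sprintf("%.1f%%", 100 * x$variance_share), collapse = ", "), "\n")
  cat("  canonical correlations:",
      paste(sprintf("%.2f", x$canonical_correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive statistics per genotype group
#'
#' Minimum, maximum, arithmetic mean and standard error of the mean of a
#' genotype-level variable within each group — the group summary tables of a
#' profiling analysis.  A single-member group reports `se = 0`.
#'
#' @param labels group labels (named by genotype, or aligned with
#'   `trait_values`).
#' @param trait_values numeric vector (aligned or named by genotype), or a
#'   matrix/data.frame summarized column by column.
#' @return data.frame with columns `group`, `variable`, `n`, `min`, `max`,
#'   `mean`, `se`.
#' @export
group_summary <- function(labels, trait_values) {
  if (is.null(dim(trait_values))) {
    trait_values <- matrix(trait_values,
                           dimnames = list(names(trait_values), "value"))
  }
  V <- as.matrix(trait_values)
  if (!is.null(names(labels)) && !is.null(rownames(V))) {
    common <- intersect(names(labels), rownames(V))
    if (!length(common)) stop("labels and trait_values share no genotypes")
    labels <- labels[common]
    V <- V[common, , drop = FALSE]
  }
  if (length(labels) != nrow(V)) stop("labels must align with trait_values")
  f <- factor(labels)
  if (any(table(f) < 1L)) stop("empty group")
  rows <- list()
  for (v in colnames(V)) {
    for (lv in levels(f)) {
      x <- V[f == lv, v]
      x <- x[is.finite(x)]
      n <- length(x)
      if (!n) stop("group ", lv, " has no finite values for ", v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = lv, variable = v, n = n,
        min = min(x), max = max(x), mean = mean(x),
        se = if (n > 1L) stats::sd(x) / sqrt(n) else 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
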