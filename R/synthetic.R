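#' Ground-truth parameters for a synthetic multi-environment trial
#'
#' Bundles every generating parameter of a factor-analytic multi-environment
#' trial (MET) simulation: the environment loadings and specific variances of
#' the genetic covariance \eqn{\Sigma = \Lambda\Lambda' + \Psi}, heterogeneous
#' residual variances, design-term variances, fixed environment means, and the
#' year-to-year genotype turnover plan that makes the trial unbalanced.  A
#' `met_truth` is the recoverable ground truth against which every downstream
#' estimator in the package can be checked.
#'
#' @param n_env number of environments (year-by-location cells), `p`.
#' @param n_geno number of genotypes, `m`.
#' @param loadings numeric `p x k` matrix of environment loadings
#'   \eqn{\Lambda}; `k = 0` is allowed via a `p x 0` matrix.
#' @param specific_var length-`p` vector of specific (lack-of-fit) variances
#'   \eqn{\Psi \ge 0}.
#' @param resid_var length-`p` vector of per-environment plot residual
#'   variances (all `> 0`).
#' @param rep_var variance of replicate-within-environment effects.
#' @param block_var variance of incomplete-block-within-replicate effects.
#' @param env_means length-`p` vector of fixed environment means.
#' @param env_year integer vector of length `p` assigning each environment to
#'   a trial year.
#' @param turnover named list, one entry per year, each a vector of genotype
#'   indices tested in that year.  Subsets must be non-empty and their union
#'   must cover all `m` genotypes.
#' @param reps replicates per environment.
#' @param block_size genotypes per incomplete block.
#' @param missing_rate probability that any individual plot is lost
#'   completely at random (default 0).
#' @param trait trait label attached to generated records.
#' @param seed root seed; all random draws derive deterministic substreams
#'   from it.
#'
#' @return An object of class `met_truth`.
#' @seealso [generate_met()], [default_fa_truth()]
#' @export
met_truth <- function(n_env, n_geno, loadings, specific_var, resid_var,
                      rep_var = 0, block_var = 0,
                      env_means = rep(0, n_env),
                      env_year = rep(1L, n_env),
                      turnover = list(`1` = seq_len(n_geno)),
                      reps = 2L, block_size = 6L,
                      missing_rate = 0, trait = "trait", seed = 1L) {
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != n_env) stop("loadings must have n_env rows")
  k <- ncol(loadings)
  specific_var <- rep_len(specific_var, n_env)
  resid_var <- rep_len(resid_var, n_env)
  if (any(specific_var < 0)) stop("specific_var must be >= 0")
  if (any(resid_var <= 0)) stop("resid_var must be > 0")
  if (rep_var < 0 || block_var < 0) stop("design variances must be >= 0")
  if (length(env_means) != n_env) stop("env_means must have length n_env")
  if (length(env_year) != n_env) stop("env_year must have length n_env")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  years <- sort(unique(env_year))
  if (!setequal(names(turnover), as.character(years))) {
    stop("turnover must have one entry per year in env_year")
  }
  if (any(!vapply(turnover, length, 1L))) {
    stop("turnover subsets must be non-empty")
  }
  covered <- sort(unique(as.integer(unlist(turnover))))
  if (!setequal(covered, seq_len(n_geno))) {
    stop("turnover subsets must jointly cover all ", n_geno, " genotypes")
  }
  Sigma <- tcrossprod(loadings) + diag(specific_var, n_env)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("implied genetic covariance Lambda Lambda' + Psi is not positive ",
         "semi-definite")
  }
  structure(list(
    n_env = as.integer(n_env), n_geno = as.integer(n_geno),
    n_factors = k, loadings = loadings,
    specific_var = specific_var, resid_var = resid_var,
    rep_var = rep_var, block_var = block_var,
    env_means = env_means, env_year = as.integer(env_year),
    turnover = turnover[as.character(years)],
    reps = as.integer(reps), block_size = as.integer(block_size),
    missing_rate = missing_rate, trait = trait, seed = as.integer(seed),
    Sigma = Sigma
  ), class = "met_truth")
}

#' @export
print.met_truth <- function(x, ...) {
  cat(sprintf(
    "met_truth: %d genotypes x %d environments, FA(%d), %d reps, seed %d\n",
    x$n_geno, x$n_env, x$n_factors, x$reps, x$seed))
  cat(sprintf("  trait '%s'; %d years; mean per-env genetic variance %.3f\n",
              x$trait, length(x$turnover), mean(diag(x$Sigma))))
  invisible(x)
}

#' Trial-scale default generating truth
#'
#' A deterministic `met_truth` mimicking the structure of a regional
#' biofortified-maize trial series: 23 environments over 4 years, 64
#' genotypes with year-to-year turnover (10 tested all 4 years, 9 for three,
#' 12 for two, 33 once), alpha-lattice-style incomplete blocks of 6 within 2
#' replicates, FA(2) genetic covariance with all-positive first-factor
#' loadings, mean per-environment genetic variance near 3.7 (the
#' provitamin-A scale in ug/g squared) and a factor-explained share near
#' 90%, and heterogeneous residual variances.
#'
#' @param n_env,n_geno,n_factors,reps trial dimensions.
#' @param genetic_var target mean per-environment genetic variance.
#' @param vaf target proportion of genetic variance carried by the factors.
#' @param seed root seed stored in the truth.
#' @param trait trait label.
#' @return A `met_truth`.
#' @export
default_fa_truth <- function(n_env = 23L, n_geno = 64L, n_factors = 2L,
                             reps = 2L, genetic_var = 3.7, vaf = 0.90,
                             seed = 1L, trait = "provitamin_a") {
  p <- n_env
  k <- n_factors
  j <- seq_len(p)
  # deterministic loading patterns: factor 1 all positive with mild spread,
  # later factors sign-mixed and mutually out of phase
  share1 <- if (k >= 2) 0.78 else 1
  base1 <- 0.8 + 0.4 * (j - 1) / max(p - 1, 1)
  L <- matrix(0, p, max(k, 1L))
  if (k >= 1) {
    c1 <- sqrt(vaf * genetic_var * share1 * p / sum(base1^2))
    L[, 1] <- c1 * base1
  }
  if (k >= 2) {
    for (r in 2:k) {
      pat <- cos(2 * pi * (r - 1) * (j - 0.5) / p)
      cr <- sqrt(vaf * genetic_var * (1 - share1) / (k - 1) * p / sum(pat^2))
      L[, r] <- cr * pat
    }
  }
  if (k == 0) L <- matrix(0, p, 0)
  psi <- 0.6 + 0.8 * (j %% 3) / 2
  psi <- psi / mean(psi) * (1 - vaf) * genetic_var
  resid <- genetic_var * (0.15 + 0.25 * ((j * 7) %% 5) / 4)
  n_years <- min(4L, p)
  qy <- p %/% n_years; ry <- p %% n_years
  env_year <- rep(seq_len(n_years),
                  times = c(rep(qy + 1L, ry), rep(qy, n_years - ry)))
  turnover <- .default_turnover(n_geno, n_years)
  met_truth(
    n_env = p, n_geno = n_geno, loadings = L, specific_var = psi,
    resid_var = resid, rep_var = 0.1 * genetic_var,
    block_var = 0.08 * genetic_var,
    env_means = 10 + 1.5 * sin(2 * pi * j / p),
    env_year = env_year, turnover = turnover,
    reps = reps, block_size = 6L, trait = trait, seed = seed
  )
}

# Turnover mirroring a 4-year regional trial series with 64 hybrids: 10
# tested in all 4 years, 9 in years 2-4, 12 in years 3-4, 33 in a single
# year (round-robin); counts scale proportionally for other m, and fewer
# years collapse the scheme.
.default_turnover <- function(m = 64L, n_years = 4L) {
  if (n_years < 2L || m < 8L) {
    return(stats::setNames(rep(list(seq_len(m)), n_years),
                           as.character(seq_len(n_years))))
  }
  n4 <- max(round(m * 10 / 64), 1L)
  n3 <- max(round(m * 9 / 64), 1L)
  n2 <- max(round(m * 12 / 64), 1L)
  n1 <- m - n4 - n3 - n2
  g4 <- seq_len(n4)
  g3 <- seq_len(n3) + n4
  g2 <- seq_len(n2) + n4 + n3
  g1 <- seq_len(n1) + n4 + n3 + n2
  yr1 <- split(g1, rep(seq_len(n_years), length.out = n1))
  start3 <- min(2L, n_years)
  start2 <- min(3L, n_years)
  out <- lapply(seq_len(n_years), function(y) {
    core <- g4
    if (y >= start3) core <- c(core, g3)
    if (y >= start2) core <- c(core, g2)
    sort(c(core, yr1[[as.character(y)]]))
  })
  stats::setNames(out, as.character(seq_len(n_years)))
}

# deterministic substream seed from a root seed (kept below 2^31)
.stream_seed <- function(root, stream, trait_index = 0L) {
  (as.numeric(root) + 1009 * stream + 95273 * trait_index) %% 2147483647
}

#' Generate a synthetic multi-environment trial dataset
#'
#' Simulates plot-level records under the generating model of a `met_truth`:
#' genotype-by-environment effects with covariance
#' \eqn{\Lambda\Lambda' + \Psi} across environments (independent across
#' genotypes), replicate and incomplete-block effects with the stated
#' variances, heterogeneous per-environment residuals, fixed environment
#' means, and the exact genotype turnover plan.  The same root seed always
#' reproduces the identical dataset; separate substreams are used per random
#' term so that, e.g., adding a trait does not perturb earlier draws.
#'
#' @param truth a [met_truth()].
#' @param trait_index internal stream offset used by [generate_multitrait()].
#' @param scores optional pre-drawn `m x k` factor scores (used to correlate
#'   traits); drawn internally when `NULL`.
#' @return A [met_dataset()] with an attribute `"realized"` carrying the
#'   realized factor scores, genetic effects, and the per-environment truth
#'   needed by parameter-recovery tests.
#' @export
generate_met <- function(truth, trait_index = 0L, scores = NULL) {
  stopifnot(inherits(truth, "met_truth"))
  p <- truth$n_env; m <- truth$n_geno; k <- truth$n_factors
  r <- truth$reps

  # genetic effects: U = F Lambda' + Delta
  if (is.null(scores)) {
    set.seed(.stream_seed(truth$seed, 1L, trait_index))
    scores <- matrix(stats::rnorm(m * max(k, 1L)), m)[, seq_len(k),
                                                      drop = FALSE]
  }
  set.seed(.stream_seed(truth$seed, 2L, trait_index))
  Delta <- matrix(stats::rnorm(m * p), m, p) %*%
    diag(sqrt(truth$specific_var), p)
  U <- Delta
  if (k > 0) U <- U + scores %*% t(truth$loadings)

  set.seed(.stream_seed(truth$seed, 3L, trait_index))
  rep_eff <- matrix(stats::rnorm(p * r, 0, sqrt(truth$rep_var)), p, r)

  env_names <- sprintf("%d::loc%02d", 2014L + truth$env_year, seq_len(p))
  geno_names <- sprintf("G%02d", seq_len(m))

  # assemble plot records env by env
  set.seed(.stream_seed(truth$seed, 4L, trait_index))
  recs <- vector("list", p * r)
  idx <- 0L
  for (j in seq_len(p)) {
    yr <- truth$env_year[j]
    gset <- truth$turnover[[as.character(yr)]]
    ng <- length(gset)
    n_blocks <- ceiling(ng / truth$block_size)
    for (rr in seq_len(r)) {
      ord <- sample.int(ng)                       # lattice-style re-blocking
      blk <- integer(ng)
      blk[ord] <- rep(seq_len(n_blocks), each = truth$block_size,
                      length.out = ng)
      blk_eff <- stats::rnorm(n_blocks, 0, sqrt(truth$block_var))
      e <- stats::rnorm(ng, 0, sqrt(truth$resid_var[j]))
      idx <- idx + 1L
      recs[[idx]] <- data.frame(
        year = 2014L + yr,
        location = sprintf("loc%02d", j),
        environment = env_names[j],
        replicate = rr,
        block = blk,
        genotype = geno_names[gset],
        trait = truth$trait,
        value = truth$env_means[j] + U[gset, j] + rep_eff[j, rr] +
          blk_eff[blk] + e,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, recs)

  if (truth$missing_rate > 0) {
    set.seed(.stream_seed(truth$seed, 5L, trait_index))
    keep <- stats::runif(nrow(records)) >= truth$missing_rate
    records <- records[keep, , drop = FALSE]
  }
  rownames(records) <- NULL

  ds <- met_dataset(records)
  attr(ds, "realized") <- list(
    scores = scores, effects = U,
    env_names = env_names, geno_names = geno_names,
    Sigma = truth$Sigma, loadings = truth$loadings,
    specific_var = truth$specific_var
  )
  ds
}

#' Multi-trait generating truth with cross-trait genetic correlations
#'
#' Combines one `met_truth` per trait with a target genetic correlation
#' matrix across traits.  Cross-trait correlation is induced on the factor
#' scores: corresponding factor columns of different traits are drawn jointly
#' with correlation `genetic_corr`, while specific, design, and residual
#' effects stay independent across traits, so each trait keeps exactly its
#' marginal `met_truth` structure.
#'
#' @param truths named list of [met_truth()] objects (one per trait; all must
#'   share dimensions, design, and turnover).
#' @param genetic_corr t x t symmetric positive semi-definite correlation
#'   matrix with unit diagonal.
#' @return An object of class `multitrait_truth`.
#' @export
multitrait_truth <- function(truths, genetic_corr) {
  t_ <- length(truths)
  stopifnot(t_ >= 1L)
  genetic_corr <- as.matrix(genetic_corr)
  if (!isTRUE(all.equal(genetic_corr, t(genetic_corr), tolerance = 1e-10))) {
    stop("genetic_corr must be symmetric")
  }
  if (max(abs(diag(genetic_corr) - 1)) > 1e-10) {
    stop("genetic_corr must have unit diagonal")
  }
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic_corr must be positive semi-definite")
  if (nrow(genetic_corr) != t_) stop("genetic_corr dimension mismatch")
  dims_ok <- vapply(truths, function(tr) {
    tr$n_env == truths[[1]]$n_env && tr$n_geno == truths[[1]]$n_geno &&
      tr$n_factors == truths[[1]]$n_factors && tr$reps == truths[[1]]$reps
  }, logical(1))
  if (!all(dims_ok)) stop("all per-trait truths must share dimensions")
  if (is.null(names(truths))) {
    names(truths) <- vapply(truths, `[[`, "", "trait")
  }
  structure(list(truths = truths, genetic_corr = genetic_corr),
            class = "multitrait_truth")
}

#' Generate a correlated multi-trait trial dataset
#'
#' @param mt a [multitrait_truth()].
#' @return A [met_dataset()] holding the records of all traits; the
#'   `"realized"` attribute is a per-trait list.
#' @seealso [multitrait_truth()], [generate_met()]
#' @export
generate_multitrait <- function(mt) {
  stopifnot(inherits(mt, "multitrait_truth"))
  truths <- mt$truths
  t_ <- length(truths)
  m <- truths[[1]]$n_geno
  k <- truths[[1]]$n_factors
  root <- truths[[1]]$seed
  Ck <- chol(mt$genetic_corr + diag(1e-12, t_))
  score_list <- vector("list", t_)
  if (k > 0) {
    set.seed(.stream_seed(root, 11L))
    for (cc in seq_len(k)) {
      Zc <- matrix(stats::rnorm(m * t_), m, t_) %*% Ck
      for (tt in seq_len(t_)) {
        if (cc == 1L) score_list[[tt]] <- matrix(0, m, k)
        score_list[[tt]][, cc] <- Zc[, tt]
      }
    }
  } else {
    score_list <- rep(list(matrix(0, m, 0)), t_)
  }
  parts <- vector("list", t_)
  realized <- vector("list", t_)
  for (tt in seq_len(t_)) {
    ds <- generate_met(truths[[tt]], trait_index = tt,
                       scores = score_list[[tt]])
    realized[[tt]] <- attr(ds, "realized")
    parts[[tt]] <- ds$records
  }
  names(realized) <- names(truths)
  out <- met_dataset(do.call(rbind, parts))
  attr(out, "realized") <- realized
  out
}
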