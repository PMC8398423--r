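#' Variance-component model for a multi-environment trial
#'
#' Fits, by REML, the all-random compound model used for the covariance
#' tables and heritability: replicate nested within environment, hybrid
#' (genotype main effect), environment, and the genotype-by-environment
#' interaction all random, with heterogeneous residual variances per
#' environment:
#' \deqn{y = \mu + u_{env} + u_{hyb} + u_{rep(env)} + u_{hyb \times env} + e.}
#'
#' @param dataset a screened [met_dataset()].
#' @param trait trait name.
#' @param use_blocks include the incomplete-block term (default `FALSE`; the
#'   combined covariance analysis uses replicate within environment as the
#'   design term).
#' @param control EM control overrides, see [fit_fa()].
#' @param drop optional name of one component to omit (`"hybrid"`,
#'   `"environment"`, `"interaction"`, `"replicate"`) — used by the drop-one
#'   REML likelihood-ratio tests.
#' @return An object of class `vc_fit` with the component variances
#'   (`sigma2_hybrid`, `sigma2_environment`, `sigma2_interaction`,
#'   `sigma2_replicate`), per-environment residual variances, the REML
#'   log-likelihood, the hybrid BLUPs, and the full prediction-error
#'   variance-covariance block of the hybrid effects (needed for Cullis
#'   heritability).
#' @seealso [remlrt_table()], [cullis_h2()]
#' @export
fit_vc <- function(dataset, trait, use_blocks = FALSE, control = list(),
                   drop = NULL) {
  stopifnot(inherits(dataset, "met_dataset"))
  rec <- dataset$records
  rec <- rec[rec$trait == trait & !is.na(rec$value), , drop = FALSE]
  if (!nrow(rec)) stop("no records for trait '", trait, "'")
  env <- factor(rec$environment)
  geno <- factor(rec$genotype)
  if (nlevels(env) < 2L) stop("need at least 2 environments")
  if (!is.null(drop)) {
    drop <- match.arg(drop, c("hybrid", "environment", "interaction",
                              "replicate"))
  }

  iid <- list(
    environment = env,
    hybrid = geno,
    replicate = interaction(env, rec$replicate, drop = TRUE)
  )
  if (use_blocks && any(!is.na(rec$block))) {
    blk <- interaction(env, rec$replicate, rec$block, drop = TRUE)
    if (nlevels(blk) > nlevels(iid$replicate)) iid$block <- blk
  }
  has_int <- TRUE
  if (!is.null(drop)) {
    if (drop == "interaction") has_int <- FALSE else iid[[drop]] <- NULL
  }

  want_pev <- "hybrid" %in% names(iid)
  fit <- .reml_fit(
    rec$value, fixed = NULL, iid = iid,
    subject = if (has_int) geno else NULL,
    level = if (has_int) env else NULL,
    structure = list(type = "iso"), resid_group = env,
    pev_block = if (want_pev) "hybrid" else NULL,
    control = control
  )

  getv <- function(nm) if (nm %in% names(fit$iid_var)) unname(fit$iid_var[nm]) else NA_real_
  structure(list(
    trait = trait,
    sigma2_hybrid = getv("hybrid"),
    sigma2_environment = getv("environment"),
    sigma2_interaction = if (has_int) fit$struct$s2 else NA_real_,
    sigma2_replicate = getv("replicate"),
    sigma2_block = getv("block"),
    resid_var = fit$resid_var,
    reml_loglik = fit$loglik,
    converged = fit$converged,
    iterations = fit$iterations,
    grand_mean = unname(fit$fixed_effects[1]),
    hybrid_blups = if (want_pev) fit$iid_blup else NULL,
    hybrid_pev = if (want_pev) fit$pev_iid_block else NULL,
    dropped = drop
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit: trait '%s' (REML ll %.4f, %s)\n", x$trait,
              x$reml_loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf(
    "  hybrid %.4g | environment %.4g | interaction %.4g | replicate %.4g\n",
    x$sigma2_hybrid, x$sigma2_environment, x$sigma2_interaction,
    x$sigma2_replicate))
  cat(sprintf("  residual variances: %.4g to %.4g over %d environments\n",
              min(x$resid_var), max(x$resid_var), length(x$resid_var)))
  invisible(x)
}

#' Drop-one REML likelihood-ratio tests for the variance components
#'
#' Fits the full compound model of [fit_vc()] and refits it with each of the
#' hybrid, environment, and interaction components dropped in turn; the
#' log-likelihood differences give the REMLRT statistics (chi-square with
#' one degree of freedom by default; see [remlrt()]).
#'
#' @inheritParams fit_vc
#' @param components which components to test.
#' @param mixture use the boundary 50:50 mixture reference.
#' @return list with the full `vc_fit` (element `fit`) and a data.frame
#'   `tests` (component, variance, statistic, p_value).
#' @export
remlrt_table <- function(dataset, trait,
                         components = c("hybrid", "environment",
                                        "interaction"),
                         use_blocks = FALSE, mixture = FALSE,
                         control = list()) {
  full <- fit_vc(dataset, trait, use_blocks = use_blocks, control = control)
  rows <- lapply(components, function(cmp) {
    red <- fit_vc(dataset, trait, use_blocks = use_blocks, control = control,
                  drop = cmp)
    tst <- remlrt(full$reml_loglik, red$reml_loglik, mixture = mixture)
    variance <- switch(cmp,
      hybrid = full$sigma2_hybrid,
      environment = full$sigma2_environment,
      interaction = full$sigma2_interaction,
      replicate = full$sigma2_replicate)
    data.frame(component = cmp, variance = variance,
               statistic = tst$statistic, p_value = tst$p_value)
  })
  list(fit = full, tests = do.call(rbind, rows))
}
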