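#' Per-environment variance components
#'
#' Fits the single-trial mixed model for one environment and trait with
#' genotype, replicate, and (when present) incomplete block as independent
#' random effects, by REML.  This is the first screening step of the
#' multi-environment analysis: environments whose genotype variance sits at
#' the boundary carry no genetic signal and are excluded from the combined
#' fit.
#'
#' @param dataset a [met_dataset()].
#' @param environment environment key (`year::location`).
#' @param trait trait name.
#' @param use_blocks model the incomplete-block term when a usable block
#'   column is present (default `TRUE`); partner sites that do not report
#'   lattice structure are handled by setting this to `FALSE` or by leaving
#'   `block` empty.
#' @return A list with elements `genotype`, `replicate`, `block`,
#'   `residual` (variance estimates, `NA` for terms not in the model),
#'   `n_genotypes`, `n_records`.
#' @export
fit_single_env <- function(dataset, environment, trait, use_blocks = TRUE) {
  stopifnot(inherits(dataset, "met_dataset"))
  rec <- dataset$records
  rec <- rec[rec$environment == environment & rec$trait == trait &
               !is.na(rec$value), , drop = FALSE]
  if (!nrow(rec)) stop("no records for environment '", environment, "'")
  ng <- length(unique(rec$genotype))
  if (ng < 2L) {
    stop("fewer than 2 genotypes with records in environment '",
         environment, "'")
  }
  out <- list(genotype = 0, replicate = NA_real_, block = NA_real_,
              residual = 0, n_genotypes = ng, n_records = nrow(rec))

  if (stats::var(rec$value) == 0) {
    # constant response: every component is zero, no model needed
    out$replicate <- 0
    if (use_blocks && any(!is.na(rec$block))) out$block <- 0
    return(out)
  }

  terms <- "(1 | genotype)"
  if (length(unique(rec$replicate)) >= 2L) {
    terms <- c(terms, "(1 | replicate)")
  }
  has_block <- use_blocks && any(!is.na(rec$block))
  if (has_block) {
    rec$.blk <- interaction(rec$replicate, rec$block, drop = TRUE)
    if (nlevels(rec$.blk) >= 2L) terms <- c(terms, "(1 | .blk)")
    else has_block <- FALSE
  }
  form <- stats::as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = rec, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else NA_real_
  }
  out$genotype <- getv("genotype")
  out$replicate <- if (length(unique(rec$replicate)) >= 2L) getv("replicate") else NA_real_
  out$block <- if (has_block) getv(".blk") else NA_real_
  out$residual <- getv("Residual")
  out
}

#' Screen out environments with zero genetic variance
#'
#' Estimates the genotype variance in every environment with
#' [fit_single_env()] and drops environments whose REML estimate sits at the
#' lower boundary.  "Zero" is operationalized as an estimate at or below
#' `floor_frac` times the phenotypic variance of that environment (a
#' scale-free boundary floor), so the screen is invariant to trait units.
#'
#' @param dataset a [met_dataset()].
#' @param trait trait name.
#' @param floor_frac relative boundary floor (default `1e-8`).
#' @param use_blocks passed to [fit_single_env()].
#' @return The dataset restricted to informative environments (records of
#'   other traits are restricted to the same environments).  The excluded
#'   environment keys are attached as attribute `"excluded"`, and the
#'   per-environment genotype variances as attribute `"env_genetic_var"`.
#' @export
screen_environments <- function(dataset, trait, floor_frac = 1e-8,
                                use_blocks = TRUE) {
  stopifnot(inherits(dataset, "met_dataset"))
  if (!trait %in% dataset$traits) stop("trait '", trait, "' not in dataset")
  rec <- dataset$records[dataset$records$trait == trait, , drop = FALSE]
  envs <- sort(unique(rec$environment))
  gvar <- vapply(envs, function(e) {
    fit_single_env(dataset, e, trait, use_blocks = use_blocks)$genotype
  }, numeric(1))
  pvar <- vapply(envs, function(e) {
    stats::var(rec$value[rec$environment == e], na.rm = TRUE)
  }, numeric(1))
  floorv <- floor_frac * pmax(pvar, .Machine$double.eps)
  keep <- gvar > floorv
  if (!any(keep)) stop("no informative environments: every environment has ",
                       "a zero genetic variance estimate")
  excluded <- envs[!keep]
  out <- if (length(excluded)) {
    subset_environments(dataset, setdiff(dataset$environments, excluded))
  } else {
    dataset
  }
  attr(out, "excluded") <- excluded
  attr(out, "env_genetic_var") <- stats::setNames(gvar, envs)
  out
}
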