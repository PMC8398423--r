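#' Run the full multi-environment-trial analysis pipeline
#'
#' Orchestrates the complete analysis from a single configuration:
#' data input (CSV path or synthetic generation), per-environment screening,
#' the variance-component model with drop-one REML likelihood-ratio tests,
#' the factor-analytic fit, principal-component rotation and latent
#' regression stability, Cullis heritability, genetic correlations among the
#' analysed traits, carotenoid metrics when the five carotenoid traits are
#' present, and PCA / Ward / canonical-discriminant profiling.  All stage
#' outputs are written to the output directory as CSV plus one
#' machine-readable `summary.json`; identical config and seed give identical
#' outputs.
#'
#' @param config either a named list or the path of a YAML file with keys:
#'   \describe{
#'     \item{input}{path of a MET CSV (omit when `synthetic` is given).}
#'     \item{synthetic}{list for [default_fa_truth()] (e.g. `n_env`,
#'       `n_geno`, `n_factors`, `reps`, `genetic_var`, `vaf`, `trait`), or
#'       `TRUE` for the defaults.}
#'     \item{traits}{traits to analyse (default: all in the data).}
#'     \item{k}{FA order per trait, or `"auto"` (smallest order up to 3
#'       whose factors explain at least `vaf_rule` percent).}
#'     \item{vaf_rule}{auto-order threshold, percent (default 85).}
#'     \item{n_groups}{profiling groups (default 3).}
#'     \item{slope_threshold}{near-zero slope threshold (default
#'       `0.25 * sd`).}
#'     \item{screen_floor}{screening floor fraction (default 1e-8).}
#'     \item{seed}{root seed (default 1).}
#'     \item{outdir}{output directory (default `tempdir()` subfolder).}
#'   }
#' @param overrides named list applied on top of the config (CLI-style).
#' @return (Invisibly) the summary list; side effect: files under `outdir`.
#' @export
run_pipeline <- function(config = list(), overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    input = NULL, synthetic = NULL, traits = NULL, k = "auto",
    vaf_rule = 85, n_groups = 3L, slope_threshold = NULL,
    screen_floor = 1e-8, seed = 1L,
    outdir = file.path(tempdir(), "metfa-pipeline")
  ), config)
  cfg <- utils::modifyList(cfg, overrides)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- input --------------------------------------------------------------
  dataset <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      args <- if (isTRUE(cfg$synthetic)) list() else cfg$synthetic
      args$seed <- cfg$seed
      truth <- do.call(default_fa_truth, args)
      logmsg("input", sprintf("synthetic trial: %d genotypes x %d environments",
                              truth$n_geno, truth$n_env))
      generate_met(truth)
    } else if (!is.null(cfg$input)) {
      logmsg("input", paste("reading", cfg$input))
      read_met_csv(cfg$input)
    } else {
      stop("config needs either 'input' or 'synthetic'")
    }
  })
  traits <- cfg$traits %||% dataset$traits
  missing_traits <- setdiff(traits, dataset$traits)
  if (length(missing_traits)) {
    stop("config names trait(s) absent from the data: ",
         paste(missing_traits, collapse = ", "))
  }

  summary <- list(config = cfg[c("traits", "k", "vaf_rule", "n_groups",
                                 "screen_floor", "seed")],
                  traits = list())
  summary$config$traits <- traits
  blup_store <- list()

  for (tr in traits) {
    tsum <- list()
    ds_t <- stage("screen", {
      s <- screen_environments(dataset, tr, floor_frac = cfg$screen_floor)
      logmsg("screen", sprintf("'%s': %d environments kept, %d excluded",
                               tr, length(s$environments),
                               length(attr(s, "excluded"))))
      s
    })
    tsum$excluded_environments <- as.character(attr(ds_t, "excluded"))

    vc <- stage("vc", remlrt_table(ds_t, tr))
    tsum$variance_components <- list(
      hybrid = vc$fit$sigma2_hybrid,
      environment = vc$fit$sigma2_environment,
      interaction = vc$fit$sigma2_interaction,
      replicate = vc$fit$sigma2_replicate)
    tsum$remlrt <- vc$tests
    logmsg("vc", sprintf("'%s': hybrid %.3g, env %.3g, interaction %.3g",
                         tr, vc$fit$sigma2_hybrid, vc$fit$sigma2_environment,
                         vc$fit$sigma2_interaction))

    h2 <- stage("heritability", cullis_h2(vc$fit))
    tsum$heritability <- h2$h2

    fa <- stage("fa", {
      if (identical(cfg$k, "auto")) {
        pick <- NULL
        for (kk in 1:3) {
          if (kk >= length(ds_t$environments)) break
          cand <- fit_fa(ds_t, tr, k = kk)
          pick <- cand
          if (percent_vaf(cand)$overall >= cfg$vaf_rule) break
        }
        pick
      } else {
        fit_fa(ds_t, tr, k = as.integer(cfg$k))
      }
    })
    vaf <- percent_vaf(fa)
    tsum$fa <- list(k = fa$k, converged = fa$converged,
                    reml_loglik = fa$reml_loglik,
                    percent_vaf = vaf$overall,
                    percent_vaf_per_factor = vaf$per_factor)
    logmsg("fa", sprintf("'%s': FA(%d), %%VAF %.1f", tr, fa$k, vaf$overall))

    st <- stage("stability", {
      s <- rotate(fa)
      if (!is.null(cfg$slope_threshold)) {
        s <- classify(s, cfg$slope_threshold)
      }
      s
    })
    slopes_df <- data.frame(
      genotype = rep(rownames(st$slopes), st$k),
      factor = rep(colnames(st$slopes), each = nrow(st$slopes)),
      slope = as.vector(st$slopes),
      label = as.vector(st$responsiveness))
    utils::write.csv(slopes_df,
                     file.path(cfg$outdir, paste0("slopes_", tr, ".csv")),
                     row.names = FALSE)
    tsum$stability <- list(
      slope_threshold = st$slope_threshold,
      n_positive_fa1 = sum(st$responsiveness[, 1] == "positive"),
      n_negative_fa1 = sum(st$responsiveness[, 1] == "negative"),
      n_nearzero_fa1 = sum(st$responsiveness[, 1] == "near-zero"))

    pb <- predict_blups(fa)
    blup_store[[tr]] <- pb$genotype_means
    blups_df <- data.frame(genotype = rownames(pb$blups),
                           genotype_mean = pb$genotype_means)
    utils::write.csv(cbind(blups_df, as.data.frame(pb$blups)),
                     file.path(cfg$outdir, paste0("blups_", tr, ".csv")),
                     row.names = FALSE)
    tsum$blup_range <- range(pb$genotype_means)
    summary$traits[[tr]] <- tsum
  }

  # ---- genetic correlations across traits ---------------------------------
  if (length(traits) >= 2L) {
    gc <- stage("correlations", genetic_correlation_matrix(dataset, traits))
    utils::write.csv(as.data.frame(gc$r_g),
                     file.path(cfg$outdir, "genetic_correlations.csv"))
    summary$genetic_correlations <- gc$r_g
    logmsg("correlations", sprintf("%d trait pairs", choose(length(traits), 2)))
  }

  # ---- carotenoid metrics + profiling -------------------------------------
  carot <- intersect(.carotenoid_names, names(blup_store))
  if (length(carot) == 5L) {
    prof <- stage("profiling", {
      genos <- Reduce(intersect, lapply(blup_store[carot], names))
      Bm <- sapply(carot, function(tr) blup_store[[tr]][genos])
      # predicted concentrations are truncated at zero for the derived
      # carotenoid arithmetic (a BLUP mean can dip below a trait's floor)
      metrics <- carotenoid_metrics(as.data.frame(pmax(Bm, 0)))
      utils::write.csv(cbind(genotype = genos, metrics),
                       file.path(cfg$outdir, "carotenoid_metrics.csv"),
                       row.names = FALSE)
      sc <- pca_scores(Bm)
      lab <- ward_groups(sc, cfg$n_groups)
      cda <- canonical_discriminant(sc, lab, structure_vars = Bm)
      gs <- group_summary(lab, as.matrix(metrics))
      utils::write.csv(gs, file.path(cfg$outdir, "group_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(genotype = genos, group = cda$labels,
                   cda$can_scores[, seq_len(min(2L, ncol(cda$can_scores))),
                                  drop = FALSE]),
        file.path(cfg$outdir, "groups.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(cda$structure_correlations),
                       file.path(cfg$outdir, "structure_correlations.csv"))
      list(cda = cda, summary = gs,
           proportions = proportions(pmax(Bm, 0)))
    })
    summary$profiling <- list(
      n_groups = cfg$n_groups,
      group_sizes = as.vector(table(prof$cda$labels)),
      variance_share = prof$cda$variance_share,
      canonical_correlations = prof$cda$canonical_correlations,
      mean_proportions = prof$proportions)
    logmsg("profiling", sprintf(
      "groups of %s; CAN shares %s",
      paste(table(prof$cda$labels), collapse = "/"),
      paste(sprintf("%.0f%%", 100 * prof$cda$variance_share), collapse = "/")))
  }

  summary$log <- log_lines
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(summary)
}
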