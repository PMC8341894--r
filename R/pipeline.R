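#' @title End-to-end analysis pipeline
#' @name pipeline
#' @description
#' One call from inputs (trees, tip regimes, trait table) to outputs
#' (map summaries, size-corrected traits, per-trait model-average tables,
#' PCA, and convergence tables), with deterministic stage seeding (child
#' seeds are the global seed plus a fixed stage offset) and a manifest of
#' input hashes and iteration counts.
NULL

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Assemble a pipeline configuration
#'
#' @param trees a `phylo` or list/`multiPhylo` of trees; the first is the
#'   primary (consensus) tree used for allometry, PCA, and convergence.
#' @param tip_states named character vector of foraging regimes.
#' @param traits data frame with `species`, a size column, and traits.
#' @param size_col,exclude size covariate column and trait columns never
#'   size-corrected (passed through on their observed scale).
#' @param mk_model Mk symmetry class for regime-history fitting.
#' @param n_draws stochastic maps drawn per tree.
#' @param models trait models to fit.
#' @param n_fit_maps number of maps (subsampled deterministically, evenly
#'   spaced) on which trait models are fit; `Inf` means all.
#' @param level confidence-set threshold for model averaging.
#' @param focal_regime regime whose tips are tested for convergence.
#' @param asr_models reconstruction models for the C metrics.
#' @param n_sim null simulations per convergence test.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(trees, tip_states, traits,
                            size_col = "standard_length",
                            exclude = "max_body_size",
                            mk_model = "ER", n_draws = 5,
                            models = c("BM1", "BMS", "OU1", "OUM", "OUMV"),
                            n_fit_maps = 10, level = 0.95,
                            focal_regime = "zp",
                            asr_models = c("bm", "mvou"),
                            n_sim = 100, seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, is.data.frame(traits),
            "species" %in% names(traits), level > 0, level <= 1)
  if (!focal_regime %in% tip_states)
    stop("focal regime '", focal_regime, "' absent from tip states")
  structure(list(trees = trees, tip_states = tip_states, traits = traits,
                 size_col = size_col, exclude = exclude,
                 mk_model = mk_model, n_draws = n_draws, models = models,
                 n_fit_maps = n_fit_maps, level = level,
                 focal_regime = focal_regime, asr_models = asr_models,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Summarize regime histories the way the results tables report them
#'
#' @param maps list of `simmap` paintings on one topology.
#' @return list extending [summarize_maps()] with `time_pct` (percent of
#'   total tree time per state) and `transition_pct` entries.
#' @export
summarize_history <- function(maps) {
  s <- summarize_maps(maps)
  s$time_pct <- 100 * s$time_fraction
  s
}

#' Run the full analysis pipeline
#'
#' Stages: prune trees to the trait table; fit the Mk regime model on the
#' primary tree; draw stochastic maps across all trees; summarize the
#' regime history; size-correct traits; fit every trait model on every
#' (subsampled) map and model-average per trait; phylogenetic PCA with
#' size regressions on the leading axes; convergence tests for the focal
#' regime. Any stage failure aborts with a stage-named error; results of
#' completed stages are preserved in the error condition's `partial`
#' field. Child seeds are `seed + stage offset`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return a `pipeline_result` list: `Q`, `maps` (count), `history`,
#'   `residuals`, `model_averages` (per trait), `fits`, `pca`,
#'   `score_regressions`, `convergence` (per ASR model), `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = paste0("stage '", name, "': ",
                                           conditionMessage(e)),
                          call = NULL, partial = res))))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("morphconv")),
    seed = cfg$seed,
    input_hashes = list(trees = .hash_obj(lapply(cfg$trees, write_newick)),
                        tip_states = .hash_obj(cfg$tip_states),
                        traits = .hash_obj(cfg$traits)))

  trees <- stage("prune", {
    lapply(cfg$trees, prune_to_species, species = cfg$traits$species)
  })
  primary <- trees[[1]]
  states <- cfg$tip_states[primary$tip.label]

  res$Q <- stage("fit_mk", {
    fit_mk(primary, states, model = cfg$mk_model)
  })

  maps <- stage("sample_maps", {
    out <- list()
    for (ti in seq_along(trees))
      out <- c(out, sample_maps(trees[[ti]], cfg$tip_states[trees[[ti]]$tip.label],
                                res$Q$Q, n_draws = cfg$n_draws,
                                seed = cfg$seed + 1000L + ti))
    out
  })
  res$n_maps <- length(maps)
  manifest$n_trees <- length(trees)
  manifest$n_draws <- cfg$n_draws
  manifest$n_maps <- length(maps)

  res$history <- stage("summarize_history", {
    # summaries require one topology; use the primary tree's maps
    summarize_history(maps[seq_len(cfg$n_draws)])
  })

  res$residuals <- stage("size_correct", {
    size_correct(primary, cfg$traits, cfg$size_col, cfg$exclude)
  })

  fit_maps <- stage("select_fit_maps", {
    idx <- if (is.finite(cfg$n_fit_maps) && cfg$n_fit_maps < length(maps))
      unique(round(seq(1, length(maps), length.out = cfg$n_fit_maps)))
    else seq_along(maps)
    primary_maps <- maps[idx][vapply(maps[idx], function(m)
      identical(m$tip.label, primary$tip.label), TRUE)]
    if (!length(primary_maps)) maps[seq_len(min(cfg$n_draws, length(maps)))]
    else primary_maps
  })

  res$fits <- stage("fit_models", {
    traits <- colnames(res$residuals)
    out <- list()
    for (tr in traits) {
      y <- res$residuals[, tr]
      out[[tr]] <- lapply(stats::setNames(cfg$models, cfg$models),
                          function(m)
                            lapply(fit_maps, function(pm)
                              tryCatch(fit_model(pm, y, m),
                                       error = function(e)
                                         list(retained = FALSE,
                                              error = conditionMessage(e)))))
    }
    out
  })
  manifest$n_fit_maps <- length(fit_maps)
  manifest$n_fits <- length(res$fits) * length(cfg$models) * length(fit_maps)

  res$model_averages <- stage("average_models", {
    lapply(res$fits, function(per_model)
      tryCatch(average_models(per_model, level = cfg$level),
               error = function(e) NULL))
  })

  res$pca <- stage("phylo_pca", {
    phylo_pca(primary, res$residuals)
  })
  res$score_regressions <- stage("score_regression", {
    size <- stats::setNames(cfg$traits[[cfg$size_col]], cfg$traits$species)
    score_regression(primary, res$pca$scores, size)
  })

  res$convergence <- stage("convergence", {
    focal <- names(states)[states == cfg$focal_regime]
    if (length(focal) < 2) stop("fewer than two focal tips after pruning")
    out <- list()
    for (am in cfg$asr_models)
      out[[am]] <- c_significance(primary, res$residuals, focal,
                                  asr_model = am, n_sim = cfg$n_sim,
                                  seed = cfg$seed + 7000L +
                                    match(am, cfg$asr_models))
    out
  })

  manifest$stage_count <- 9L
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs as TSV with a JSON mirror
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(d, f)
    utils::write.table(d, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  avg_tab <- do.call(rbind, lapply(names(res$model_averages), function(tr) {
    ma <- res$model_averages[[tr]]
    if (is.null(ma)) return(NULL)
    cbind(trait = tr, ma$table)
  }))
  if (!is.null(avg_tab)) wtsv(avg_tab, "model_averages.tsv")
  conv_tab <- do.call(rbind, lapply(names(res$convergence), function(am) {
    cv <- res$convergence[[am]]
    data.frame(asr = am, metric = names(cv$observed),
               cutoff = unname(cv$cutoff), observed = unname(cv$observed),
               p_value = unname(cv$p_value))
  }))
  if (!is.null(conv_tab)) wtsv(conv_tab, "convergence.tsv")
  hist_tab <- data.frame(state = names(res$history$time_fraction),
                         time_pct = unname(res$history$time_pct))
  wtsv(hist_tab, "history_time_in_state.tsv")
  wtsv(data.frame(res$score_regressions), "pca_score_regressions.tsv")
  jsonlite::write_json(
    list(manifest = res$manifest,
         history = list(mean_transitions = res$history$mean_transitions,
                        time_pct = as.list(res$history$time_pct)),
         pca_var_explained = res$pca$var_explained,
         convergence = lapply(res$convergence, function(cv)
           list(observed = as.list(cv$observed),
                cutoff = as.list(cv$cutoff),
                p_value = as.list(cv$p_value)))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
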