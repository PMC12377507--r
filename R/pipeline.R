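#' Configure an end-to-end UAIscore pipeline run
#'
#' Bundles every stage parameter: either paths to an expression TSV and a
#' clinical CSV, or a [trial_config()] simulation block (exactly one of the
#' two); the cohort-split ratio; the variance-filter keep fraction; the
#' screening significance levels; forest hyperparameters; evaluation times
#' and bootstrap replicates; and one global seed that fans out
#' deterministically into per-stage seeds.
#'
#' @param simulation Optional [trial_config()].
#' @param expression_path,clinical_path Optional input files (used when
#'   `simulation` is `NULL`).
#' @param split_ratio Training fraction.
#' @param keep_fraction MAD-filter keep fraction.
#' @param alpha Significance level for both screening stages.
#' @param n_trees,min_node_size Forest hyperparameters.
#' @param eval_times AUC evaluation times; default quartiles of follow-up.
#' @param n_bootstrap Bootstrap replicates for AUC CIs.
#' @param out_dir Optional output directory; when given, every stage artifact
#'   is written there.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            expression_path = NULL, clinical_path = NULL,
                            split_ratio = 0.65, keep_fraction = 0.5,
                            alpha = 0.05, n_trees = 1000, min_node_size = 15,
                            eval_times = NULL, n_bootstrap = 100,
                            out_dir = NULL, seed = 1L) {
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(expression_path) || !is.null(clinical_path)
  if (has_sim == has_paths) {
    abort("exactly one of `simulation` or input paths must be given")
  }
  if (has_paths && (is.null(expression_path) || is.null(clinical_path))) {
    abort("both expression_path and clinical_path are required")
  }
  if (has_sim) stopifnot(inherits(simulation, "trial_config"))
  structure(
    list(simulation = simulation, expression_path = expression_path,
         clinical_path = clinical_path, split_ratio = split_ratio,
         keep_fraction = keep_fraction, alpha = alpha, n_trees = n_trees,
         min_node_size = min_node_size, eval_times = eval_times,
         n_bootstrap = n_bootstrap, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full UAIscore pipeline
#'
#' Executes simulate/load -> MAD filter -> stratified cohort split ->
#' dual-endpoint survival screen -> treatment-interaction screen -> marker
#' selection -> forest training -> scoring -> four-group labelling ->
#' benefit analysis -> time-dependent AUC, and returns every stage output
#' together with a run manifest (stage record counts, seeds, timings, config
#' hash). With the same config and seed the run is bit-reproducible. Any
#' stage failure aborts with the stage name attached; the partial manifest is
#' attached to the error condition.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `uai_pipeline` with elements `manifest`,
#'   `expression`, `clinical`, `truth` (simulation only), `split`,
#'   `mad`, `survival_screen`, `interaction`, `markers`, `model`, `scores`,
#'   `four_groups`, `benefit`, `auc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = seed, stages = list(), counts = list(),
                   warnings = character())
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            manifest = manifest)
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- inputs ----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    trial <- t_stage("simulate",
                     simulate_trial(config$simulation, seed = stage_seed(seed, "simulate")))
    expr <- trial$expression; clinical <- trial$clinical; truth <- trial$truth
  } else {
    expr <- t_stage("read", read_expression(config$expression_path))
    clinical <- t_stage("read_clinical", {
      withCallingHandlers(read_clinical(config$clinical_path), warning = function(w) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    })
  }
  common <- intersect(colnames(expr), clinical$sample_id)
  expr <- expr[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), ]
  manifest$counts$n_samples <- length(common)
  manifest$counts$genes_input <- nrow(expr)

  # -- variance filter and split --------------------------------------------
  mf <- t_stage("mad_filter", mad_filter(expr, config$keep_fraction))
  manifest$counts$genes_after_mad <- nrow(mf$expression)

  strata <- paste(clinical$arm, clinical$dfs_event, sep = "_")
  split <- t_stage("split",
                   split_cohort(clinical$sample_id, config$split_ratio,
                                seed = stage_seed(seed, "split"), strata = strata))
  manifest$counts$n_training <- length(split$training_ids)
  manifest$counts$n_validation <- length(split$validation_ids)

  # -- screening cascade -----------------------------------------------------
  surv_screen <- t_stage("survival_screen",
                         dual_endpoint_screen(mf$expression, clinical,
                                              samples = split$training_ids,
                                              alpha = config$alpha))
  passed <- surv_screen$gene_id[surv_screen$passed]
  manifest$counts$genes_after_survival_screen <- length(passed)

  interaction <- t_stage("interaction_screen",
                         interaction_screen(mf$expression, clinical,
                                            gene_ids = passed,
                                            training_ids = split$training_ids,
                                            alpha = config$alpha))
  markers <- t_stage("select_markers", {
    withCallingHandlers(select_marker_genes(interaction), warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  })
  manifest$counts$n_markers <- nrow(markers)
  manifest$counts$n_markers_protective <- sum(markers$direction == "protective")
  manifest$counts$n_markers_risk <- sum(markers$direction == "risk")

  # -- model -----------------------------------------------------------------
  if (nrow(markers) == 0) {
    abort("pipeline stage 'train' refused: empty marker gene set", manifest = manifest)
  }
  model <- t_stage("train",
                   train_uaiscore(mf$expression, clinical, markers,
                                  training_ids = split$training_ids,
                                  n_trees = config$n_trees,
                                  min_node_size = config$min_node_size,
                                  seed = stage_seed(seed, "train")))
  scores <- t_stage("score", uai_score(model, mf$expression))
  groups <- t_stage("four_groups", four_group_labels(scores, clinical))
  manifest$counts$four_groups <- as.list(attr(groups, "counts"))

  # -- evaluation ------------------------------------------------------------
  benefit <- t_stage("benefit", {
    withCallingHandlers(benefit_analysis(scores, clinical, "dfs"),
                        warning = function(w) {
                          manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
                          invokeRestart("muffleWarning")
                        })
  })
  eval_times <- config$eval_times %||%
    unname(quantile(clinical$dfs_time[clinical$dfs_event == 1], c(0.25, 0.5, 0.75)))
  auc <- t_stage("auc", {
    d <- dplyr::left_join(scores, clinical, by = "sample_id")
    time_dependent_auc(d, -uaiscore, dfs_time, dfs_event,
                       eval_times = eval_times,
                       n_bootstrap = config$n_bootstrap,
                       marker = "UAIscore",
                       seed = stage_seed(seed, "bootstrap"))
  })

  result <- structure(
    list(manifest = manifest, expression = mf$expression, clinical = clinical,
         truth = truth, split = split, mad = mf,
         survival_screen = surv_screen, interaction = interaction,
         markers = markers, model = model, scores = scores,
         four_groups = groups, benefit = benefit, auc = auc),
    class = "uai_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(result$expression, file.path(dir, "expression_filtered.tsv"))
  write_clinical(result$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(as_tibble(result$split), file.path(dir, "cohort_split.csv"), progress = FALSE)
  readr::write_csv(result$survival_screen, file.path(dir, "survival_screen.csv"), progress = FALSE)
  readr::write_csv(result$interaction, file.path(dir, "interaction_screen.csv"), progress = FALSE)
  readr::write_csv(as_tibble(result$markers), file.path(dir, "marker_genes.csv"), progress = FALSE)
  readr::write_csv(as_tibble(result$scores), file.path(dir, "uaiscores.csv"), progress = FALSE)
  readr::write_csv(result$four_groups, file.path(dir, "four_groups.csv"), progress = FALSE)
  readr::write_csv(as_tibble(result$benefit), file.path(dir, "benefit_analysis.csv"), progress = FALSE)
  readr::write_csv(as_tibble(result$auc), file.path(dir, "auc_curve.csv"), progress = FALSE)
  manifest <- result$manifest
  manifest$counts$four_groups <- unlist(manifest$counts$four_groups)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.uai_pipeline <- function(x, ...) {
  cat("<uai_pipeline>\n")
  co <- x$manifest$counts
  cat(sprintf("  %d samples (%d train / %d validation)\n",
              co$n_samples, co$n_training, co$n_validation))
  cat(sprintf("  genes: %d -> %d (MAD) -> %d (survival screen) -> %d markers (%d protective / %d risk)\n",
              co$genes_input, co$genes_after_mad, co$genes_after_survival_screen,
              co$n_markers, co$n_markers_protective, co$n_markers_risk))
  cat("  four groups:", paste(names(co$four_groups),
                              unlist(co$four_groups), collapse = ", ", sep = "="), "\n")
  invisible(x)
}
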