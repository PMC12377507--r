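#' Train the UAIscore random survival forest
#'
#' Fits a random survival forest of disease-free survival on marker-gene
#' expression using the immunotherapy-arm training patients, then defines the
#' UAIscore of a sample as the forest-predicted survival probability at a
#' landmark time — so a *higher* score means a *better* predicted outcome
#' under treatment. The stratification cutoff is the median UAIscore over all
#' training patients (both arms) and is frozen into the model: scoring new
#' data never recomputes it.
#'
#' Training uses the IO arm only because the score targets outcome *under
#' immunotherapy*; the median cutoff uses the whole training cohort so that
#' high/low strata are balanced in the population being stratified. Both
#' choices are configurable via `train_arm` and `cutoff_ids`.
#'
#' @param expr Genes x samples expression matrix containing all marker genes.
#' @param clinical Clinical tibble with `sample_id`, `arm`, `dfs_time`,
#'   `dfs_event`.
#' @param markers A [select_marker_genes()] result, or a character vector of
#'   gene identifiers.
#' @param training_ids Training-cohort sample identifiers.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features tried per split; default `floor(sqrt(n_markers))`.
#' @param min_node_size Minimum terminal node size (default 15).
#' @param landmark_time Time at which predicted survival is read off; default
#'   is the median observed DFS follow-up among training patients. A landmark
#'   beyond the last observed training event time is clipped with a warning.
#' @param train_arm Arm whose patients train the forest (default `"IO"`).
#' @param cutoff_ids Samples over which the median cutoff is taken (default:
#'   all of `training_ids`).
#' @param seed Integer seed (forest growth is single-threaded and
#'   seed-deterministic).
#' @return An object of class `uaiscore_model`.
#' @export
train_uaiscore <- function(expr, clinical, markers, training_ids,
                           n_trees = 1000, mtry = NULL, min_node_size = 15,
                           landmark_time = NULL, train_arm = "IO",
                           cutoff_ids = NULL, seed = 1L) {
  assert_expression_matrix(expr)
  assert_clinical(clinical)
  marker_ids <- if (is.data.frame(markers)) as.character(markers$gene_id) else as.character(markers)
  if (length(marker_ids) == 0) abort("cannot train a UAIscore model on an empty marker set")
  missing_genes <- setdiff(marker_ids, rownames(expr))
  if (length(missing_genes)) {
    abort(paste0("expression matrix lacks marker gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (!all(training_ids %in% colnames(expr)) ||
      !all(training_ids %in% clinical$sample_id)) {
    abort("training_ids must be present in both expression and clinical data")
  }
  cl <- clinical[match(training_ids, clinical$sample_id), ]
  fit_ids <- training_ids[cl$arm == train_arm]
  fit_cl <- cl[cl$arm == train_arm, ]
  if (sum(fit_cl$dfs_event) < 10) {
    abort(paste0("need at least 10 DFS events in the ", train_arm,
                 "-arm training patients"))
  }

  landmark_time <- landmark_time %||% median(cl$dfs_time)
  max_obs <- max(fit_cl$dfs_time)
  if (landmark_time > max_obs) {
    warn(sprintf("landmark_time %.3g beyond last observed training time; clipped to %.3g",
                 landmark_time, max_obs))
    landmark_time <- max_obs
  }

  train_df <- as.data.frame(t(expr[marker_ids, fit_ids, drop = FALSE]))
  safe_names <- paste0("g", seq_along(marker_ids))
  names(train_df) <- safe_names
  train_df$.time <- fit_cl$dfs_time
  train_df$.event <- fit_cl$dfs_event

  mtry <- mtry %||% max(1L, floor(sqrt(length(marker_ids))))
  forest <- ranger::ranger(
    survival::Surv(.time, .event) ~ ., data = train_df,
    num.trees = n_trees, mtry = mtry, min.node.size = min_node_size,
    seed = as.integer(seed), num.threads = 1, oob.error = TRUE
  )

  model <- structure(
    list(forest = forest, marker_genes = marker_ids,
         feature_names = safe_names,
         markers = if (is.data.frame(markers)) markers else NULL,
         landmark_time = landmark_time,
         training_cutoff = NA_real_, orientation = "higher_score_lower_hazard",
         train_arm = train_arm, training_ids = training_ids,
         fit_ids = fit_ids, endpoint = "dfs", seed = as.integer(seed),
         oob_error = forest$prediction.error),
    class = "uaiscore_model"
  )
  cutoff_ids <- cutoff_ids %||% training_ids
  model$training_cutoff <- median(uaiscore_values(model, expr, cutoff_ids))
  model
}

# Predicted survival probability at the landmark time for given samples.
uaiscore_values <- function(model, expr, sample_ids) {
  newdata <- as.data.frame(t(expr[model$marker_genes, sample_ids, drop = FALSE]))
  names(newdata) <- model$feature_names
  pr <- predict(model$forest, data = newdata, num.threads = 1)
  times <- pr$unique.death.times
  # step-function survival: value at the last death time <= landmark
  idx <- findInterval(model$landmark_time, times)
  s <- if (idx == 0) rep(1, nrow(newdata)) else pr$survival[, idx]
  setNames(as.numeric(s), sample_ids)
}

#' Score samples with a trained UAIscore model
#'
#' Computes the continuous UAIscore (predicted survival probability at the
#' model's landmark time) for every sample of an expression matrix and
#' assigns the high/low group using the frozen training-median cutoff.
#' Scoring is pure: it never modifies the model or recomputes the cutoff.
#'
#' @param model A [train_uaiscore()] fit.
#' @param expr Genes x samples expression matrix containing every marker gene.
#' @param samples Optional subset of samples to score.
#' @return A tibble of class `uai_score_table`: `sample_id`, `uaiscore`,
#'   `group` (`"high"` iff `uaiscore > training_cutoff`).
#' @export
uai_score <- function(model, expr, samples = NULL) {
  stopifnot(inherits(model, "uaiscore_model"))
  assert_expression_matrix(expr)
  missing_genes <- setdiff(model$marker_genes, rownames(expr))
  if (length(missing_genes)) {
    abort(paste0("expression matrix lacks marker gene(s): ",
                 paste(missing_genes, collapse = ", ")))
  }
  samples <- samples %||% colnames(expr)
  vals <- uaiscore_values(model, expr, samples)
  out <- tibble(sample_id = samples,
                uaiscore = as.numeric(vals),
                group = ifelse(vals > model$training_cutoff, "high", "low"))
  structure(out, class = c("uai_score_table", class(tibble())),
            training_cutoff = model$training_cutoff)
}

#' Cross-classify samples by UAIscore group and treatment arm
#'
#' Combines score stratification with randomized treatment to form the four
#' benefit-analysis groups: high score + immunotherapy, high + observation,
#' low + immunotherapy, low + observation.
#'
#' @param scores A [uai_score()] table.
#' @param clinical Clinical tibble covering the same samples.
#' @return A tibble `sample_id`, `group`, `arm`, `label` with the label a
#'   factor over the four group names; group counts are attached as the
#'   `counts` attribute.
#' @export
four_group_labels <- function(scores, clinical) {
  if (!all(scores$sample_id %in% clinical$sample_id) ||
      !all(clinical$sample_id %in% scores$sample_id)) {
    abort("scores and clinical must cover exactly the same samples")
  }
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  lv <- c("high+IO", "high+Obs", "low+IO", "low+Obs")
  label <- factor(paste0(scores$group, "+", cl$arm), levels = lv)
  out <- tibble(sample_id = scores$sample_id, group = scores$group,
                arm = cl$arm, label = label)
  attr(out, "counts") <- table(out$label)
  out
}

#' @export
print.uaiscore_model <- function(x, ...) {
  cat("<uaiscore_model>\n")
  cat("  markers:", length(x$marker_genes),
      "| trees:", x$forest$num.trees, "\n")
  cat("  trained on", length(x$fit_ids), x$train_arm, "patients; landmark",
      signif(x$landmark_time, 4), "\n")
  cat("  training cutoff (median score):", signif(x$training_cutoff, 4), "\n")
  cat("  OOB error (1 - C):", signif(x$oob_error, 4), "\n")
  invisible(x)
}

#' @export
tidy.uaiscore_model <- function(x, ...) {
  imp <- tryCatch(ranger::importance(x$forest), error = function(e) NULL)
  tibble(gene_id = x$marker_genes,
         direction = if (!is.null(x$markers$direction)) x$markers$direction else NA_character_,
         importance = if (!is.null(imp)) as.numeric(imp[x$feature_names]) else NA_real_)
}

#' @export
glance.uaiscore_model <- function(x, ...) {
  tibble(n_markers = length(x$marker_genes),
         n_trees = x$forest$num.trees,
         n_training = length(x$fit_ids),
         train_arm = x$train_arm,
         landmark_time = x$landmark_time,
         training_cutoff = x$training_cutoff,
         oob_error = x$oob_error,
         oob_concordance = 1 - x$oob_error)
}
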