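#' Batch univariate Cox screen of genes against a survival endpoint
#'
#' Fits, for every gene, a univariate Cox proportional-hazards model of the
#' chosen endpoint on the gene's standardized expression (Efron tie handling)
#' and returns the Wald p-value and hazard ratio per SD. Genes whose fit is
#' degenerate or fails to converge are kept in the output with `p = 1` and
#' `converged = FALSE`, so batch screening is total.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Clinical tibble with `sample_id`, `dfs_time`/`dfs_event`
#'   and (for `endpoint = "os"`) `os_time`/`os_event`.
#' @param endpoint `"dfs"` or `"os"`.
#' @param samples Optional sample subset (e.g. the training cohort).
#' @return A tibble: `gene_id`, `beta`, `hr`, `se`, `p`, `converged`.
#' @export
univariate_survival_screen <- function(expr, clinical,
                                       endpoint = c("dfs", "os"),
                                       samples = NULL) {
  endpoint <- match.arg(endpoint)
  assert_expression_matrix(expr)
  assert_clinical(clinical, require_os = endpoint == "os")
  samples <- samples %||% colnames(expr)
  if (!all(samples %in% colnames(expr)) || !all(samples %in% clinical$sample_id)) {
    abort("`samples` must be present in both expression and clinical data")
  }
  cl <- clinical[match(samples, clinical$sample_id), ]
  time <- cl[[paste0(endpoint, "_time")]]
  event <- cl[[paste0(endpoint, "_event")]]
  if (sum(event) < 2) {
    abort(paste0("survival screen needs at least 2 ", toupper(endpoint), " events"))
  }
  std <- standardize_rows(expr[, samples, drop = FALSE])
  degenerate_times <- length(unique(time[event == 1])) < 2 && all(event == 1)
  y <- Surv(time, event)

  rows <- lapply(seq_len(nrow(expr)), function(i) {
    if (std$constant[i] || degenerate_times) {
      return(list(beta = NA_real_, hr = NA_real_, se = NA_real_, p = 1, converged = FALSE))
    }
    fit_gene_cox(std$z[i, ], y)
  })
  out <- dplyr::bind_rows(rows)
  out$gene_id <- rownames(expr)
  out[, c("gene_id", "beta", "hr", "se", "p", "converged")]
}

# Univariate Cox on one standardized gene; failures become non-significant.
fit_gene_cox <- function(x, y) {
  fit <- tryCatch(
    suppressWarnings(coxph(y ~ x, ties = "efron",
                           control = coxph.control(iter.max = 25))),
    error = function(e) NULL
  )
  bad <- is.null(fit) || is.na(fit$coefficients[1]) ||
    !is.finite(fit$coefficients[1]) || abs(fit$coefficients[1]) > 15
  if (!bad) {
    se <- sqrt(diag(fit$var))[1]
    bad <- !is.finite(se) || se <= 0 || se > 15
  }
  if (bad) {
    return(list(beta = NA_real_, hr = NA_real_, se = NA_real_, p = 1, converged = FALSE))
  }
  b <- unname(fit$coefficients[1])
  list(beta = b, hr = exp(b), se = se,
       p = 2 * pnorm(-abs(b / se)), converged = TRUE)
}

#' Screen genes associated with both survival endpoints
#'
#' Convenience cascade step: runs [univariate_survival_screen()] for DFS and
#' OS on the same samples and returns the genes reaching `p < alpha` on both
#' endpoints, with the per-endpoint statistics side by side.
#'
#' @inheritParams univariate_survival_screen
#' @param alpha Per-endpoint significance level (raw p-values, no
#'   multiple-testing correction at this stage).
#' @return A tibble with one row per gene: per-endpoint `p`/`hr` columns and
#'   the logical `passed` flag.
#' @export
dual_endpoint_screen <- function(expr, clinical, samples = NULL, alpha = 0.05) {
  dfs <- univariate_survival_screen(expr, clinical, "dfs", samples)
  os <- univariate_survival_screen(expr, clinical, "os", samples)
  tibble(
    gene_id = dfs$gene_id,
    cox_p_dfs = dfs$p, cox_hr_dfs = dfs$hr,
    cox_p_os = os$p, cox_hr_os = os$hr,
    converged = dfs$converged & os$converged,
    passed = dfs$p < alpha & os$p < alpha
  )
}

#' Arm-specific treatment-interaction screen at a mean-expression cutoff
#'
#' For each gene, training samples are dichotomized at the training-set mean
#' expression; within each treatment arm separately, a log-rank test of high
#' vs low DFS and the corresponding Cox hazard ratio (high vs low) are
#' computed. A gene is an interaction candidate when its expression produces a
#' survival difference in *exactly one* arm (`p < alpha`): `interaction_arm`
#' records which; genes significant in both arms are excluded as prognostic
#' (`"both"`), and genes significant in neither are `"none"`. The HR direction
#' of the significant arm classifies the gene as protective (HR < 1) or risk
#' (HR > 1).
#'
#' The per-gene mean cutoff is computed on `training_ids` only and recorded,
#' so later application to validation data reuses the frozen cutoff.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Clinical tibble (needs `arm`, `dfs_time`, `dfs_event`).
#' @param gene_ids Genes to screen (default: all rows of `expr`).
#' @param training_ids Samples used for cutoffs and tests.
#' @param alpha Significance level per arm.
#' @return A tibble with one row per gene: `gene_id`, `cutoff`,
#'   `logrank_p_io`, `logrank_p_obs`, `hr_io`, `hr_obs`, `interaction_arm`
#'   (`IO`/`Obs`/`none`/`both`), `direction` (`protective`/`risk`/`NA`),
#'   `testable`.
#' @export
interaction_screen <- function(expr, clinical, gene_ids = NULL,
                               training_ids = NULL, alpha = 0.05) {
  assert_expression_matrix(expr)
  assert_clinical(clinical)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  gene_ids <- gene_ids %||% rownames(expr)
  training_ids <- training_ids %||% colnames(expr)
  if (length(gene_ids) == 0) {
    out <- tibble(gene_id = character(), cutoff = numeric(),
                  logrank_p_io = numeric(), logrank_p_obs = numeric(),
                  hr_io = numeric(), hr_obs = numeric(),
                  interaction_arm = character(), direction = character(),
                  testable = logical())
    attr(out, "alpha") <- alpha
    return(out)
  }
  if (!all(gene_ids %in% rownames(expr))) abort("unknown gene_ids")
  cl <- clinical[match(training_ids, clinical$sample_id), ]
  if (length(unique(cl$arm)) < 2) {
    abort("interaction screen needs both arms among training samples")
  }
  arm_idx <- list(IO = which(cl$arm == "IO"), Obs = which(cl$arm == "Obs"))
  surv_by_arm <- lapply(arm_idx, function(ii) Surv(cl$dfs_time[ii], cl$dfs_event[ii]))

  rows <- lapply(gene_ids, function(g) {
    x <- expr[g, training_ids]
    cutoff <- mean(x)
    high <- x > cutoff
    res <- list(gene_id = g, cutoff = cutoff,
                logrank_p_io = NA_real_, logrank_p_obs = NA_real_,
                hr_io = NA_real_, hr_obs = NA_real_,
                interaction_arm = "none", direction = NA_character_,
                testable = TRUE)
    for (arm in c("IO", "Obs")) {
      ii <- arm_idx[[arm]]
      hi <- high[ii]
      if (all(hi) || !any(hi)) { res$testable <- FALSE; next }
      lr <- arm_logrank_hr(surv_by_arm[[arm]], hi)
      key <- if (arm == "IO") "io" else "obs"
      res[[paste0("logrank_p_", key)]] <- lr$p
      res[[paste0("hr_", key)]] <- lr$hr
    }
    if (!res$testable) { res$interaction_arm <- "none"; return(res) }
    sig <- c(IO = isTRUE(res$logrank_p_io < alpha),
             Obs = isTRUE(res$logrank_p_obs < alpha))
    if (sum(sig) == 1) {
      res$interaction_arm <- names(sig)[sig]
      hr <- if (res$interaction_arm == "IO") res$hr_io else res$hr_obs
      if (is.finite(hr)) res$direction <- if (hr < 1) "protective" else "risk"
    } else if (sum(sig) == 2) {
      res$interaction_arm <- "both"
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  out
}

# Log-rank p and high-vs-low Cox HR within one arm.
arm_logrank_hr <- function(y, high) {
  p <- tryCatch({
    sd <- survdiff(y ~ high)
    unname(1 - pchisq(sd$chisq, df = 1))
  }, error = function(e) NA_real_)
  hr <- tryCatch({
    fit <- suppressWarnings(coxph(y ~ high, ties = "efron"))
    unname(exp(fit$coefficients[1]))
  }, error = function(e) NA_real_)
  list(p = p, hr = hr)
}

#' Partition interaction-screen survivors into marker genes by HR direction
#'
#' Selects the genes whose `interaction_arm` is a single arm (IO or Obs) and
#' partitions them at the hazard-ratio boundary HR = 1 of the significant arm:
#' protective markers (HR < 1) and risk markers (HR > 1). An HR of exactly 1
#' is assigned to the risk partition with a warning. The two partitions are
#' disjoint and together contain every selected gene.
#'
#' @param records Output of [interaction_screen()].
#' @param alpha Significance level recorded in the provenance (defaults to the
#'   one carried by `records`).
#' @return An object of class `marker_gene_set`: a tibble with `gene_id`,
#'   `interaction_arm`, `hr`, `direction`, plus `alpha` and counts as
#'   attributes.
#' @export
select_marker_genes <- function(records, alpha = NULL) {
  needed <- c("gene_id", "interaction_arm", "hr_io", "hr_obs", "direction")
  if (!all(needed %in% names(records))) {
    abort("records must come from interaction_screen()")
  }
  alpha <- alpha %||% attr(records, "alpha") %||% 0.05
  sel <- records[records$interaction_arm %in% c("IO", "Obs"), ]
  hr <- ifelse(sel$interaction_arm == "IO", sel$hr_io, sel$hr_obs)
  direction <- ifelse(hr < 1, "protective", "risk")
  if (any(hr == 1, na.rm = TRUE)) {
    warn("hazard ratio exactly 1 assigned to the risk partition")
  }
  out <- tibble(gene_id = sel$gene_id,
                interaction_arm = sel$interaction_arm,
                hr = hr, direction = direction)
  if (nrow(out) == 0) warn("empty marker gene set: no interaction genes selected")
  structure(out, class = c("marker_gene_set", class(tibble())),
            alpha = alpha)
}

#' @export
print.marker_gene_set <- function(x, ...) {
  cat("<marker_gene_set>", nrow(x), "markers (",
      sum(x$direction == "protective"), "protective /",
      sum(x$direction == "risk"), "risk )\n")
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' @rdname select_marker_genes
#' @param x A `marker_gene_set`.
#' @export
protective_genes <- function(x) x$gene_id[x$direction == "protective"]

#' @rdname select_marker_genes
#' @export
risk_genes <- function(x) x$gene_id[x$direction == "risk"]
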