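#' Combine the UAIscore with binary biomarkers into one risk score
#'
#' Integrates a continuous score with binary biomarkers (ctDNA, tTMB, PD-L1
#' as 0/1) by fitting a multivariable Cox model on the training samples and
#' using the resulting linear predictor as the combined risk value. The
#' coefficients are frozen on the training split, so held-out samples are
#' scored without refitting. Samples missing any component are excluded from
#' the fit and flagged (`complete = FALSE`) in the output, mirroring
#' complete-case biomarker-evaluable subsets.
#'
#' @param data Data frame with one row per sample, containing `sample_id`,
#'   every component column and the endpoint columns.
#' @param components Character vector of component column names. Binary
#'   components must be coded 0/1 (missing allowed).
#' @param time,event Endpoint columns (tidy-eval).
#' @param training_ids Sample identifiers used to fit the combination; all
#'   other samples are scored with the frozen coefficients.
#' @return An object of class `uai_combined`: list with `scores` (tibble
#'   `sample_id`, `risk`, `score` = `-risk` for benefit orientation,
#'   `complete`), `coefficients`, `fit` (a `uai_cox`), `components`,
#'   `n_training`.
#' @export
combine_modalities <- function(data, components, time, event, training_ids = NULL) {
  if (!length(components)) abort("at least one component is required")
  if (!"sample_id" %in% names(data)) abort("data must contain sample_id")
  missing_cols <- setdiff(components, names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown component(s): ", paste(missing_cols, collapse = ", ")))
  }
  time_v <- eval_tidy(enquo(time), data)
  event_v <- eval_tidy(enquo(event), data)
  training_ids <- training_ids %||% data$sample_id
  comp <- as.data.frame(data[, components, drop = FALSE])
  complete <- complete.cases(comp)
  in_train <- data$sample_id %in% training_ids
  fit_rows <- complete & in_train
  if (!any(fit_rows)) abort("no complete-component training samples")

  fit_df <- data.frame(sample_id = data$sample_id, .time = time_v,
                       .event = event_v, comp, check.names = FALSE)[fit_rows, ]
  fit <- cox_fit(fit_df, .time, .event, covariates = components)
  beta <- fit$fit$coefficients
  beta[is.na(beta)] <- 0

  risk <- rep(NA_real_, nrow(data))
  risk[complete] <- as.numeric(as.matrix(comp[complete, , drop = FALSE]) %*% beta)
  structure(
    list(scores = tibble(sample_id = data$sample_id, risk = risk,
                         score = -risk, complete = complete),
         coefficients = beta, fit = fit, components = components,
         n_training = sum(fit_rows)),
    class = "uai_combined"
  )
}

#' @export
print.uai_combined <- function(x, ...) {
  cat("<uai_combined>", paste(x$components, collapse = " + "),
      "| fitted on", x$n_training, "complete-case training samples\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.uai_combined <- function(x, ...) tidy(x$fit)

#' @export
glance.uai_combined <- function(x, ...) {
  dplyr::mutate(glance(x$fit), n_components = length(x$components))
}
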