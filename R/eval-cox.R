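#' Cox proportional-hazards regression with tidy output
#'
#' Partial-likelihood fit (Efron tie handling) of a survival endpoint on one
#' or more covariates, returning hazard ratios with Wald 95% confidence
#' intervals and p-values. Degenerate designs — constant or collinear
#' covariates, monotone-likelihood separation — are flagged in the result
#' rather than raised, so batch use stays total.
#'
#' @param data Data frame with one row per sample.
#' @param time,event Columns (tidy-eval) with follow-up time and 0/1 event.
#' @param covariates Character vector of covariate column names in `data`.
#' @return An object of class `uai_cox` wrapping the [survival::coxph()] fit;
#'   use [tidy()] for per-covariate hazard ratios and [glance()] for model
#'   fit statistics and flags.
#' @export
cox_fit <- function(data, time, event, covariates) {
  time_v <- eval_tidy(enquo(time), data)
  event_v <- eval_tidy(enquo(event), data)
  check_surv_inputs(time_v, event_v)
  if (!length(covariates)) abort("at least one covariate is required")
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown covariate(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[, covariates, drop = FALSE])
  constant <- vapply(df, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  if (any(constant)) {
    abort(paste0("constant covariate(s): ", paste(covariates[constant], collapse = ", ")))
  }
  if (sum(event_v) < length(covariates)) {
    abort("fewer events than covariates")
  }
  df$.time <- time_v
  df$.event <- event_v
  fml <- stats::as.formula(paste("Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  warnings_seen <- character()
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  se <- sqrt(diag(fit$var))
  flags <- character()
  if (any(is.na(fit$coefficients))) flags <- c(flags, "collinear")
  if (any(!is.finite(se)) || any(se > 15, na.rm = TRUE) ||
      any(abs(fit$coefficients) > 15, na.rm = TRUE)) {
    flags <- c(flags, "separation")
  }
  if (any(grepl("did not converge|infinite", warnings_seen))) {
    flags <- c(flags, "non_convergence")
  }
  structure(list(fit = fit, covariates = covariates, flags = flags,
                 n = fit$n, n_events = fit$nevent),
            class = "uai_cox")
}

#' @export
print.uai_cox <- function(x, ...) {
  cat("<uai_cox>", x$n, "samples,", x$n_events, "events")
  if (length(x$flags)) cat("  [flags:", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.uai_cox <- function(x, conf_level = 0.95, ...) {
  beta <- x$fit$coefficients
  se <- sqrt(diag(x$fit$var))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(term = names(beta),
         estimate = unname(beta),
         std_error = unname(se),
         hr = exp(unname(beta)),
         conf_low = exp(unname(beta - zq * se)),
         conf_high = exp(unname(beta + zq * se)),
         p_value = 2 * pnorm(-abs(unname(beta) / unname(se))))
}

#' @export
glance.uai_cox <- function(x, ...) {
  ll <- x$fit$loglik
  tibble(n = x$n, n_events = x$n_events,
         log_lik = ll[length(ll)], log_lik_null = ll[1],
         concordance = unname(x$fit$concordance["concordance"]),
         flagged = length(x$flags) > 0,
         flags = paste(x$flags, collapse = ";"))
}
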