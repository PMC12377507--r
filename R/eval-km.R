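#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function, optionally per group,
#' via [survival::survfit()]. On uncensored data this equals the empirical
#' survival function exactly.
#'
#' @param data Data frame with one row per sample.
#' @param time,event Columns (tidy-eval) holding follow-up time (> 0) and
#'   event indicator (0/1).
#' @param group Optional grouping column.
#' @return A tibble of class `uai_km`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `std_err`, `lower`, `upper`.
#' @export
#' @examples
#' d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 1))
#' km_fit(d, t, e)
km_fit <- function(data, time, event, group = NULL) {
  time <- eval_tidy(enquo(time), data)
  event <- eval_tidy(enquo(event), data)
  gq <- enquo(group)
  grp <- if (quo_is_null(gq)) rep("all", length(time)) else as.character(eval_tidy(gq, data))
  check_surv_inputs(time, event)
  if (any(is.na(grp)) || any(!nzchar(grp))) abort("empty or missing group label")
  tab <- table(grp)
  if (any(tab == 0)) abort(paste0("empty group: ", names(tab)[tab == 0][1]))

  out <- purrr::map(sort(unique(grp)), function(g) {
    keep <- grp == g
    fit <- survfit(Surv(time[keep], event[keep]) ~ 1, conf.type = "log-log")
    tibble(group = g, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor,
           survival = fit$surv, std_err = fit$std.err,
           lower = fit$lower, upper = fit$upper)
  }) |> purrr::list_rbind()
  structure(out, class = c("uai_km", class(tibble())))
}

check_surv_inputs <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) abort("events must be 0/1")
  invisible(NULL)
}

#' Log-rank (Mantel-Cox) test across survival curves
#'
#' @inheritParams km_fit
#' @param group Grouping column; at least two groups required.
#' @return A one-row tibble: `statistic` (chi-squared), `df`, `p_value`,
#'   `n`, `n_events`.
#' @export
logrank_test <- function(data, time, event, group) {
  time <- eval_tidy(enquo(time), data)
  event <- eval_tidy(enquo(event), data)
  grp <- eval_tidy(enquo(group), data)
  check_surv_inputs(time, event)
  if (length(unique(grp)) < 2) abort("log-rank test needs at least 2 groups")
  if (sum(event) < 1) abort("log-rank test needs at least 1 event")
  sd <- survdiff(Surv(time, event) ~ grp)
  df <- length(sd$n) - 1
  tibble(statistic = unname(sd$chisq), df = df,
         p_value = unname(1 - pchisq(sd$chisq, df)),
         n = length(time), n_events = sum(event))
}

#' @export
autoplot.uai_km <- function(object, ...) {
  # extend each curve to a step function starting at S(0) = 1
  d <- dplyr::bind_rows(
    dplyr::distinct(object, .data$group) |> mutate(time = 0, survival = 1),
    dplyr::select(object, "group", "time", "survival")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival, colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
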