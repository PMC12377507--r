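#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-case / dynamic-control AUC of a continuous risk score at a grid
#' of evaluation times, corrected for right censoring by IPCW. At time `t`,
#' cases are subjects with an observed event by `t` (weight `1/G(T_i-)`) and
#' controls are subjects still event-free past `t` (weight `1/G(t)`), where
#' `G` is the Kaplan-Meier estimate of the censoring survival function. The
#' AUC is the weighted proportion of case-control pairs ranked concordantly
#' by the score (ties count 1/2), so it is invariant to strictly increasing
#' transformations of the score. Percentile bootstrap confidence intervals
#' are taken over samples.
#'
#' The score is oriented as *risk*: higher score should mean earlier events.
#' To evaluate a benefit-oriented score such as the UAIscore, pass its
#' negation (or set `higher_risk = FALSE`).
#'
#' @param data Data frame with one row per sample.
#' @param score Column (tidy-eval) with the continuous marker.
#' @param time,event Columns with follow-up time and 0/1 event indicator.
#' @param eval_times Numeric vector of evaluation times; times beyond the
#'   last observed event are dropped with a warning.
#' @param n_bootstrap Bootstrap replicates for the 95% CI (0 disables).
#' @param higher_risk If `FALSE`, the score is negated before evaluation.
#' @param marker Label stored with the curve (for plotting/comparison).
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble of class `uai_auc`: `marker`, `time`, `auc`, `ci_lo`,
#'   `ci_hi`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(data, score, time, event, eval_times,
                               n_bootstrap = 200, higher_risk = TRUE,
                               marker = "score", seed = 1L) {
  s <- eval_tidy(enquo(score), data)
  t_v <- eval_tidy(enquo(time), data)
  e_v <- eval_tidy(enquo(event), data)
  check_surv_inputs(t_v, e_v)
  if (any(!is.finite(s))) abort("score contains non-finite values")
  if (n_bootstrap < 0) abort("n_bootstrap must be >= 0")
  if (!higher_risk) s <- -s

  last_event <- suppressWarnings(max(t_v[e_v == 1]))
  keep <- eval_times <= last_event & eval_times <= max(t_v)
  if (!all(keep)) {
    warn(sprintf("%d evaluation time(s) beyond last observed event dropped",
                 sum(!keep)))
    eval_times <- eval_times[keep]
  }
  if (!length(eval_times)) abort("no usable evaluation times")

  est <- ipcw_auc_curve(s, t_v, e_v, eval_times)
  ci_lo <- rep(NA_real_, length(eval_times))
  ci_hi <- rep(NA_real_, length(eval_times))
  if (n_bootstrap > 0) {
    n <- length(s)
    boot <- with_seed(as.integer(seed), {
      vapply(seq_len(n_bootstrap), function(b) {
        ii <- sample.int(n, n, replace = TRUE)
        ipcw_auc_curve(s[ii], t_v[ii], e_v[ii], eval_times)$auc
      }, numeric(length(eval_times)))
    })
    boot <- matrix(boot, nrow = length(eval_times))
    ci_lo <- apply(boot, 1, quantile, 0.025, na.rm = TRUE, names = FALSE)
    ci_hi <- apply(boot, 1, quantile, 0.975, na.rm = TRUE, names = FALSE)
  }
  structure(
    tibble(marker = marker, time = eval_times, auc = est$auc,
           ci_lo = ci_lo, ci_hi = ci_hi,
           n_cases = est$n_cases, n_controls = est$n_controls),
    class = c("uai_auc", class(tibble()))
  )
}

# IPCW cumulative/dynamic AUC at each time; censoring survival G by KM on the
# censoring indicator, evaluated left-continuously at case event times.
ipcw_auc_curve <- function(s, time, event, eval_times) {
  G <- censoring_km(time, event)
  w_case_all <- 1 / G(time, left = TRUE)
  auc <- n_cases <- n_controls <- numeric(length(eval_times))
  for (k in seq_along(eval_times)) {
    t0 <- eval_times[k]
    is_case <- time <= t0 & event == 1
    is_ctrl <- time > t0
    n_cases[k] <- sum(is_case)
    n_controls[k] <- sum(is_ctrl)
    if (n_cases[k] == 0 || n_controls[k] == 0) { auc[k] <- NA_real_; next }
    w_case <- w_case_all[is_case]
    w_ctrl <- rep(1 / G(t0, left = FALSE), n_controls[k])
    sc <- s[is_case]; sn <- s[is_ctrl]
    # weighted concordant-pair fraction via ranking (O(n log n))
    ord <- order(sn)
    sn_sorted <- sn[ord]; wn_sorted <- w_ctrl[ord]
    cum_w <- c(0, cumsum(wn_sorted))
    total_w_ctrl <- cum_w[length(cum_w)]
    below <- findInterval(sc, sn_sorted, left.open = TRUE)   # controls with sn <  sc
    at_or_below <- findInterval(sc, sn_sorted)               # controls with sn <= sc
    w_below <- cum_w[below + 1]
    w_ties <- cum_w[at_or_below + 1] - w_below
    num <- sum(w_case * (w_below + 0.5 * w_ties))
    auc[k] <- num / (sum(w_case) * total_w_ctrl)
  }
  list(auc = auc, n_cases = n_cases, n_controls = n_controls)
}

# KM estimator of the censoring survival function G(t) = P(C > t).
# Returns a function of t; left = TRUE evaluates G(t-).
censoring_km <- function(time, event) {
  fit <- survfit(Surv(time, 1 - event) ~ 1)
  step_t <- fit$time
  step_s <- fit$surv
  function(t, left = FALSE) {
    idx <- if (left) findInterval(t, step_t, left.open = TRUE) else findInterval(t, step_t)
    g <- ifelse(idx == 0, 1, step_s[pmax(idx, 1)])
    pmax(g, .Machine$double.eps)
  }
}

#' @export
autoplot.uai_auc <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$time, .data$auc, colour = .data$marker,
                                    fill = .data$marker)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7)
  if (!all(is.na(object$ci_lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                                  alpha = 0.15, colour = NA)
  }
  p + ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "AUC(t)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
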