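#' Treatment-benefit analysis within score strata
#'
#' Core four-group analysis: within the high-score stratum and the low-score
#' stratum separately, estimates the treatment effect — Cox hazard ratio of
#' IO vs observation with 95% CI and the log-rank p-value — and, conversely,
#' the score-group effect within each treatment arm. A stratum missing one of
#' the arms is skipped with a warning. A predictive (benefit) score shows
#' HR(IO vs Obs) < 1 in the high stratum and no advantage (HR >= 1) in the
#' low stratum.
#'
#' @param scores A [uai_score()] table (`sample_id`, `group`).
#' @param clinical Clinical tibble with `sample_id`, `arm` and the endpoint
#'   columns.
#' @param endpoint `"dfs"` or `"os"`.
#' @return A tibble of class `uai_benefit`: `analysis`
#'   (`"arm_within_score"` / `"score_within_arm"`), `stratum`, `comparison`,
#'   `hr`, `conf_low`, `conf_high`, `p_logrank`, `p_cox`, `n`, `n_events`.
#' @export
benefit_analysis <- function(scores, clinical, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  assert_clinical(clinical, require_os = endpoint == "os")
  if (!all(scores$sample_id %in% clinical$sample_id)) {
    abort("scores contain samples absent from the clinical table")
  }
  cl <- clinical[match(scores$sample_id, clinical$sample_id), ]
  d <- tibble(sample_id = scores$sample_id, group = scores$group, arm = cl$arm,
              time = cl[[paste0(endpoint, "_time")]],
              event = cl[[paste0(endpoint, "_event")]])

  one_contrast <- function(dd, covariate, ref, alt, stratum, analysis) {
    present <- unique(dd[[covariate]])
    if (!all(c(ref, alt) %in% present)) {
      warn(sprintf("stratum '%s' lacks a %s level; skipped", stratum, covariate))
      return(NULL)
    }
    dd$.x <- as.integer(dd[[covariate]] == alt)
    fit <- cox_fit(dd, time, event, covariates = ".x")
    td <- tidy(fit)
    lr <- logrank_test(dd, time, event, .x)
    tibble(analysis = analysis, stratum = stratum,
           comparison = paste(alt, "vs", ref),
           hr = td$hr, conf_low = td$conf_low, conf_high = td$conf_high,
           p_logrank = lr$p_value, p_cox = td$p_value,
           n = fit$n, n_events = fit$n_events)
  }

  out <- dplyr::bind_rows(
    purrr::map(c("high", "low"), function(g) {
      one_contrast(d[d$group == g, ], "arm", "Obs", "IO", g, "arm_within_score")
    }),
    purrr::map(c("IO", "Obs"), function(a) {
      one_contrast(d[d$arm == a, ], "group", "low", "high", a, "score_within_arm")
    })
  )
  structure(out, class = c("uai_benefit", class(tibble())))
}
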