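#' Configure a synthetic two-arm adjuvant-immunotherapy trial
#'
#' Describes the generative model for [simulate_trial()]: a 1:1 (by default)
#' randomized trial with proportional-hazards disease-free survival (DFS),
#' an overall-survival (OS) endpoint coupled to DFS, right censoring from
#' administrative cutoff and dropout, a log-scale expression matrix with
#' planted gene effects, and binary biomarkers (ctDNA, tTMB, PD-L1) with
#' their own prognostic hazard contributions.
#'
#' Gene classes: *prognostic* genes carry the same log-hazard per standard
#' deviation of expression in both arms; *predictive* genes act in the
#' treatment (IO) arm only — protective with log-hazard `-beta_predictive`,
#' risk with `+beta_predictive`. All remaining genes are null.
#'
#' The DFS hazard for patient \eqn{i} is
#' \deqn{h_i(t) = h_0 \exp\!\Big(\sum_{g \in prog} \beta_g x_{gi}
#'   + a_i \sum_{g \in pred} \beta_g x_{gi} + \sum_b \beta_b z_{bi}\Big)}
#' with \eqn{a_i = 1} for the IO arm, exponential baseline hazard \eqn{h_0},
#' latent expression \eqn{x_{gi} \sim N(0,1)} and biomarkers
#' \eqn{z_{bi} \sim Bernoulli(prevalence_b)}. Observed time is the minimum of
#' the event time, an exponential dropout time and the administrative cutoff.
#' The latent OS event time is the latent DFS event time plus an exponential
#' lag with rate `baseline_hazard * os_coupling / (1 - os_coupling)`, so
#' `os_coupling` near 1 ties OS tightly to DFS and OS >= DFS always holds.
#'
#' Defaults emulate a trial of 728 patients at desk scale: 2,000 genes with a
#' small planted signature per class, ~70% DFS events by the administrative
#' cutoff, and biomarker prevalences in the range reported for muscle-invasive
#' urothelial carcinoma cohorts. Effect sizes are illustrative — the source
#' trial data are access-controlled, so no parameter here is calibrated to it.
#'
#' @param n_patients Number of randomized patients.
#' @param arm_ratio Fraction randomized to the treatment (IO) arm.
#' @param n_genes_total Total genes in the expression matrix.
#' @param n_prognostic,n_predictive_protective,n_predictive_risk Planted gene
#'   counts per class; the remainder are null.
#' @param beta_prognostic Log-hazard per SD of expression, both arms.
#' @param beta_predictive Absolute log-hazard per SD of expression in the IO
#'   arm only; sign is negative for protective genes, positive for risk genes.
#' @param baseline_hazard Exponential baseline DFS hazard (events per month).
#' @param admin_censor_time Administrative censoring time (months).
#' @param dropout_censor_rate Exponential dropout censoring rate.
#' @param os_coupling DFS-OS coupling in (0, 1); higher = tighter coupling.
#' @param biomarker_prevalence Named fractions positive for `ctdna_c1d1`,
#'   `ttmb`, `pdl1`.
#' @param biomarker_log_hr Named prognostic log-hazards for the same markers.
#' @param noise_sd Measurement noise SD added to the latent expression.
#' @param seed Default seed used by [simulate_trial()] when none is passed.
#'
#' @return A list of class `trial_config`.
#' @seealso [simulate_trial()]
#' @export
#' @examples
#' cfg <- trial_config(n_patients = 100, n_genes_total = 50, seed = 1)
#' trial <- simulate_trial(cfg)
#' dim(trial$expression)
trial_config <- function(n_patients = 728,
                         arm_ratio = 0.5,
                         n_genes_total = 2000,
                         n_prognostic = 3,
                         n_predictive_protective = 3,
                         n_predictive_risk = 3,
                         beta_prognostic = 0.5,
                         beta_predictive = 1.0,
                         baseline_hazard = 0.08,
                         admin_censor_time = 36,
                         dropout_censor_rate = 0.01,
                         os_coupling = 0.7,
                         biomarker_prevalence = c(ctdna_c1d1 = 0.37, ttmb = 0.40, pdl1 = 0.45),
                         biomarker_log_hr = c(ctdna_c1d1 = 0.7, ttmb = -0.15, pdl1 = -0.1),
                         noise_sd = 0.2,
                         seed = 1L) {
  cfg <- list(
    n_patients = n_patients, arm_ratio = arm_ratio,
    n_genes_total = n_genes_total, n_prognostic = n_prognostic,
    n_predictive_protective = n_predictive_protective,
    n_predictive_risk = n_predictive_risk,
    beta_prognostic = beta_prognostic, beta_predictive = beta_predictive,
    baseline_hazard = baseline_hazard, admin_censor_time = admin_censor_time,
    dropout_censor_rate = dropout_censor_rate, os_coupling = os_coupling,
    biomarker_prevalence = biomarker_prevalence,
    biomarker_log_hr = biomarker_log_hr,
    noise_sd = noise_sd, seed = seed
  )
  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  num <- unlist(cfg[c("n_patients", "arm_ratio", "n_genes_total", "n_prognostic",
                      "n_predictive_protective", "n_predictive_risk",
                      "beta_prognostic", "beta_predictive", "baseline_hazard",
                      "admin_censor_time", "dropout_censor_rate", "os_coupling",
                      "noise_sd")])
  if (!all(is.finite(num))) abort("trial_config: all numeric fields must be finite")
  planted <- cfg$n_prognostic + cfg$n_predictive_protective + cfg$n_predictive_risk
  if (planted > cfg$n_genes_total) {
    abort("trial_config: planted gene counts exceed n_genes_total")
  }
  if (cfg$n_patients < 2) abort("trial_config: n_patients must be at least 2")
  if (cfg$arm_ratio <= 0 || cfg$arm_ratio >= 1) abort("trial_config: arm_ratio must be in (0,1)")
  if (cfg$baseline_hazard <= 0) abort("trial_config: baseline_hazard must be positive")
  if (cfg$admin_censor_time <= 0) abort("trial_config: admin_censor_time must be positive")
  if (cfg$dropout_censor_rate < 0) abort("trial_config: dropout_censor_rate must be non-negative")
  if (cfg$os_coupling <= 0 || cfg$os_coupling >= 1) abort("trial_config: os_coupling must be in (0,1)")
  if (cfg$noise_sd < 0) abort("trial_config: noise_sd must be non-negative")
  prev <- cfg$biomarker_prevalence
  if (length(prev) && (any(!is.finite(prev)) || any(prev <= 0) || any(prev >= 1))) {
    abort("trial_config: biomarker prevalences must lie in (0,1)")
  }
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat("  patients:", x$n_patients, sprintf("(%.0f%% IO)", 100 * x$arm_ratio), "\n")
  cat("  genes:", x$n_genes_total,
      sprintf("(%d prognostic, %d protective, %d risk)",
              x$n_prognostic, x$n_predictive_protective, x$n_predictive_risk), "\n")
  cat("  effects: beta_prognostic =", x$beta_prognostic,
      " beta_predictive =", x$beta_predictive, "\n")
  cat("  hazard:", x$baseline_hazard, "/month, admin censor at",
      x$admin_censor_time, "months\n")
  invisible(x)
}

#' Simulate a synthetic randomized trial with planted gene effects
#'
#' Draws one complete trial — expression matrix, clinical table and ground
#' truth — from the generative model described in [trial_config()]. The same
#' config and seed always reproduce the identical dataset bit for bit.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A list of class `synthetic_trial` with elements:
#' \describe{
#'   \item{expression}{numeric genes x samples matrix, log-like scale
#'     (per-gene baseline level plus standard-normal signal plus noise).}
#'   \item{clinical}{tibble: `sample_id`, `arm` (IO/Obs), `dfs_time`,
#'     `dfs_event`, `os_time`, `os_event`, `ctdna_c1d1`, `ctdna_c3d1`,
#'     `ttmb`, `pdl1`.}
#'   \item{truth}{list: `genes` tibble (`gene_id`, `class`, `true_beta`),
#'     `samples` tibble (`sample_id`, `latent_benefit`, `linear_predictor`),
#'     where `latent_benefit` is minus the IO-arm-specific part of the
#'     linear predictor (higher = more benefit from treatment).}
#'   \item{config}{the config used.}
#' }
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  validate_trial_config(config)
  seed <- seed %||% config$seed
  with_seed(as.integer(seed), simulate_trial_impl(config))
}

simulate_trial_impl <- function(cfg) {
  n <- cfg$n_patients
  p <- cfg$n_genes_total
  sample_ids <- sprintf("P%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(p))

  # gene classes in a fixed layout: planted genes first, then nulls
  class_vec <- rep("null", p)
  idx <- 0
  take <- function(k) (idx + 1):(idx + k)
  if (cfg$n_prognostic > 0) { class_vec[take(cfg$n_prognostic)] <- "prognostic"; idx <- idx + cfg$n_prognostic }
  if (cfg$n_predictive_protective > 0) { class_vec[take(cfg$n_predictive_protective)] <- "predictive_protective"; idx <- idx + cfg$n_predictive_protective }
  if (cfg$n_predictive_risk > 0) { class_vec[take(cfg$n_predictive_risk)] <- "predictive_risk"; idx <- idx + cfg$n_predictive_risk }

  true_beta <- numeric(p)
  true_beta[class_vec == "prognostic"] <- cfg$beta_prognostic
  true_beta[class_vec == "predictive_protective"] <- -abs(cfg$beta_predictive)
  true_beta[class_vec == "predictive_risk"] <- abs(cfg$beta_predictive)

  # latent standardized expression drives the hazard; the observed matrix adds
  # a per-gene baseline level and measurement noise (log-like scale)
  x <- matrix(rnorm(p * n), nrow = p, dimnames = list(gene_ids, sample_ids))
  baseline_level <- runif(p, 2, 10)
  expr <- x + baseline_level
  if (cfg$noise_sd > 0) expr <- expr + matrix(rnorm(p * n, sd = cfg$noise_sd), nrow = p)

  arm <- ifelse(runif(n) < cfg$arm_ratio, "IO", "Obs")
  a <- as.integer(arm == "IO")

  # biomarkers: Bernoulli with stated prevalence, prognostic in both arms
  bm_names <- names(cfg$biomarker_prevalence)
  z <- sapply(bm_names, function(b) rbinom(n, 1, cfg$biomarker_prevalence[[b]]))
  if (length(bm_names)) z <- matrix(z, nrow = n, dimnames = list(NULL, bm_names))

  prog <- class_vec == "prognostic"
  pred <- class_vec %in% c("predictive_protective", "predictive_risk")
  lp_prog <- if (any(prog)) colSums(x[prog, , drop = FALSE] * true_beta[prog]) else numeric(n)
  lp_pred <- if (any(pred)) colSums(x[pred, , drop = FALSE] * true_beta[pred]) else numeric(n)
  lp_bm <- if (length(bm_names)) {
    drop(z %*% unlist(cfg$biomarker_log_hr[bm_names]))
  } else numeric(n)
  lp <- lp_prog + a * lp_pred + lp_bm

  # exponential event times under the proportional-hazards model
  t_event <- rexp(n, rate = cfg$baseline_hazard * exp(lp))
  t_drop <- if (cfg$dropout_censor_rate > 0) rexp(n, cfg$dropout_censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, cfg$admin_censor_time)
  dfs_time <- pmin(t_event, t_cens)
  dfs_event <- as.integer(t_event <= t_cens)

  # OS: DFS latent event time plus exponential lag, censored at the same time
  lag_rate <- cfg$baseline_hazard * cfg$os_coupling / (1 - cfg$os_coupling)
  t_os <- t_event + rexp(n, lag_rate)
  os_time <- pmin(t_os, t_cens)
  os_event <- as.integer(t_os <= t_cens)

  # post-treatment ctDNA: clearance from baseline positivity, more often
  # under IO; purely illustrative, not hazard-linked
  ctdna_c3d1 <- NULL
  if ("ctdna_c1d1" %in% bm_names) {
    clear_p <- ifelse(a == 1, 0.5, 0.2)
    cleared <- rbinom(n, 1, clear_p)
    ctdna_c3d1 <- ifelse(z[, "ctdna_c1d1"] == 1L & cleared == 0L, "pos", "neg")
  }

  clinical <- tibble(
    sample_id = sample_ids,
    arm = arm,
    dfs_time = dfs_time, dfs_event = dfs_event,
    os_time = os_time, os_event = os_event,
    ctdna_c1d1 = if ("ctdna_c1d1" %in% bm_names) ifelse(z[, "ctdna_c1d1"] == 1, "pos", "neg") else NA_character_,
    ctdna_c3d1 = ctdna_c3d1 %||% NA_character_,
    ttmb = if ("ttmb" %in% bm_names) ifelse(z[, "ttmb"] == 1, "pos", "neg") else NA_character_,
    pdl1 = if ("pdl1" %in% bm_names) ifelse(z[, "pdl1"] == 1, "IC23", "IC01") else NA_character_
  )

  truth <- list(
    genes = tibble(gene_id = gene_ids, class = class_vec, true_beta = true_beta),
    samples = tibble(sample_id = sample_ids,
                     latent_benefit = -lp_pred,
                     linear_predictor = lp)
  )

  structure(list(expression = expr, clinical = clinical, truth = truth,
                 config = cfg),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>\n")
  cat(" ", ncol(x$expression), "patients x", nrow(x$expression), "genes\n")
  cat("  arms:", sum(x$clinical$arm == "IO"), "IO /",
      sum(x$clinical$arm == "Obs"), "Obs\n")
  cat("  DFS events:", sum(x$clinical$dfs_event),
      sprintf("(%.0f%%)", 100 * mean(x$clinical$dfs_event)), "\n")
  invisible(x)
}
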