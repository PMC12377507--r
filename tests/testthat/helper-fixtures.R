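# Shared fixtures, all generated in code.

# A small expression matrix with named genes/samples.
toy_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples), nrow = n_genes,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%03d", seq_len(n_samples))))
  })
}

# Minimal valid clinical table for given sample ids.
toy_clinical <- function(sample_ids, seed = 1) {
  n <- length(sample_ids)
  withr::with_seed(seed, {
    t_ev <- rexp(n, 0.1)
    cens <- pmin(rexp(n, 0.03), 30)
    tibble::tibble(
      sample_id = sample_ids,
      arm = rep_len(c("IO", "Obs"), n),
      dfs_time = pmin(t_ev, cens),
      dfs_event = as.integer(t_ev <= cens),
      os_time = pmin(t_ev + rexp(n, 0.2), cens),
      os_event = as.integer(t_ev + rexp(n, 0.2) <= cens)
    ) |> dplyr::mutate(os_time = pmax(os_time, dfs_time))
  })
}

# Default small simulated trial reused across tests.
small_trial <- function(seed = 42, ...) {
  cfg <- trial_config(n_patients = 240, n_genes_total = 80,
                      n_prognostic = 2, n_predictive_protective = 2,
                      n_predictive_risk = 2, seed = seed, ...)
  simulate_trial(cfg)
}

# Independent Kaplan-Meier estimate of P(C > t) (censoring distribution),
# written as an explicit loop for use as an oracle.
oracle_censor_surv <- function(time, event, t, left = FALSE) {
  ut <- sort(unique(time[event == 0]))
  s <- 1
  for (u in ut) {
    if ((left && u >= t) || (!left && u > t)) break
    at_risk <- sum(time >= u)
    d <- sum(time == u & event == 0)
    s <- s * (1 - d / at_risk)
  }
  s
}
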