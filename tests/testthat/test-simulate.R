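test_that("identical config and seed reproduce the dataset bit for bit", {
  a <- small_trial(seed = 7)
  b <- small_trial(seed = 7)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- small_trial(seed = 8)
  expect_false(identical(a$expression, c$expression))
})

test_that("overall survival never precedes disease-free survival", {
  tr <- small_trial(seed = 11)
  expect_true(all(tr$clinical$os_time >= tr$clinical$dfs_time))
  # a death-bearing DFS event cannot be censored for OS before dfs_time
  expect_true(all(tr$clinical$os_time > 0))
})

test_that("every gene has exactly one class label and nulls have beta zero", {
  tr <- small_trial(seed = 3)
  g <- tr$truth$genes
  expect_setequal(g$gene_id, rownames(tr$expression))
  expect_true(all(g$class %in% c("prognostic", "predictive_protective",
                                 "predictive_risk", "null")))
  expect_true(all(g$true_beta[g$class == "null"] == 0))
  expect_true(all(g$true_beta[g$class == "predictive_protective"] < 0))
  expect_true(all(g$true_beta[g$class == "predictive_risk"] > 0))
})

test_that("realized arm fraction stays within binomial 99% bounds", {
  tr <- simulate_trial(trial_config(n_patients = 1000, n_genes_total = 10,
                                    n_prognostic = 0, n_predictive_protective = 0,
                                    n_predictive_risk = 0, seed = 5))
  n_io <- sum(tr$clinical$arm == "IO")
  expect_gte(n_io, qbinom(0.005, 1000, 0.5))
  expect_lte(n_io, qbinom(0.995, 1000, 0.5))
})

test_that("no censoring configuration yields all events", {
  cfg <- trial_config(n_patients = 150, n_genes_total = 10,
                      n_prognostic = 0, n_predictive_protective = 0,
                      n_predictive_risk = 0,
                      admin_censor_time = 1e9, dropout_censor_rate = 1e-12,
                      seed = 2)
  tr <- simulate_trial(cfg)
  expect_true(all(tr$clinical$dfs_event == 1))
  expect_true(all(tr$clinical$os_event == 1))
})

test_that("empirical censoring fraction matches the competing-exponentials value", {
  cfg <- trial_config(n_patients = 5000, n_genes_total = 20,
                      n_prognostic = 1, n_predictive_protective = 1,
                      n_predictive_risk = 1, seed = 9)
  tr <- simulate_trial(cfg)
  lp <- tr$truth$samples$linear_predictor
  h <- cfg$baseline_hazard * exp(lp)
  r <- cfg$dropout_censor_rate
  # P(event) given covariates: event beats dropout and the admin cutoff
  p_event <- h / (h + r) * (1 - exp(-(h + r) * cfg$admin_censor_time))
  expected <- mean(p_event)
  mc_sd <- sqrt(mean(p_event * (1 - p_event)) / length(p_event))
  expect_lt(abs(mean(tr$clinical$dfs_event) - expected), 4 * mc_sd)
})

test_that("global-null per-gene Cox z statistics are standard normal", {
  cfg <- trial_config(n_patients = 400, n_genes_total = 300,
                      n_prognostic = 0, n_predictive_protective = 0,
                      n_predictive_risk = 0,
                      biomarker_log_hr = c(ctdna_c1d1 = 0, ttmb = 0, pdl1 = 0),
                      seed = 13)
  tr <- simulate_trial(cfg)
  scr <- univariate_survival_screen(tr$expression, tr$clinical, "dfs")
  z <- scr$beta / scr$se
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(var(z), 0.8)
  expect_lt(var(z), 1.2)
})

test_that("arm-stratified Cox recovers a planted predictive effect", {
  cfg <- trial_config(n_patients = 2000, n_genes_total = 5,
                      n_prognostic = 0, n_predictive_protective = 1,
                      n_predictive_risk = 0, beta_predictive = 1.0,
                      noise_sd = 0, seed = 21)
  tr <- simulate_trial(cfg)
  gene <- tr$truth$genes$gene_id[tr$truth$genes$class == "predictive_protective"]
  d <- tr$clinical
  d$x <- as.numeric(scale(tr$expression[gene, d$sample_id]))
  io <- d[d$arm == "IO", ]
  obs <- d[d$arm == "Obs", ]
  beta_io <- survival::coxph(survival::Surv(dfs_time, dfs_event) ~ x, data = io)$coefficients
  beta_obs <- survival::coxph(survival::Surv(dfs_time, dfs_event) ~ x, data = obs)$coefficients
  expect_lt(abs(beta_io - (-1.0)), 0.15)
  expect_lt(abs(beta_obs), 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(arm_ratio = 1.2), "arm_ratio")
  expect_error(trial_config(n_genes_total = 5, n_prognostic = 10), "planted")
  expect_error(trial_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(trial_config(os_coupling = 1), "os_coupling")
  expect_error(trial_config(biomarker_prevalence = c(ctdna_c1d1 = 1.5)), "prevalence")
})

test_that("biomarkers are drawn with the stated prevalence and hazard link", {
  cfg <- trial_config(n_patients = 4000, n_genes_total = 10,
                      n_prognostic = 0, n_predictive_protective = 0,
                      n_predictive_risk = 0,
                      biomarker_prevalence = c(ctdna_c1d1 = 0.3),
                      biomarker_log_hr = c(ctdna_c1d1 = 0.7),
                      seed = 31)
  tr <- simulate_trial(cfg)
  pos <- tr$clinical$ctdna_c1d1 == "pos"
  expect_lt(abs(mean(pos) - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
  d <- tr$clinical
  d$z <- as.integer(pos)
  fit <- survival::coxph(survival::Surv(dfs_time, dfs_event) ~ z, data = d)
  expect_lt(abs(fit$coefficients - 0.7), 0.15)
})
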