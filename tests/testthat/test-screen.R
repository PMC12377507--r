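test_that("null genes reach p < 0.05 at roughly the nominal rate", {
  cfg <- trial_config(n_patients = 400, n_genes_total = 400,
                      n_prognostic = 0, n_predictive_protective = 0,
                      n_predictive_risk = 0, seed = 17)
  tr <- simulate_trial(cfg)
  scr <- univariate_survival_screen(tr$expression, tr$clinical, "dfs")
  expect_gte(mean(scr$p < 0.05), 0.03)
  expect_lte(mean(scr$p < 0.05), 0.08)
})

test_that("a planted prognostic gene is detected with high power", {
  hits <- vapply(1:60, function(s) {
    cfg <- trial_config(n_patients = 475, n_genes_total = 3,
                        n_prognostic = 1, n_predictive_protective = 0,
                        n_predictive_risk = 0, beta_prognostic = 0.8,
                        biomarker_log_hr = c(ctdna_c1d1 = 0, ttmb = 0, pdl1 = 0),
                        seed = 1000 + s)
    tr <- simulate_trial(cfg)
    gene <- tr$truth$genes$gene_id[tr$truth$genes$class == "prognostic"]
    scr <- univariate_survival_screen(tr$expression, tr$clinical, "dfs")
    scr$p[scr$gene_id == gene] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate survival input is flagged, not fatal", {
  m <- toy_matrix(4, 20)
  cl <- tibble::tibble(sample_id = colnames(m), arm = rep(c("IO", "Obs"), 10),
                       dfs_time = rep(5, 20), dfs_event = rep(1L, 20))
  scr <- univariate_survival_screen(m, cl, "dfs")
  expect_true(all(!scr$converged))
  expect_true(all(scr$p == 1))
})

test_that("screen errors without events and on unknown samples", {
  m <- toy_matrix(3, 10)
  cl <- tibble::tibble(sample_id = colnames(m), arm = rep(c("IO", "Obs"), 5),
                       dfs_time = 1:10, dfs_event = rep(0L, 10))
  expect_error(univariate_survival_screen(m, cl, "dfs"), "DFS events")
  expect_error(univariate_survival_screen(m, cl[1:5, ], "dfs", samples = colnames(m)),
               "present in both")
})

test_that("constructed interaction toy selects the IO arm as protective", {
  # IO arm: high expression -> late events, low -> early; Obs arm: no signal
  ids <- sprintf("s%02d", 1:12)
  expr <- matrix(rep(c(10, 10, 10, 0, 0, 0, 10, 10, 10, 0, 0, 0), each = 1),
                 nrow = 1, dimnames = list("gene1", ids))
  cl <- tibble::tibble(
    sample_id = ids,
    arm = rep(c("IO", "Obs"), each = 6),
    dfs_time = c(10, 11, 12, 1, 2, 3, 5, 6, 7, 5.5, 6.5, 7.5),
    dfs_event = rep(1L, 12)
  )
  rec <- interaction_screen(expr, cl, training_ids = ids)
  expect_identical(rec$interaction_arm, "IO")
  expect_identical(rec$direction, "protective")
  expect_lt(rec$hr_io, 1)

  # oracle: exhaustive permutation of the 6 IO labels confirms the IO-arm
  # split is the most extreme labelling of its log-rank statistic
  io <- cl[cl$arm == "IO", ]
  stat_for <- function(high) {
    sd <- survival::survdiff(survival::Surv(io$dfs_time, io$dfs_event) ~ high)
    sd$chisq
  }
  observed <- stat_for(expr[1, 1:6] > mean(expr[1, 1:6]))
  perms <- utils::combn(6, 3)
  stats <- apply(perms, 2, function(ii) stat_for(seq_len(6) %in% ii))
  expect_equal(max(stats), observed, tolerance = 1e-10)
})

test_that("a gene with identical curves in both arms is not selected", {
  tr <- small_trial(seed = 19)
  nulls <- tr$truth$genes$gene_id[tr$truth$genes$class == "null"]
  rec <- interaction_screen(tr$expression, tr$clinical, gene_ids = nulls[1:30],
                            training_ids = tr$clinical$sample_id)
  # most null genes must land in 'none'; a few level-alpha flukes are expected
  expect_gt(mean(rec$interaction_arm == "none"), 0.75)
})

test_that("untestable dichotomization yields interaction_arm none", {
  ids <- sprintf("s%02d", 1:8)
  # constant within IO: every IO sample sits on one side of the global mean
  expr <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4), nrow = 1,
                 dimnames = list("g1", ids))
  cl <- tibble::tibble(sample_id = ids, arm = rep(c("IO", "Obs"), each = 4),
                       dfs_time = 1:8, dfs_event = rep(1L, 8))
  rec <- interaction_screen(expr, cl, training_ids = ids)
  expect_false(rec$testable)
  expect_identical(rec$interaction_arm, "none")
})

test_that("marker selection partitions survivors at the HR = 1 boundary", {
  records <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    interaction_arm = c("IO", "IO", "Obs", "none", "both"),
    hr_io = c(0.4, 2.0, 1.3, 0.5, 3.0),
    hr_obs = c(1.1, 0.9, 0.6, 0.4, 2.5),
    direction = NA_character_
  )
  mk <- select_marker_genes(records)
  expect_setequal(protective_genes(mk), c("g1", "g3"))
  expect_setequal(risk_genes(mk), "g2")
  expect_length(intersect(protective_genes(mk), risk_genes(mk)), 0)
  expect_setequal(mk$gene_id, c("g1", "g2", "g3"))
})

test_that("empty selection warns and HR exactly 1 goes to risk with warning", {
  none <- tibble::tibble(gene_id = "g1", interaction_arm = "none",
                         hr_io = 0.5, hr_obs = 0.5, direction = NA_character_)
  expect_warning(mk <- select_marker_genes(none), "empty marker")
  expect_identical(nrow(mk), 0L)

  boundary <- tibble::tibble(gene_id = "g1", interaction_arm = "IO",
                             hr_io = 1.0, hr_obs = 0.5, direction = NA_character_)
  expect_warning(mk2 <- select_marker_genes(boundary), "risk partition")
  expect_identical(mk2$direction, "risk")
})

test_that("screen cascade only shrinks the gene set", {
  tr <- small_trial(seed = 23)
  sp <- split_cohort(tr$clinical$sample_id, 0.65, seed = 24,
                     strata = paste(tr$clinical$arm, tr$clinical$dfs_event))
  mf <- mad_filter(tr$expression)
  scr <- dual_endpoint_screen(mf$expression, tr$clinical, samples = sp$training_ids)
  passed <- scr$gene_id[scr$passed]
  rec <- interaction_screen(mf$expression, tr$clinical, gene_ids = passed,
                            training_ids = sp$training_ids)
  mk <- suppressWarnings(select_marker_genes(rec))
  expect_lte(nrow(mf$expression), nrow(tr$expression))
  expect_lte(length(passed), nrow(mf$expression))
  expect_lte(nrow(rec), length(passed))
  expect_lte(nrow(mk), nrow(rec))
  expect_true(all(mk$gene_id %in% passed))
})
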