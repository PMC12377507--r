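strong_trial <- function(seed) {
  simulate_trial(trial_config(
    n_patients = 400, n_genes_total = 60,
    n_prognostic = 0, n_predictive_protective = 4, n_predictive_risk = 4,
    beta_predictive = 1.0, seed = seed
  ))
}

planted_markers <- function(tr) {
  g <- tr$truth$genes
  tibble::tibble(
    gene_id = g$gene_id[g$class != "null"],
    interaction_arm = "IO",
    hr = ifelse(g$class[g$class != "null"] == "predictive_protective", 0.5, 2),
    direction = ifelse(g$class[g$class != "null"] == "predictive_protective",
                       "protective", "risk")
  )
}

test_that("training is seed-deterministic and scoring is pure", {
  tr <- strong_trial(1)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  m1 <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 200, seed = 5)
  m2 <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 200, seed = 5)
  s1 <- uai_score(m1, tr$expression)
  s2 <- uai_score(m2, tr$expression)
  expect_identical(s1$uaiscore, s2$uaiscore)
  expect_identical(m1$training_cutoff, m2$training_cutoff)

  # duplicated sample column scores identically
  expr2 <- cbind(tr$expression, dup = tr$expression[, 1])
  colnames(expr2)[ncol(expr2)] <- "dup"
  s3 <- uai_score(m1, expr2)
  expect_equal(s3$uaiscore[s3$sample_id == "dup"],
               s3$uaiscore[s3$sample_id == colnames(tr$expression)[1]])
})

test_that("training-set median split yields balanced groups", {
  tr <- strong_trial(2)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  model <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 300, seed = 3)
  sc <- uai_score(model, tr$expression, samples = ids)
  expect_lte(abs(sum(sc$group == "high") - sum(sc$group == "low")), 1)
  expect_true(all((sc$uaiscore > model$training_cutoff) == (sc$group == "high")))
})

test_that("scores track disease-free survival in the treatment arm", {
  tr <- strong_trial(3)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  model <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 500, seed = 7)
  sc <- uai_score(model, tr$expression)
  d <- dplyr::left_join(sc, tr$clinical, by = "sample_id") |>
    dplyr::filter(arm == "IO")
  cidx <- survival::concordance(
    survival::Surv(dfs_time, dfs_event) ~ uaiscore, data = d, reverse = FALSE
  )$concordance
  # higher score = better outcome => concordance of score with time > 0.5
  expect_gte(cidx, 0.7)
  # orientation: score correlates positively with the latent benefit signal
  bt <- dplyr::left_join(sc, tr$truth$samples, by = "sample_id")
  expect_gt(cor(bt$uaiscore, bt$latent_benefit, method = "spearman"), 0)
})

test_that("permuting survival before training gives chance-level OOB concordance", {
  tr <- strong_trial(4)
  mk <- planted_markers(tr)
  cl <- tr$clinical
  perm <- withr::with_seed(99, sample(nrow(cl)))
  cl$dfs_time <- cl$dfs_time[perm]
  cl$dfs_event <- cl$dfs_event[perm]
  model <- train_uaiscore(tr$expression, cl, mk, cl$sample_id,
                          n_trees = 500, seed = 11)
  oob_c <- 1 - model$oob_error
  expect_gte(oob_c, 0.45)
  expect_lte(oob_c, 0.55)
})

test_that("non-marker genes cannot influence the score", {
  tr <- strong_trial(5)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  model <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 200, seed = 2)
  expr_shift <- tr$expression
  nulls <- setdiff(rownames(expr_shift), mk$gene_id)
  expr_shift[nulls, ] <- expr_shift[nulls, ] + 100
  expect_identical(uai_score(model, tr$expression)$uaiscore,
                   uai_score(model, expr_shift)$uaiscore)
})

test_that("training refuses bad inputs and missing markers are named", {
  tr <- strong_trial(6)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  expect_error(train_uaiscore(tr$expression, tr$clinical, character(0), ids),
               "empty marker")
  expect_error(train_uaiscore(tr$expression, tr$clinical, "not_a_gene", ids),
               "not_a_gene")
  model <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 100, seed = 1)
  expect_error(uai_score(model, tr$expression[-1, , drop = FALSE]),
               mk$gene_id[1])
  expect_warning(
    train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 50,
                   landmark_time = 1e6, seed = 1),
    "clipped"
  )
})

test_that("four-group labels cross-classify score and arm", {
  tr <- strong_trial(7)
  mk <- planted_markers(tr)
  ids <- tr$clinical$sample_id
  model <- train_uaiscore(tr$expression, tr$clinical, mk, ids, n_trees = 200, seed = 4)
  sc <- uai_score(model, tr$expression)
  fg <- four_group_labels(sc, tr$clinical)
  counts <- attr(fg, "counts")
  expect_identical(sum(counts), nrow(tr$clinical))
  expect_true(all(counts > 0))
  expect_setequal(levels(fg$label), c("high+IO", "high+Obs", "low+IO", "low+Obs"))

  io_only <- tr$clinical[tr$clinical$arm == "IO", ]
  fg_io <- four_group_labels(sc[sc$sample_id %in% io_only$sample_id, ], io_only)
  expect_setequal(as.character(unique(fg_io$label)), c("high+IO", "low+IO"))
  expect_error(four_group_labels(sc[-1, ], tr$clinical), "same samples")
})

test_that("tidy and glance summarize a fitted model", {
  tr <- strong_trial(8)
  mk <- planted_markers(tr)
  model <- train_uaiscore(tr$expression, tr$clinical, mk,
                          tr$clinical$sample_id, n_trees = 100, seed = 9)
  td <- tidy(model)
  expect_setequal(td$gene_id, mk$gene_id)
  gl <- glance(model)
  expect_identical(gl$n_markers, nrow(mk))
  expect_equal(gl$oob_concordance, 1 - model$oob_error)
})
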