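#' Read and write expression matrices and clinical tables
#'
#' The expression dialect is tab-separated with genes as rows: first column
#' `gene_id`, remaining columns one per sample. The clinical dialect is
#' comma-separated with columns `sample_id`, `arm` (`IO`/`Obs`,
#' case-insensitive; `atezolizumab`/`observation` also accepted), `dfs_time`,
#' `dfs_event`, `os_time`, `os_event` and optional tri-state biomarkers
#' `ctdna_c1d1`, `ctdna_c3d1`, `ttmb` (`pos`/`neg`/missing) and `pdl1`
#' (`IC23`/`IC01`/missing). Write-then-read round-trips are lossless for
#' finite values.
#'
#' @param path File path.
#' @return `read_expression()`: a numeric genes x samples matrix.
#'   `read_clinical()`: a tibble in the package's clinical layout.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_expression <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(d)[1] != "gene_id") abort("expression file must start with a gene_id column")
  genes <- d$gene_id
  if (anyDuplicated(genes)) abort("duplicate gene_id in expression file")
  m <- as.matrix(d[, -1])
  if (!is.numeric(m)) abort("non-numeric expression values")
  rownames(m) <- genes
  assert_expression_matrix(m)
  m
}

#' @rdname trial_io
#' @param expr Genes x samples matrix.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  d <- dplyr::bind_cols(tibble(gene_id = rownames(expr)), as_tibble(expr))
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_clinical <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "arm", "dfs_time", "dfs_event")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort(paste0("clinical file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(d$sample_id)) abort("duplicate sample_id in clinical file")
  arm <- tolower(trimws(as.character(d$arm)))
  arm_map <- c(io = "IO", immunotherapy = "IO", atezolizumab = "IO",
               obs = "Obs", observation = "Obs", control = "Obs")
  unknown <- setdiff(unique(arm), names(arm_map))
  if (length(unknown)) {
    abort(paste0("unknown arm label(s): ", paste(unknown, collapse = ", ")))
  }
  d$arm <- unname(arm_map[arm])
  for (col in c("dfs_time", "dfs_event", "os_time", "os_event")) {
    if (col %in% names(d) && !is.numeric(d[[col]])) {
      abort(paste0("column ", col, " must be numeric"))
    }
  }
  if (all(c("os_time", "dfs_time") %in% names(d))) {
    bad <- which(d$os_time < d$dfs_time)
    if (length(bad)) {
      warn(sprintf("os_time < dfs_time for %d sample(s) (e.g. row %d)",
                   length(bad), bad[1]))
    }
  }
  as_tibble(d)
}

#' @rdname trial_io
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, progress = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(trial$expression, file.path(dir, "expression.tsv"))
  write_clinical(trial$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(trial$truth$genes, file.path(dir, "truth_genes.csv"), progress = FALSE)
  readr::write_csv(trial$truth$samples, file.path(dir, "truth_samples.csv"), progress = FALSE)
  invisible(dir)
}
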