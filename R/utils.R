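# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Deterministic fan-out of one global seed into per-stage seeds. Offsets are
# fixed so each stage is independently rerunnable; result stays below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, split = 23L, screen = 37L, train = 53L,
               score = 71L, evaluate = 89L, bootstrap = 101L)
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

assert_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(paste0("`", arg, "` must be a numeric genes x samples matrix"))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort(paste0("`", arg, "` must have gene rownames and sample colnames"))
  }
  if (anyDuplicated(rownames(expr))) abort("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr))) abort("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(expr))) abort("expression matrix contains non-finite values")
  invisible(expr)
}

assert_clinical <- function(clinical, require_os = FALSE) {
  need <- c("sample_id", "arm", "dfs_time", "dfs_event")
  if (require_os) need <- c(need, "os_time", "os_event")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols)) {
    abort(paste0("clinical table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) abort("duplicate sample_id in clinical table")
  if (!all(clinical$arm %in% c("IO", "Obs"))) {
    abort("arm labels must be 'IO' or 'Obs' (see read_clinical() for case-folding)")
  }
  invisible(clinical)
}

# Standardize rows of a genes x samples matrix; constant rows are flagged.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  ok <- is.finite(sdv) & sdv > 0
  z <- (x - mu) / ifelse(ok, sdv, 1)
  list(z = z, constant = !ok)
}
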