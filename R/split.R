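#' Split samples into training and validation cohorts
#'
#' Seed-deterministic random partition of sample identifiers into a training
#' and a validation cohort. When `strata` is supplied (typically treatment
#' arm crossed with event status), the split is performed within each stratum,
#' rounding the per-stratum training size to `round(n_stratum * ratio)`, so the
#' realized training fraction stays within one sample of `ratio` in every
#' stratum. A stratum with fewer than two samples is assigned wholly to
#' training with a warning.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param ratio Training fraction in (0, 1). The default 0.65 mirrors the
#'   common 6.5:3.5 discovery/validation design.
#' @param seed Integer seed.
#' @param strata Optional vector of stratum labels, one per sample.
#' @return A list of class `cohort_split` with `training_ids`,
#'   `validation_ids`, `ratio`, `seed`.
#' @export
#' @examples
#' split_cohort(paste0("s", 1:100), ratio = 0.65, seed = 7)
split_cohort <- function(sample_ids, ratio = 0.65, seed = 1L, strata = NULL) {
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")
  if (ratio <= 0 || ratio >= 1) abort("ratio must be in (0, 1)")
  if (!is.null(strata) && length(strata) != length(sample_ids)) {
    abort("strata must label every sample")
  }
  if (is.null(strata)) strata <- rep("all", length(sample_ids))

  training <- with_seed(as.integer(seed), {
    unlist(lapply(split(sample_ids, strata), function(ids) {
      if (length(ids) < 2) {
        warn(paste0("stratum with ", length(ids),
                    " sample(s) assigned wholly to training"))
        return(ids)
      }
      n_train <- round(length(ids) * ratio)
      n_train <- min(max(n_train, 1L), length(ids) - 1L)
      sample(ids, n_train)
    }), use.names = FALSE)
  })

  structure(
    list(training_ids = sample_ids[sample_ids %in% training],
         validation_ids = sample_ids[!sample_ids %in% training],
         ratio = ratio, seed = as.integer(seed)),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split>", length(x$training_ids), "training /",
      length(x$validation_ids), "validation (ratio", x$ratio, ")\n")
  invisible(x)
}

#' @export
as_tibble.cohort_split <- function(x, ...) {
  tibble(sample_id = c(x$training_ids, x$validation_ids),
         cohort = rep(c("training", "validation"),
                      c(length(x$training_ids), length(x$validation_ids))))
}
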