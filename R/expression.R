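#' Read a proteins-by-samples abundance matrix
#'
#' Expression tables are wide tibbles: a `protein` identifier column followed
#' by one numeric column per sample. The replicate structure lives in a
#' separate design tibble (`sample_id`, `condition`, `replicate`), read with
#' [read_sample_design()].
#'
#' @param path TSV file; first column protein ids, header row sample ids.
#' @param log2_transform If `TRUE`, non-positive values become missing and the
#'   rest are log2-transformed (raw intensity input); otherwise values are
#'   taken as already log-scale (or as log-ratios).
#' @return A wide expression tibble.
#' @export
read_expr_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  names(x)[1] <- "protein"
  m <- em_matrix(x)
  if (log2_transform) {
    m[!is.na(m) & m <= 0] <- NA_real_
    m <- log2(m)
  }
  em_tibble(m)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `condition`, `replicate`.
#' @return A design tibble.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  required <- c("sample_id", "condition", "replicate")
  if (!all(required %in% names(d))) {
    abort(paste0("design must have columns: ", paste(required, collapse = ", ")))
  }
  d <- dplyr::mutate(d,
    sample_id = as.character(.data$sample_id),
    condition = as.character(.data$condition),
    replicate = as.integer(.data$replicate)
  )
  if (anyDuplicated(d[c("condition", "replicate")])) {
    abort("design rows must be unique in (condition, replicate)")
  }
  d
}

#' Median-center each sample profile
#'
#' Subtracts, per sample, the median of its present values, so every output
#' sample has median zero. Idempotent.
#'
#' @param x Wide expression tibble.
#' @return The centered tibble.
#' @export
median_center <- function(x) {
  m <- em_matrix(x)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  em_tibble(sweep(m, 2, med))
}

#' Keep proteins replicated in every condition
#'
#' Retains proteins with at least `min_reps` present values in *every*
#' condition of the design (the "quantified in at least two out of three
#' replicates for all cell lines" style filter).
#'
#' @param x Wide expression tibble.
#' @param design Design tibble (`sample_id`, `condition`, `replicate`).
#' @param min_reps Minimum present replicates per condition. Default 2.
#' @return The filtered tibble.
#' @export
filter_by_replication <- function(x, design, min_reps = 2) {
  stopifnot(min_reps >= 1)
  design <- check_design(x, design)
  m <- em_matrix(x)
  conds <- unique(design$condition)
  ok <- rep(TRUE, nrow(m))
  for (cc in conds) {
    cols <- design$sample_id[design$condition == cc]
    ok <- ok & rowSums(!is.na(m[, cols, drop = FALSE])) >= min_reps
  }
  x[ok, , drop = FALSE]
}

#' Flag replicates that cluster away from their condition
#'
#' Computes pairwise Pearson correlation between samples over commonly present
#' proteins and flags a replicate when its nearest neighbour (highest
#' correlation among the other samples) belongs to a different condition.
#' Ties are resolved in favour of same-condition neighbours, and a condition
#' with a single replicate is never flagged. Only flags are returned; the
#' caller decides whether to exclude.
#'
#' @param x Wide expression tibble.
#' @param design Design tibble.
#' @return Character vector of flagged `sample_id`s (possibly empty).
#' @export
flag_outlier_replicates <- function(x, design) {
  design <- check_design(x, design)
  m <- em_matrix(x)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- NA_real_
  n_reps <- table(design$condition)
  flagged <- character(0)
  for (i in seq_len(ncol(m))) {
    cond_i <- design$condition[i]
    if (n_reps[[cond_i]] < 2) next
    same <- design$condition == cond_i & seq_len(ncol(m)) != i
    best_same <- suppressWarnings(max(r[i, same], na.rm = TRUE))
    best_other <- suppressWarnings(max(r[i, !same & seq_len(ncol(m)) != i],
                                       na.rm = TRUE))
    if (is.finite(best_other) &&
        (!is.finite(best_same) || best_other > best_same)) {
      flagged <- c(flagged, design$sample_id[i])
    }
  }
  flagged
}

#' Quantile-normalize sample distributions
#'
#' Forces every sample to the same distribution (the mean of order statistics
#' across samples). Missing entries keep their missingness pattern; present
#' values are ranked among present values and assigned the mean order
#' statistic interpolated at proportional rank. Idempotent after the first
#' application.
#'
#' @param x Wide expression tibble.
#' @return The normalized tibble.
#' @export
quantile_normalize <- function(x) {
  m <- em_matrix(x)
  em_tibble(limma::normalizeQuantiles(m, ties = TRUE))
}
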