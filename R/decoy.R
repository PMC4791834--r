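#' Run the member-calling pipeline on one matrix and resource
#'
#' Convenience chain used by the decoy benchmark and the end-to-end pipeline:
#' restrict the resource to quantified proteins, complex-wise normalize, fit
#' condition contrasts, moderate, and call variable members and complexes.
#'
#' @param x Median-centered wide expression tibble.
#' @param design Design tibble.
#' @param resource A [complex_resource()].
#' @param trim_fraction,member_alpha,complex_threshold,min_members Pipeline
#'   thresholds (see the stage functions).
#' @return A [call_variable()] result.
#' @export
run_member_pipeline <- function(x, design, resource, trim_fraction = 0.2,
                                member_alpha = 0.05, complex_threshold = 0.20,
                                min_members = 5) {
  res_q <- restrict_to_quantified(resource, x$protein, min_members)
  if (nrow(res_q) == 0) abort("no complex has enough quantified members")
  corrected <- normalize_complexwise(x, design, res_q, trim_fraction)
  fit <- fit_condition_contrasts(corrected, design)
  mod <- ebayes_moderate(fit)
  call_variable(mod, res_q, member_alpha, complex_threshold)
}

#' Decoy benchmark of variable-member calls
#'
#' Runs the full calling pipeline on nested, increasing condition subsets,
#' once with the real complex resource and `n_seeds` times with
#' size-preserving decoy resources ([generate_decoys()]). With real
#' complexes the number of variable members should saturate as conditions
#' accumulate, while decoys — whose members share no true co-regulation, so
#' complex-wise normalization cannot cancel shared abundance — provide the
#' null behaviour.
#'
#' @param x Median-centered wide expression tibble.
#' @param design Design tibble.
#' @param resource A [complex_resource()].
#' @param condition_subsets List of character vectors of condition names,
#'   nested and increasing; `NULL` uses cumulative prefixes of sizes
#'   `4, 8, ...` up to all conditions.
#' @param n_seeds Number of decoy resources per subset. Default 20.
#' @param seed Base seed for decoy generation. Default 1.
#' @param ... Passed to [run_member_pipeline()].
#' @return A tibble with one row per subset: `n_conditions`,
#'   `real_variable_count`, `decoy_mean`, `decoy_sd`, plus a list column
#'   `decoy_counts`.
#' @export
decoy_benchmark <- function(x, design, resource, condition_subsets = NULL,
                            n_seeds = 20, seed = 1, ...) {
  design <- check_design(x, design)
  conds <- unique(design$condition)
  if (is.null(condition_subsets)) {
    sizes <- unique(c(seq(4, length(conds), by = 4), length(conds)))
    sizes <- sizes[sizes >= 2]
    condition_subsets <- lapply(sizes, function(s) conds[seq_len(s)])
  }
  n_prev <- 0
  for (cs in condition_subsets) {
    if (length(cs) <= n_prev) abort("condition_subsets must be increasing")
    n_prev <- length(cs)
  }
  count_variable <- function(res) {
    purrr::possibly(function() {
      calls <- run_member_pipeline(x_sub(cs), design_sub(cs), res, ...)
      sum(calls$proteins$is_variable)
    }, otherwise = NA_integer_)()
  }
  design_sub <- function(cs) design[design$condition %in% cs, , drop = FALSE]
  x_sub <- function(cs) x[, c("protein", design_sub(cs)$sample_id)]
  rows <- vector("list", length(condition_subsets))
  for (i in seq_along(condition_subsets)) {
    cs <- condition_subsets[[i]]
    real_n <- count_variable(resource)
    decoy_n <- vapply(seq_len(n_seeds), function(s) {
      count_variable(generate_decoys(resource, seed = seed + s - 1L))
    }, integer(1))
    rows[[i]] <- tibble(
      n_conditions = length(cs),
      real_variable_count = real_n,
      decoy_mean = mean(decoy_n, na.rm = TRUE),
      decoy_sd = stats::sd(decoy_n, na.rm = TRUE),
      decoy_counts = list(decoy_n)
    )
  }
  dplyr::bind_rows(rows)
}
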