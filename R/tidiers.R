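#' Tidy a moderated-fit object
#'
#' @param x An [ebayes_moderate()] result.
#' @param ... Unused.
#' @return Tibble of per-(protein, condition) statistics.
#' @export
tidy.ebayes_fit <- function(x, ...) x$table

#' One-row summary of a moderated fit
#'
#' @param x An [ebayes_moderate()] result.
#' @param ... Unused.
#' @return Tibble with `d0`, `s0_sq`, protein and test counts.
#' @export
glance.ebayes_fit <- function(x, ...) {
  tibble(
    d0 = x$d0, s0_sq = x$s0_sq,
    n_proteins = nrow(x$variances),
    n_tests = nrow(x$table),
    n_conditions = length(x$conditions)
  )
}

#' Tidy member calls
#'
#' @param x A [call_variable()] result.
#' @param ... Unused.
#' @return Per-(protein, condition) call tibble joined with the per-protein
#'   variable flag.
#' @export
tidy.member_calls <- function(x, ...) {
  dplyr::left_join(x$conditions, x$proteins, by = "protein")
}

#' One-row summary of member calls
#'
#' @param x A [call_variable()] result.
#' @param ... Unused.
#' @return Tibble of member/complex counts at the thresholds used.
#' @export
glance.member_calls <- function(x, ...) {
  tibble(
    n_members = nrow(x$proteins),
    n_variable_members = sum(x$proteins$is_variable),
    n_complexes = nrow(x$complexes),
    n_variable_complexes = sum(x$complexes$verdict == "variable"),
    member_alpha = x$member_alpha,
    complex_threshold = x$complex_threshold
  )
}

#' Tidy a signature evaluation
#'
#' @param x A [feature_sampling_eval()] result.
#' @param ... Unused.
#' @return Per-size summary tibble (means, standard errors, Wilcoxon test).
#' @export
tidy.signature_eval <- function(x, ...) x$summary

#' One-row summary of a signature evaluation
#'
#' @param x A [feature_sampling_eval()] result.
#' @param ... Unused.
#' @return Tibble with the best signature accuracy and overall comparison.
#' @export
glance.signature_eval <- function(x, ...) {
  tibble(
    n_sizes = nrow(x$summary),
    n_samples = x$n_samples,
    max_signature_accuracy = max(x$summary$mean_accuracy_signature),
    all_sizes_signature_above_random =
      all(x$summary$mean_accuracy_signature > x$summary$mean_accuracy_random)
  )
}
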