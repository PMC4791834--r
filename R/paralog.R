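#' Co-regulated paralog pairs
#'
#' A paralog pair is reported for every condition where *both* members are
#' significant (adjusted p below `alpha`). Pairs referencing proteins absent
#' from the calls are skipped with a warning. Pairs are stored canonically
#' (lexicographic member order).
#'
#' @param calls A [call_variable()] result (or its `conditions` tibble with
#'   `protein`, `condition`, `log2fc`, `p_adj`).
#' @param pairs Tibble with columns `protein_a`, `protein_b` and optionally
#'   `family_id`.
#' @param alpha Adjusted-p threshold for co-regulation. Default 0.05.
#' @return A tibble with one row per (pair, condition):
#'   `protein_a`, `protein_b`, `family_id`, `condition`, `fc_a`, `fc_b`.
#' @export
find_coregulated_pairs <- function(calls, pairs, alpha = 0.05) {
  tab <- if (inherits(calls, "member_calls")) calls$conditions else calls
  if (!"family_id" %in% names(pairs)) pairs$family_id <- NA_character_
  pairs <- dplyr::mutate(pairs,
    a = pmin(as.character(.data$protein_a), as.character(.data$protein_b)),
    b = pmax(as.character(.data$protein_a), as.character(.data$protein_b))
  )
  if (any(pairs$a == pairs$b)) abort("paralog pairs must have distinct members")
  known <- unique(tab$protein)
  missing_pair <- !(pairs$a %in% known) | !(pairs$b %in% known)
  if (any(missing_pair)) {
    warn(paste0(sum(missing_pair),
                " paralog pair(s) reference proteins absent from the calls; skipped"))
    pairs <- pairs[!missing_pair, , drop = FALSE]
  }
  sig <- tab[!is.na(tab$p_adj) & tab$p_adj < alpha,
             c("protein", "condition", "log2fc")]
  a_sig <- dplyr::inner_join(
    pairs[c("a", "b", "family_id")],
    dplyr::rename(sig, a = "protein", fc_a = "log2fc"),
    by = "a", relationship = "many-to-many"
  )
  both <- dplyr::inner_join(
    a_sig,
    dplyr::rename(sig, b = "protein", fc_b = "log2fc"),
    by = c("b", "condition"), relationship = "many-to-many"
  )
  tibble(
    protein_a = both$a, protein_b = both$b, family_id = both$family_id,
    condition = both$condition, fc_a = both$fc_a, fc_b = both$fc_b
  )
}

#' Classify paralog switches
#'
#' A co-regulated pair at a condition is a *switch* when the two members'
#' log2 fold changes have opposite signs (one subunit replacing the other in
#' the complex); otherwise, including when either fold change is exactly
#' zero, it is *co-directional*. Each co-significant condition is classified
#' independently; the per-pair roll-up labels a pair `switch` if any of its
#' conditions is a switch.
#'
#' @param coregulated A [find_coregulated_pairs()] result.
#' @return A list with `conditions` (the input plus a `direction` column) and
#'   `pairs` (per-pair roll-up with `direction`).
#' @export
classify_switches <- function(coregulated) {
  cr <- coregulated
  cr$direction <- ifelse(sign(cr$fc_a) * sign(cr$fc_b) == -1,
                         "switch", "co_directional")
  pairs <- cr %>%
    dplyr::group_by(.data$protein_a, .data$protein_b, .data$family_id) %>%
    dplyr::summarise(
      direction = ifelse(any(.data$direction == "switch"),
                         "switch", "co_directional"),
      n_conditions = dplyr::n(),
      .groups = "drop"
    )
  list(conditions = cr, pairs = pairs)
}

#' Enrichment of paralogs among variable members
#'
#' Fisher's exact test of the association between being a paralog and being a
#' variable complex member, over the universe of all quantified members.
#'
#' @param variable_members Character vector of variable member ids.
#' @param all_members Universe: all quantified complex members.
#' @param paralog_members Character vector of members that are paralogs.
#' @return A one-row tibble from [fisher_overlap()].
#' @export
paralog_enrichment <- function(variable_members, all_members, paralog_members) {
  if (length(paralog_members) == 0) {
    abort("paralog_members is empty: the 2x2 table is undefined")
  }
  fisher_overlap(intersect(variable_members, all_members),
                 intersect(paralog_members, all_members),
                 all_members)
}
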