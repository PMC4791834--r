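#' Select one probe set per gene by maximal variance
#'
#' Microarray genes are often represented by several probe sets; to avoid
#' bias toward such genes only the probe set with the highest variance across
#' samples is retained (ties broken lexicographically by probe id).
#'
#' @param probe_table Tibble with columns `probe`, `gene` and one numeric
#'   column per sample.
#' @return The filtered tibble, one row per gene.
#' @export
select_probesets <- function(probe_table) {
  stopifnot(all(c("probe", "gene") %in% names(probe_table)))
  value_cols <- setdiff(names(probe_table), c("probe", "gene"))
  v <- apply(as.matrix(probe_table[value_cols]), 1, stats::var, na.rm = TRUE)
  probe_table %>%
    dplyr::mutate(.var = v) %>%
    dplyr::arrange(.data$gene, dplyr::desc(.data$.var), .data$probe) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".var")
}

#' Classify variable members as transcriptionally regulated
#'
#' For every variable (protein, condition) call, the matched mRNA change at
#' the same condition decides the class:
#' * `transcriptional_true` — mRNA significant (`p_adj < alpha`), above the
#'   fold-change floor (`|log2fc| > fc_floor`) and of the same sign as the
#'   protein change;
#' * `transcriptional_trend` — same sign and above the floor, but not
#'   significant (`p_adj >= alpha`);
#' * `not_transcriptional` — otherwise.
#' Proteins without a gene mapping, or conditions without mRNA data, are
#' returned as `unclassifiable` rather than forced into a class.
#'
#' @param calls A [call_variable()] result (or its `conditions` tibble).
#' @param mrna Tibble of mRNA changes: `gene`, `condition`, `log2fc`, `p_adj`.
#' @param mapping Two-column tibble mapping `protein` to `gene`.
#' @param fc_floor Minimum absolute mRNA log2 fold change. Default 0.5.
#' @param alpha mRNA significance threshold. Default 0.05.
#' @return A tibble with one row per variable (protein, condition):
#'   `protein`, `gene`, `condition`, `protein_fc`, `mrna_fc`, `mrna_p_adj`,
#'   `class`.
#' @export
classify_regulation <- function(calls, mrna, mapping, fc_floor = 0.5,
                                alpha = 0.05) {
  tab <- if (inherits(calls, "member_calls")) calls$conditions else calls
  variant <- tab[tab$is_variable_at_condition %in% TRUE,
                 c("protein", "condition", "log2fc")]
  names(mapping)[1:2] <- c("protein", "gene")
  out <- variant %>%
    dplyr::rename(protein_fc = "log2fc") %>%
    dplyr::left_join(mapping[c("protein", "gene")], by = "protein") %>%
    dplyr::left_join(
      dplyr::rename(mrna, mrna_fc = "log2fc", mrna_p_adj = "p_adj"),
      by = c("gene", "condition")
    )
  consistent <- !is.na(out$mrna_fc) &
    abs(out$mrna_fc) > fc_floor &
    sign(out$mrna_fc) == sign(out$protein_fc) &
    sign(out$protein_fc) != 0
  out$class <- dplyr::case_when(
    is.na(out$gene) | is.na(out$mrna_fc) ~ "unclassifiable",
    consistent & out$mrna_p_adj < alpha ~ "transcriptional_true",
    consistent ~ "transcriptional_trend",
    TRUE ~ "not_transcriptional"
  )
  out
}

#' Link transcriptional calls to candidate miRNA regulation
#'
#' A call is miRNA-linked when some miRNA targeting the gene is itself
#' significantly regulated (`p_adj < mirna_alpha`) at the same condition with
#' a fold change of sign *opposite* to the mRNA change (the repressive
#' anti-correlation expected of miRNA regulation). Only transcriptional
#' classes can be linked.
#'
#' @param regulation A [classify_regulation()] result.
#' @param mirna_changes Tibble: `mirna`, `condition`, `log2fc`, `p_adj`.
#' @param targets Tibble: `mirna`, `gene`.
#' @param mirna_alpha miRNA significance threshold. Default 0.01.
#' @return `regulation` with a logical `mirna_linked` column added.
#' @export
link_mirna <- function(regulation, mirna_changes, targets, mirna_alpha = 0.01) {
  sig <- mirna_changes[!is.na(mirna_changes$p_adj) &
                         mirna_changes$p_adj < mirna_alpha, ]
  cand <- dplyr::inner_join(sig, targets, by = "mirna",
                            relationship = "many-to-many")
  out <- regulation
  transcriptional <- out$class %in% c("transcriptional_true",
                                      "transcriptional_trend")
  linked_rows <- integer(0)
  if (nrow(cand) > 0 && any(transcriptional)) {
    probe <- out[transcriptional, c("gene", "condition", "mrna_fc")]
    probe$.row <- which(transcriptional)
    j <- dplyr::inner_join(probe, cand, by = c("gene", "condition"),
                           relationship = "many-to-many")
    linked_rows <- unique(j$.row[sign(j$log2fc) * sign(j$mrna_fc) == -1])
  }
  out$mirna_linked <- seq_len(nrow(out)) %in% linked_rows
  out
}
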