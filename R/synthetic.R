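# Synthetic data with planted, exported ground truth. The generators emulate
# the study conditions of the real inputs (replicate-structured log2
# abundance matrices with co-regulated complex members, a planted fraction of
# variable members, paralog switches, matched transcript/miRNA tables and a
# two-group tissue cohort) so that every pipeline stage has a
# parameter-recovery test that needs no external download.

#' Generate a random complex resource
#'
#' Complex sizes are drawn uniformly in `size_range`; a stated fraction of
#' the proteins used is assigned to two complexes (never twice to the same
#' complex), the rest to exactly one.
#'
#' @param n_complexes Number of complexes.
#' @param n_proteins Size of the protein identifier pool (an upper bound on
#'   distinct members; leftover identifiers become non-member background
#'   proteins in [generate_proteome()]).
#' @param size_range Inclusive integer range of complex sizes. Default
#'   `c(5, 30)`.
#' @param multi_membership_rate Fraction of member proteins belonging to two
#'   complexes. Default 0.1.
#' @param seed Integer seed.
#' @return A list: `resource` (a [complex_resource()]) and `truth` (tibble
#'   `protein`, `n_complexes`).
#' @export
generate_resource <- function(n_complexes, n_proteins, size_range = c(5, 30),
                              multi_membership_rate = 0.1, seed = 1) {
  stopifnot(size_range[1] >= 2, size_range[2] >= size_range[1])
  with_seed(seed, {
    sizes <- size_range[1] - 1L +
      sample.int(size_range[2] - size_range[1] + 1L, n_complexes,
                 replace = TRUE)
    slots <- sum(sizes)
    n_unique <- min(n_proteins, round(slots / (1 + multi_membership_rate)))
    n_multi <- slots - n_unique
    if (n_multi > n_unique) {
      abort("protein pool too small: some protein would need >2 memberships")
    }
    ids <- sprintf("P%05d", seq_len(n_proteins))
    uniq <- sample(ids, n_unique)
    assignment <- sample(c(uniq, if (n_multi > 0) sample(uniq, n_multi)))
    idx_complex <- rep(seq_len(n_complexes), sizes)
    # repair within-complex duplicates by random swaps (size/multiset kept)
    for (iter in seq_len(100L * slots)) {
      dup_pos <- which(stats::ave(seq_len(slots), idx_complex, assignment,
                                  FUN = seq_along) > 1)
      if (length(dup_pos) == 0) break
      for (p in dup_pos) {
        q <- sample.int(slots, 1)
        tmp <- assignment[p]; assignment[p] <- assignment[q]; assignment[q] <- tmp
      }
    }
    resource <- complex_resource(
      complex_id = sprintf("CPX%03d", seq_len(n_complexes)),
      name = sprintf("synthetic complex %d", seq_len(n_complexes)),
      source = "user",
      members = unname(split(assignment, idx_complex))
    )
    counts <- table(assignment)
    truth <- tibble(
      protein = ids,
      n_complexes = as.integer(ifelse(ids %in% names(counts),
                                      counts[ids], 0L))
    )
    list(resource = resource, truth = truth)
  })
}

#' Generate a replicate-structured proteome with planted variable members
#'
#' Each log2 abundance entry is the sum of a protein baseline, a shared
#' per-(complex, sample) abundance term (inducing within-complex
#' correlation; for proteins in two complexes the mean of both terms), a
#' planted member effect (for variable members, at their affected condition,
#' with random sign), and Gaussian noise. Effects are planted on the member,
#' not the complex, so complex-wise normalization must recover them.
#'
#' @param resource A [complex_resource()] (e.g. from [generate_resource()]).
#' @param n_conditions,n_replicates Design dimensions. Defaults 16 and 3.
#' @param variable_fraction Fraction of member proteins planted as variable.
#'   Default 0.22.
#' @param effect_size Absolute planted log2 effect. Default 1.
#' @param complex_abundance_sd SD of the shared per-(complex, sample)
#'   abundance term. Default 1.
#' @param noise_sd SD of the i.i.d. measurement noise. Default 0.25.
#' @param missing_rate Completely-at-random missingness rate. Default 0.
#' @param n_background Non-member background proteins appended to the
#'   matrix. Default 0.
#' @param seed Integer seed.
#' @return A list: `x` (wide tibble), `design`, `truth` (tibble `protein`,
#'   `is_member`, `is_variable`, `condition`, `true_effect`), `resource`, and
#'   `params`.
#' @export
generate_proteome <- function(resource, n_conditions = 16, n_replicates = 3,
                              variable_fraction = 0.22, effect_size = 1,
                              complex_abundance_sd = 1, noise_sd = 0.25,
                              missing_rate = 0, n_background = 0, seed = 1) {
  members <- unique(unlist(resource$members, use.names = FALSE))
  with_seed(seed, {
    conds <- sprintf("C%02d", seq_len(n_conditions))
    design <- tidyr::expand_grid(condition = conds,
                                 replicate = seq_len(n_replicates)) %>%
      dplyr::mutate(sample_id = paste0(.data$condition, "_r", .data$replicate)) %>%
      dplyr::select("sample_id", "condition", "replicate")
    proteins <- c(members,
                  if (n_background > 0) sprintf("BG%05d", seq_len(n_background)))
    n_s <- nrow(design)
    baseline <- stats::rnorm(length(proteins), 0, 1.5)
    m <- matrix(baseline, length(proteins), n_s,
                dimnames = list(proteins, design$sample_id))
    if (complex_abundance_sd > 0) {
      tmat <- matrix(stats::rnorm(nrow(resource) * n_s, 0, complex_abundance_sd),
                     nrow(resource), n_s)
      idx <- complex_index(resource)
      krow <- match(idx$complex_id, resource$complex_id)
      shared <- rowsum(tmat[krow, , drop = FALSE], idx$protein) /
        as.vector(table(idx$protein)[sort(unique(idx$protein))])
      m[rownames(shared), ] <- m[rownames(shared), ] + shared
    }
    n_var <- round(variable_fraction * length(members))
    var_prot <- sample(members, n_var)
    var_cond <- sample(conds, n_var, replace = TRUE)
    var_sign <- sample(c(-1, 1), n_var, replace = TRUE)
    for (i in seq_len(n_var)) {
      cols <- design$sample_id[design$condition == var_cond[i]]
      m[var_prot[i], cols] <- m[var_prot[i], cols] + var_sign[i] * effect_size
    }
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    if (missing_rate > 0) {
      m[matrix(stats::runif(length(m)) < missing_rate, nrow(m))] <- NA_real_
    }
    truth <- tibble(
      protein = proteins,
      is_member = proteins %in% members,
      is_variable = proteins %in% var_prot,
      condition = NA_character_,
      true_effect = 0
    )
    truth$condition[match(var_prot, truth$protein)] <- var_cond
    truth$true_effect[match(var_prot, truth$protein)] <- var_sign * effect_size
    list(
      x = em_tibble(m), design = design, truth = truth, resource = resource,
      params = list(
        n_conditions = n_conditions, n_replicates = n_replicates,
        variable_fraction = variable_fraction, effect_size = effect_size,
        complex_abundance_sd = complex_abundance_sd, noise_sd = noise_sd,
        missing_rate = missing_rate, seed = seed
      )
    )
  })
}

#' Plant paralog pairs (switches and co-directional) into a proteome
#'
#' Selects disjoint pairs of so-far-invariant proteins sharing a complex.
#' Switch pairs receive opposite-sign effects at a shared condition;
#' co-directional pairs same-sign effects; null pairs (negative controls for
#' false-call rates) receive no effect. The proteome matrix and truth are
#' updated in the returned copy.
#'
#' @param proteome A [generate_proteome()] result.
#' @param n_pairs Number of effect-carrying pairs. Default 20.
#' @param switch_fraction Fraction of effect pairs planted as switches.
#'   Default 0.7.
#' @param n_null_pairs Number of no-effect pairs. Default `n_pairs`.
#' @param effect_size Absolute planted effect; defaults to the proteome's.
#' @param seed Integer seed.
#' @return The proteome list with updated `x` and `truth`, plus `pairs`
#'   (tibble `protein_a`, `protein_b`, `family_id`) and `pair_truth`
#'   (adds `planted` in `switch`/`co_directional`/`null` and `condition`).
#' @export
generate_paralog_switches <- function(proteome, n_pairs = 20,
                                      switch_fraction = 0.7,
                                      n_null_pairs = n_pairs,
                                      effect_size = NULL, seed = 1) {
  resource <- proteome$resource
  effect_size <- effect_size %||% proteome$params$effect_size
  with_seed(seed, {
    m <- em_matrix(proteome$x)
    truth <- proteome$truth
    design <- proteome$design
    conds <- unique(design$condition)
    free <- truth$protein[truth$is_member & !truth$is_variable]
    candidates <- dplyr::bind_rows(lapply(seq_len(nrow(resource)), function(k) {
      mem <- intersect(resource$members[[k]], free)
      if (length(mem) < 2) return(NULL)
      pr <- t(utils::combn(sort(mem), 2))
      tibble(protein_a = pr[, 1], protein_b = pr[, 2])
    }))
    candidates <- candidates[sample.int(nrow(candidates)), , drop = FALSE]
    used <- character(0)
    picked <- list()
    for (i in seq_len(nrow(candidates))) {
      if (length(picked) >= n_pairs + n_null_pairs) break
      ca <- candidates$protein_a[i]; cb <- candidates$protein_b[i]
      if (ca %in% used || cb %in% used) next
      used <- c(used, ca, cb)
      picked[[length(picked) + 1]] <- candidates[i, ]
    }
    if (length(picked) < n_pairs + n_null_pairs) {
      abort("not enough disjoint same-complex pairs of invariant proteins")
    }
    pairs <- dplyr::bind_rows(picked)
    pairs$family_id <- sprintf("FAM%03d", seq_len(nrow(pairs)))
    n_switch <- round(switch_fraction * n_pairs)
    planted <- c(rep("switch", n_switch),
                 rep("co_directional", n_pairs - n_switch),
                 rep("null", n_null_pairs))
    pair_cond <- sample(conds, nrow(pairs), replace = TRUE)
    pair_sign <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
    for (i in seq_len(nrow(pairs))) {
      if (planted[i] == "null") next
      cols <- design$sample_id[design$condition == pair_cond[i]]
      sa <- pair_sign[i]
      sb <- if (planted[i] == "switch") -sa else sa
      m[pairs$protein_a[i], cols] <- m[pairs$protein_a[i], cols] + sa * effect_size
      m[pairs$protein_b[i], cols] <- m[pairs$protein_b[i], cols] + sb * effect_size
      for (p in c(pairs$protein_a[i], pairs$protein_b[i])) {
        j <- match(p, truth$protein)
        truth$is_variable[j] <- TRUE
        truth$condition[j] <- pair_cond[i]
        truth$true_effect[j] <- effect_size *
          (if (p == pairs$protein_a[i]) sa else sb)
      }
    }
    pair_truth <- dplyr::mutate(pairs, planted = planted,
                                condition = ifelse(planted == "null",
                                                   NA_character_, pair_cond))
    out <- proteome
    out$x <- em_tibble(m)
    out$truth <- truth
    out$pairs <- pairs[c("protein_a", "protein_b", "family_id")]
    out$pair_truth <- pair_truth
    out
  })
}

#' Generate matched transcript and miRNA tables for variable members
#'
#' Each planted variable (protein, condition) is assigned a transcriptional
#' class: with probability `transcriptional_fraction` a same-sign mRNA change
#' above the fold-change floor with a small adjusted p ("TRUE"), with
#' probability `trend_fraction` the same but non-significant ("TREND"), else
#' a sub-floor mRNA change (not transcriptional). A `mirna_fraction` of the
#' transcriptional calls additionally receives a significantly regulated,
#' anti-correlated miRNA with a target-table entry. Tables are
#' noiseless-threshold inputs: values sit clearly on the intended side of
#' every threshold, so classification recovers the planted classes exactly.
#'
#' @param proteome A [generate_proteome()] result (uses its `truth`).
#' @param transcriptional_fraction,trend_fraction Class probabilities.
#'   Defaults 0.38 and 0.06.
#' @param mirna_fraction Fraction of transcriptional calls miRNA-linked.
#'   Default 0.45.
#' @param fc_floor Fold-change floor used by the classifier. Default 0.5.
#' @param seed Integer seed.
#' @return A list: `mrna`, `mirna`, `targets`, `mapping` tibbles and `truth`
#'   (per variable (protein, condition): `class`, `mirna_linked`).
#' @export
generate_transcriptome <- function(proteome, transcriptional_fraction = 0.38,
                                   trend_fraction = 0.06,
                                   mirna_fraction = 0.45, fc_floor = 0.5,
                                   seed = 1) {
  truth <- proteome$truth
  conds <- unique(proteome$design$condition)
  vars <- truth[truth$is_variable, , drop = FALSE]
  with_seed(seed, {
    mapping <- tibble(protein = truth$protein,
                      gene = paste0("g_", truth$protein))
    n <- nrow(vars)
    u <- stats::runif(n)
    class <- ifelse(u < transcriptional_fraction, "transcriptional_true",
                    ifelse(u < transcriptional_fraction + trend_fraction,
                           "transcriptional_trend", "not_transcriptional"))
    sgn <- sign(vars$true_effect)
    mrna_fc <- dplyr::case_when(
      class == "not_transcriptional" ~ sgn * fc_floor * 0.3,
      TRUE ~ sgn * (fc_floor + 0.5)
    )
    mrna_p <- ifelse(class == "transcriptional_true", 1e-3, 0.5)
    planted <- tibble(
      gene = paste0("g_", vars$protein), condition = vars$condition,
      log2fc = mrna_fc, p_adj = mrna_p
    )
    grid <- tidyr::expand_grid(gene = mapping$gene, condition = conds) %>%
      dplyr::anti_join(planted, by = c("gene", "condition")) %>%
      dplyr::mutate(log2fc = 0, p_adj = 1)
    mrna <- dplyr::bind_rows(planted, grid)
    transcriptional <- class %in% c("transcriptional_true",
                                    "transcriptional_trend")
    linked <- transcriptional & stats::runif(n) < mirna_fraction
    mirna <- tibble(mirna = character(0), condition = character(0),
                    log2fc = numeric(0), p_adj = numeric(0))
    targets <- tibble(mirna = character(0), gene = character(0))
    if (any(linked)) {
      ids <- sprintf("mir%03d", seq_len(sum(linked)))
      mirna <- tibble(
        mirna = ids, condition = vars$condition[linked],
        log2fc = -sgn[linked] * 1, p_adj = 1e-3
      )
      targets <- tibble(mirna = ids, gene = paste0("g_", vars$protein[linked]))
    }
    # inert decoy miRNA, never significant
    mirna <- dplyr::bind_rows(mirna, tibble(
      mirna = "mir_null", condition = conds[1], log2fc = 2, p_adj = 0.9
    ))
    list(
      mrna = mrna, mirna = mirna, targets = targets, mapping = mapping,
      truth = tibble(
        protein = vars$protein, condition = vars$condition,
        class = class, mirna_linked = linked
      )
    )
  })
}

#' Generate a two-group cohort with planted signature proteins
#'
#' Log2 intensities are baseline plus Gaussian noise; each signature protein
#' additionally carries a between-group mean shift of `effect` (random sign
#' per protein). Raw (linear-scale) intensities and unique-peptide counts are
#' emitted so the cohort exercises [preprocess_cohort()] end to end.
#'
#' @param n_group_a,n_group_b Samples per group. Defaults 7 and 14.
#' @param n_proteins Quantified proteins. Default 2000.
#' @param n_signature Planted signature proteins. Default 53.
#' @param effect Between-group log2 shift of signature proteins. Default
#'   0.75 (1.5 times the default noise SD).
#' @param noise_sd Log2-scale noise SD. Default 0.5.
#' @param seed Integer seed.
#' @return A list: `raw` (tibble `protein`, `unique_peptides`, samples),
#'   `groups`, `truth` (tibble `protein`, `is_signature`, `effect`).
#' @export
generate_cohort <- function(n_group_a = 7, n_group_b = 14, n_proteins = 2000,
                            n_signature = 53, effect = 0.75, noise_sd = 0.5,
                            seed = 1) {
  with_seed(seed, {
    groups <- tibble(
      sample_id = c(sprintf("N%02d", seq_len(n_group_a)),
                    sprintf("T%02d", seq_len(n_group_b))),
      group = rep(c("normal", "cancer"), c(n_group_a, n_group_b))
    )
    proteins <- sprintf("P%05d", seq_len(n_proteins))
    sig <- sample(proteins, n_signature)
    sig_sign <- stats::setNames(sample(c(-1, 1), n_signature, replace = TRUE),
                                sig)
    baseline <- stats::rnorm(n_proteins, 22, 2)
    m <- matrix(baseline, n_proteins, nrow(groups),
                dimnames = list(proteins, groups$sample_id))
    shift <- rep(0, n_proteins)
    shift[match(sig, proteins)] <- sig_sign * effect
    m[, groups$group == "cancer"] <- m[, groups$group == "cancer"] + shift
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    raw <- em_tibble(2^m)
    raw <- dplyr::mutate(
      raw,
      unique_peptides = ifelse(raw$protein %in% sig, 2L,
                               sample(1:10, n_proteins, replace = TRUE)),
      .after = "protein"
    )
    truth <- tibble(
      protein = proteins,
      is_signature = proteins %in% sig,
      effect = shift
    )
    list(raw = raw, groups = groups, truth = truth)
  })
}
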