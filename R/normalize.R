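#' Relative abundance with respect to a trimmed mean across conditions
#'
#' For each protein, the per-condition mean values are computed and their
#' trimmed mean (trimming `floor(trim_fraction * n_conditions)` values from
#' each tail; the plain mean when nothing is trimmed) is subtracted from every
#' value of the protein. This re-expresses each profile relative to its
#' typical level so that condition-specific deviations stand out.
#'
#' @param x Wide expression tibble (log2 scale, median-centered upstream).
#' @param design Design tibble (`sample_id`, `condition`, `replicate`).
#' @param trim_fraction Fraction trimmed from each tail of the condition
#'   means, in [0, 0.5). Default 0.2.
#' @return The relative-abundance tibble, same shape as `x`.
#' @export
relative_abundance <- function(x, design, trim_fraction = 0.2) {
  if (!(trim_fraction >= 0 && trim_fraction < 0.5)) {
    abort("trim_fraction must be in [0, 0.5)")
  }
  design <- check_design(x, design)
  m <- em_matrix(x)
  cmeans <- condition_means(m, design)
  ref <- apply(cmeans, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    mean(v, trim = trim_fraction)
  })
  em_tibble(m - ref)
}

# proteins x conditions matrix of per-condition means (NA when a protein has
# no present value in a condition).
condition_means <- function(m, design) {
  conds <- unique(design$condition)
  out <- matrix(NA_real_, nrow(m), length(conds),
                dimnames = list(rownames(m), conds))
  for (cc in conds) {
    cols <- design$sample_id[design$condition == cc]
    sub <- m[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    out[, cc] <- ifelse(n > 0, s / n, NA_real_)
  }
  out
}

#' Complex-wise normalization of member abundances
#'
#' The two-step normalization that exposes compositional (stoichiometric)
#' signal: first each protein is expressed relative to its trimmed mean
#' across conditions ([relative_abundance()]), then, within each complex and
#' sample, the mean relative abundance of the *other* complex members is
#' subtracted. A change affecting a whole complex cancels exactly; only
#' deviations of a member from its complex remain. For proteins belonging to
#' several complexes the corrected values are averaged across those
#' complexes. A complex with fewer than two present members in a sample
#' contributes missing values for that sample.
#'
#' @param x Wide expression tibble, median-centered.
#' @param design Design tibble.
#' @param resource A [complex_resource()], already restricted to quantified
#'   proteins (see [restrict_to_quantified()]).
#' @param trim_fraction Passed to [relative_abundance()]. Default 0.2.
#' @return A corrected wide tibble containing only proteins that are members
#'   of at least one complex in `resource`, with the resource attached as
#'   attribute `"resource"`.
#' @export
normalize_complexwise <- function(x, design, resource, trim_fraction = 0.2) {
  design <- check_design(x, design)
  rel <- em_matrix(relative_abundance(x, design, trim_fraction))
  members_all <- unique(unlist(resource$members, use.names = FALSE))
  members_all <- intersect(rownames(rel), members_all)
  if (length(members_all) == 0) {
    abort("no complex member is present in the expression table")
  }
  total <- matrix(0, length(members_all), ncol(rel),
                  dimnames = list(members_all, colnames(rel)))
  count <- total
  for (k in seq_len(nrow(resource))) {
    mem <- intersect(resource$members[[k]], members_all)
    if (length(mem) < 2) next
    rc <- rel[mem, , drop = FALSE]
    pres <- !is.na(rc)
    n_s <- colSums(pres)
    s_s <- colSums(rc, na.rm = TRUE)
    corr <- rc - sweep(-rc, 2, s_s, `+`) / sweep(-pres, 2, n_s, `+`)
    corr[, n_s < 2] <- NA_real_
    add <- !is.na(corr)
    corr[!add] <- 0
    total[mem, ] <- total[mem, ] + corr
    count[mem, ] <- count[mem, ] + add
  }
  out <- total / count
  out[count == 0] <- NA_real_
  res_tbl <- em_tibble(out)
  attr(res_tbl, "resource") <- resource
  class(res_tbl) <- c("corrected_matrix", class(res_tbl))
  res_tbl
}
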