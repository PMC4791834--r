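#' Within- versus between-complex co-expression
#'
#' Pearson correlations across samples for all protein pairs that share a
#' complex, and for a (seeded) subsample of pairs that share none. Pairs with
#' fewer than 3 commonly present samples are dropped. Between-complex pairs
#' are subsampled to at most `max_between_ratio` times the number of
#' within-complex pairs; the distribution comparison is unaffected.
#'
#' @param x Wide expression tibble restricted to complex members (other rows
#'   are ignored).
#' @param resource A [complex_resource()].
#' @param max_between_ratio Cap on between/within pair count ratio. Default 10.
#' @param seed Seed for the between-pair subsample. Default 1.
#' @return A tibble with columns `protein_a`, `protein_b`, `same_complex`,
#'   `r`.
#' @export
within_between_correlations <- function(x, resource, max_between_ratio = 10,
                                        seed = 1) {
  idx <- complex_index(resource)
  m <- em_matrix(x)
  keep <- rownames(m) %in% idx$protein
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) abort("need at least two complex members with data")
  prots <- rownames(m)
  within_pairs <- unique(dplyr::bind_rows(lapply(seq_len(nrow(resource)), function(k) {
    mem <- sort(intersect(resource$members[[k]], prots))
    if (length(mem) < 2) return(NULL)
    pr <- t(utils::combn(mem, 2))
    tibble(protein_a = pr[, 1], protein_b = pr[, 2])
  })))
  if (nrow(within_pairs) == 0) abort("no within-complex pair has data")
  n_common <- crossprod(!is.na(t(m)) * 1)
  rmat <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  pair_r <- function(a, b) rmat[cbind(a, b)]
  pair_n <- function(a, b) n_common[cbind(a, b)]
  within_pairs$same_complex <- TRUE
  within_pairs$r <- pair_r(within_pairs$protein_a, within_pairs$protein_b)
  within_pairs <- within_pairs[pair_n(within_pairs$protein_a,
                                      within_pairs$protein_b) >= 3, ]
  cid <- unique(idx$complex_id)
  incidence <- matrix(0L, length(prots), length(cid),
                      dimnames = list(prots, cid))
  idx_here <- idx[idx$protein %in% prots, ]
  incidence[cbind(idx_here$protein, idx_here$complex_id)] <- 1L
  share <- tcrossprod(incidence) > 0
  no_share <- which(upper.tri(share) & !share, arr.ind = TRUE)
  between <- cbind(prots[no_share[, 1]], prots[no_share[, 2]])
  n_max <- ceiling(max_between_ratio * nrow(within_pairs))
  if (nrow(between) > n_max) {
    between <- with_seed(seed,
      between[sample.int(nrow(between), n_max), , drop = FALSE])
  }
  between_pairs <- tibble(
    protein_a = between[, 1], protein_b = between[, 2],
    same_complex = FALSE,
    r = pair_r(between[, 1], between[, 2])
  )
  between_pairs <- between_pairs[pair_n(between_pairs$protein_a,
                                        between_pairs$protein_b) >= 3, ]
  out <- dplyr::bind_rows(within_pairs, between_pairs)
  out[!is.na(out$r), , drop = FALSE]
}

#' Rank-sum comparison of two groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test. For `length(a) + length(b) <= 12`
#' the null distribution of the rank sum is enumerated exhaustively (exact
#' even under ties, using midranks); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param method `"auto"` (exact enumeration up to a total of 12
#'   observations, normal approximation above), or force `"exact"` /
#'   `"normal"`.
#' @return A one-row tibble with `W` (rank-sum of group a minus its minimum,
#'   i.e. the Mann-Whitney U) and `p`.
#' @export
compare_member_groups <- function(values_a, values_b,
                                  alternative = c("two.sided", "greater", "less"),
                                  method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  ranks <- rank(c(a, b))
  s_obs <- sum(ranks[seq_len(na)])
  w <- s_obs - na * (na + 1) / 2
  if (method == "auto") method <- if (n <= 12) "exact" else "normal"
  if (method == "exact") {
    combos <- utils::combn(n, na)
    s_all <- colSums(matrix(ranks[combos], nrow = na))
    e_s <- na * (n + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(s_all - e_s) >= abs(s_obs - e_s) - 1e-12),
      greater = mean(s_all >= s_obs - 1e-12),
      less = mean(s_all <= s_obs + 1e-12)
    )
  } else {
    e_s <- na * (n + 1) / 2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    v_s <- na * nb / 12 * ((n + 1) - tie_term)
    z_num <- s_obs - e_s
    cc <- 0.5
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-(abs(z_num) - cc) / sqrt(v_s)),
      greater = stats::pnorm(-(z_num - cc) / sqrt(v_s)),
      less = stats::pnorm((z_num + cc) / sqrt(v_s))
    )
    p <- min(1, p)
  }
  tibble(W = w, p = p)
}

#' Complex-level profile correlation and clustering
#'
#' Summarizes each complex as the unweighted per-sample mean over its
#' quantified members (on the median-centered matrix, *not* the complex-wise
#' normalized one, so overall complex abundance differences are retained),
#' correlates complex profiles, and builds an average-linkage tree on
#' `1 - r`.
#'
#' @param x Median-centered wide expression tibble.
#' @param resource A [complex_resource()].
#' @param min_members Minimum quantified members for a complex profile.
#'   Default 2.
#' @return A list with `profiles` (complex x sample tibble), `cor` (complex x
#'   complex correlation matrix), `hclust` and `phylo` (the same tree, for
#'   Newick export via [ape::write.tree()]).
#' @export
complex_profile_clustering <- function(x, resource, min_members = 2) {
  m <- em_matrix(x)
  prof <- lapply(seq_len(nrow(resource)), function(k) {
    mem <- intersect(resource$members[[k]], rownames(m))
    if (length(mem) < min_members) return(NULL)
    colMeans(m[mem, , drop = FALSE], na.rm = TRUE)
  })
  keep <- !vapply(prof, is.null, logical(1))
  if (sum(keep) < 2) abort("need at least two complexes with quantified members")
  pm <- do.call(rbind, prof[keep])
  rownames(pm) <- resource$complex_id[keep]
  rmat <- suppressWarnings(stats::cor(t(pm), use = "pairwise.complete.obs"))
  hc <- stats::hclust(stats::as.dist(1 - rmat), method = "average")
  list(
    profiles = em_tibble(pm) %>% dplyr::rename(complex_id = "protein"),
    cor = rmat,
    hclust = hc,
    phylo = ape::as.phylo(hc)
  )
}
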