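#' Preprocess a two-group tissue cohort
#'
#' Applies, in order: the unique-peptide filter (`min_unique_peptides`), the
#' per-group presence filter (at least `min_present_per_group` samples
#' quantified in *each* group), log2 transformation of raw intensities
#' (non-positive values become missing), and quantile normalization
#' ([quantile_normalize()]).
#'
#' @param raw Tibble with columns `protein`, `unique_peptides`, then one raw
#'   intensity column per sample (0 or NA = not quantified).
#' @param groups Tibble with columns `sample_id` and `group` (exactly two
#'   groups, each with at least 2 samples).
#' @param min_unique_peptides Minimum unique peptides. Default 2.
#' @param min_present_per_group Minimum quantified samples per group.
#'   Default 4.
#' @return A list of class `cohort_matrix`: `x` (log2, quantile-normalized
#'   wide tibble) and `groups`.
#' @export
preprocess_cohort <- function(raw, groups, min_unique_peptides = 2,
                              min_present_per_group = 4) {
  stopifnot(all(c("protein", "unique_peptides") %in% names(raw)))
  groups <- check_groups(groups)
  raw <- raw[raw$unique_peptides >= min_unique_peptides, , drop = FALSE]
  x <- raw[c("protein", groups$sample_id)]
  m <- em_matrix(x)
  m[!is.na(m) & m <= 0] <- NA_real_
  for (g in unique(groups$group)) {
    cols <- groups$sample_id[groups$group == g]
    keep <- rowSums(!is.na(m[, cols, drop = FALSE])) >= min_present_per_group
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no protein survives the cohort filters")
  out <- list(x = quantile_normalize(em_tibble(log2(m))), groups = groups)
  class(out) <- "cohort_matrix"
  out
}

check_groups <- function(groups) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  groups <- dplyr::mutate(groups,
    sample_id = as.character(.data$sample_id),
    group = as.character(.data$group)
  )
  if (length(unique(groups$group)) != 2) {
    abort("classification requires exactly two groups")
  }
  if (any(table(groups$group) < 2)) {
    abort("each group needs at least 2 samples (leave-one-out centroids)")
  }
  groups
}

#' Leave-one-out nearest-centroid classification
#'
#' Each sample is held out in turn; group centroids are the per-feature means
#' over the remaining samples, and the held-out sample is assigned to the
#' group with the smaller Euclidean distance over the chosen features.
#' Distance ties are left unclassified and count as errors (conservative).
#'
#' @param cohort A `cohort_matrix` (from [preprocess_cohort()]) or a list
#'   with elements `x` (wide tibble) and `groups`.
#' @param features Character vector of protein ids to classify on.
#' @return A list: `accuracy` (fraction correct) and `predictions` (tibble
#'   `sample_id`, `group`, `predicted`, `correct`).
#' @export
nearest_centroid_loo <- function(cohort, features) {
  x <- cohort$x
  groups <- check_groups(cohort$groups)
  if (length(features) < 1) abort("need at least one feature")
  m <- em_matrix(x)
  missing_f <- setdiff(features, rownames(m))
  if (length(missing_f) > 0) {
    abort(paste0("features absent from the cohort: ",
                 paste(utils::head(missing_f, 5), collapse = ", ")))
  }
  m <- m[features, groups$sample_id, drop = FALSE]
  gl <- groups$group
  levs <- unique(gl)
  preds <- character(ncol(m))
  for (i in seq_len(ncol(m))) {
    keep <- seq_len(ncol(m)) != i
    d <- vapply(levs, function(g) {
      cols <- keep & gl == g
      if (sum(cols) == 0) {
        abort("a group has a single sample; its leave-one-out centroid is undefined")
      }
      centroid <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
      sqrt(sum((m[, i] - centroid)^2, na.rm = TRUE))
    }, numeric(1))
    preds[i] <- if (abs(d[1] - d[2]) < .Machine$double.eps^0.5 * max(1, d)) {
      NA_character_
    } else {
      levs[which.min(d)]
    }
  }
  predictions <- tibble(
    sample_id = colnames(m), group = gl, predicted = preds,
    correct = !is.na(preds) & preds == gl
  )
  list(accuracy = mean(predictions$correct), predictions = predictions)
}

#' Evaluate signature versus random feature sets
#'
#' For every feature-set size, draws `n_samples` feature sets without
#' replacement from the signature pool and from the random pool (by default
#' the full feature universe, signature members included), records the
#' leave-one-out nearest-centroid accuracy of each set, and compares the two
#' accuracy distributions per size with a Wilcoxon rank-sum test
#' ([compare_member_groups()]).
#'
#' @param cohort A `cohort_matrix` or list with `x` and `groups`.
#' @param signature_pool Character vector of signature feature ids.
#' @param sizes Feature-set sizes. Default `seq(4, 28, by = 4)`.
#' @param n_samples Feature sets per size per pool. Default 100.
#' @param seed Seed making the sampling reproducible. Default 1.
#' @param exclude_signature_from_random If `TRUE`, remove signature members
#'   from the random pool. Default `FALSE` (compare against all quantified
#'   proteins, as in the reference analysis).
#' @param alternative Wilcoxon alternative for signature vs random accuracy.
#'   Default `"greater"`.
#' @return An object of class `signature_eval`: a list with `draws` (tibble:
#'   `size`, `pool`, `draw`, `accuracy`) and `summary` (per size: means,
#'   standard errors, Wilcoxon `W` and `p`).
#' @export
feature_sampling_eval <- function(cohort, signature_pool,
                                  sizes = seq(4, 28, by = 4), n_samples = 100,
                                  seed = 1,
                                  exclude_signature_from_random = FALSE,
                                  alternative = "greater") {
  x <- cohort$x
  groups <- check_groups(cohort$groups)
  universe <- x$protein
  signature_pool <- intersect(signature_pool, universe)
  if (length(signature_pool) < max(sizes)) {
    abort("signature pool smaller than the largest feature-set size")
  }
  random_pool <- if (exclude_signature_from_random) {
    setdiff(universe, signature_pool)
  } else {
    universe
  }
  draws <- with_seed(seed, {
    rows <- list()
    for (sz in sizes) {
      for (pool_name in c("signature", "random")) {
        pool <- if (pool_name == "signature") signature_pool else random_pool
        acc <- vapply(seq_len(n_samples), function(i) {
          feats <- sample(pool, sz)
          nearest_centroid_loo(cohort, feats)$accuracy
        }, numeric(1))
        rows[[length(rows) + 1]] <- tibble(
          size = sz, pool = pool_name, draw = seq_len(n_samples),
          accuracy = acc
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  summary <- draws %>%
    dplyr::group_by(.data$size, .data$pool) %>%
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      se_accuracy = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "pool",
                       values_from = c("mean_accuracy", "se_accuracy"))
  tests <- draws %>%
    dplyr::group_by(.data$size) %>%
    dplyr::summarise(
      test = list(compare_member_groups(
        .data$accuracy[.data$pool == "signature"],
        .data$accuracy[.data$pool == "random"],
        alternative = alternative
      )),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test")
  out <- list(
    draws = draws,
    summary = dplyr::left_join(summary, tests, by = "size"),
    n_samples = n_samples, seed = seed
  )
  class(out) <- "signature_eval"
  out
}

#' Average-linkage dendrogram of cohort samples
#'
#' Agglomerative average-linkage clustering of samples on Euclidean distance
#' over the chosen features; deterministic leaf order.
#'
#' @param cohort A `cohort_matrix` or list with `x` and (optionally) `groups`.
#' @param features Character vector of protein ids.
#' @return A list with `hclust` and `phylo` (export Newick via
#'   [ape::write.tree()]).
#' @export
hierarchical_dendrogram <- function(cohort, features) {
  x <- if (is.data.frame(cohort)) cohort else cohort$x
  m <- em_matrix(x)
  missing_f <- setdiff(features, rownames(m))
  if (length(missing_f) > 0) {
    abort(paste0("features absent from the cohort: ",
                 paste(utils::head(missing_f, 5), collapse = ", ")))
  }
  d <- stats::dist(t(m[features, , drop = FALSE]), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, phylo = ape::as.phylo(hc))
}
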