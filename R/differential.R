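#' Per-protein one-condition-vs-rest contrasts
#'
#' Fits, per protein, a one-way linear model on condition means over the
#' samples where the protein is present. The contrast tested for condition
#' `c` is `mean(c) - mean(other condition means)` (unweighted across the
#' other conditions, so unequal replicate counts do not bias the reference).
#' The standard error uses the residual variance pooled across all samples of
#' that protein. Proteins are tested only in conditions where they are
#' present; proteins with zero residual degrees of freedom are retained but
#' flagged (they are excluded from the moderation fit).
#'
#' @param x Corrected (or any log-scale) wide expression tibble.
#' @param design Design tibble (`sample_id`, `condition`, `replicate`).
#' @return An object of class `contrast_fit`: a list with
#'   `effects` (tibble: `protein`, `condition`, `effect`, `unscaled_se`),
#'   `variances` (tibble: `protein`, `sigma2`, `df`), and `conditions`.
#' @export
fit_condition_contrasts <- function(x, design) {
  design <- check_design(x, design)
  m <- em_matrix(x)
  conds <- unique(design$condition)
  if (length(conds) < 2) abort("need at least 2 conditions to form contrasts")
  P <- nrow(m)
  pres <- !is.na(m)
  n_pc <- matrix(0L, P, length(conds), dimnames = list(rownames(m), conds))
  mean_pc <- matrix(NA_real_, P, length(conds),
                    dimnames = list(rownames(m), conds))
  for (cc in conds) {
    cols <- design$condition == cc
    n_pc[, cc] <- rowSums(pres[, cols, drop = FALSE])
    s <- rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
    mean_pc[, cc] <- ifelse(n_pc[, cc] > 0, s / n_pc[, cc], NA_real_)
  }
  k <- rowSums(n_pc > 0)
  n_tot <- rowSums(n_pc)
  fitted <- mean_pc[, design$condition, drop = FALSE]
  res2 <- (m - fitted)^2
  ss <- rowSums(res2, na.rm = TRUE)
  df <- n_tot - k
  sigma2 <- ifelse(df > 0, ss / df, NA_real_)

  eff_list <- vector("list", length(conds))
  inv_n <- ifelse(n_pc > 0, 1 / n_pc, 0)
  for (j in seq_along(conds)) {
    cc <- conds[j]
    testable <- n_pc[, cc] > 0 & k >= 2
    other <- mean_pc[, setdiff(conds, cc), drop = FALSE]
    other_mean <- rowMeans(other, na.rm = TRUE)
    effect <- mean_pc[, cc] - other_mean
    k_other <- k - 1
    sum_inv_other <- rowSums(inv_n[, setdiff(conds, cc), drop = FALSE])
    unscaled <- sqrt(inv_n[, cc] + sum_inv_other / k_other^2)
    eff_list[[j]] <- tibble(
      protein = rownames(m)[testable],
      condition = cc,
      effect = unname(effect[testable]),
      unscaled_se = unname(unscaled[testable])
    )
  }
  out <- list(
    effects = dplyr::bind_rows(eff_list),
    variances = tibble(protein = rownames(m), sigma2 = unname(sigma2),
                       df = unname(df), zero_df = unname(df == 0)),
    conditions = conds
  )
  class(out) <- "contrast_fit"
  out
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation of contrast fits
#'
#' Shrinks per-protein residual variances toward a prior estimated across all
#' proteins, in the standard hierarchical model where residual variances
#' follow a scaled inverse-chi-square distribution with prior degrees of
#' freedom `d0` and prior variance `s0_sq`. The hyperparameters are estimated
#' by moment-matching of the log residual variances (digamma/trigamma
#' equations solved numerically). Moderated t statistics use the posterior
#' variance `s_tilde_sq = (d0 * s0_sq + df * s2) / (d0 + df)` with
#' `d0 + df` degrees of freedom. Proteins with zero residual df are excluded
#' from the hyperparameter fit but still moderated (their posterior variance
#' is `s0_sq`).
#'
#' @param fit A [fit_condition_contrasts()] result.
#' @param d0 Optional override of the prior degrees of freedom: `0` gives
#'   ordinary (unmoderated) t statistics, `Inf` a pooled-variance t.
#' @param min_proteins Below this number of proteins with positive residual
#'   df, moderation falls back to ordinary t (`d0 = 0`). Default 10.
#' @return An object of class `ebayes_fit`: a list with `table` (tibble:
#'   `protein`, `condition`, `log2fc`, `t_mod`, `p`, `df_total`), `d0`,
#'   `s0_sq`, and the per-protein `variances` tibble gaining `s_tilde_sq`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, min_proteins = 10) {
  stopifnot(inherits(fit, "contrast_fit"))
  v <- fit$variances
  usable <- which(v$df > 0 & !is.na(v$sigma2) & v$sigma2 > 0)
  if (is.null(d0) && length(usable) < min_proteins) d0 <- 0
  if (is.null(d0)) {
    dg <- v$df[usable]
    z <- log(v$sigma2[usable])
    e <- z - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    n <- length(e)
    rhs <- mean((e - emean)^2 * n / (n - 1) - trigamma(dg / 2))
    if (rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    if (d0 == 0) {
      s0_sq <- NA_real_
    } else if (is.infinite(d0)) {
      dg <- v$df[usable]
      e <- log(v$sigma2[usable]) - digamma(dg / 2) + log(dg / 2)
      s0_sq <- exp(mean(e))
    } else {
      dg <- v$df[usable]
      e <- log(v$sigma2[usable]) - digamma(dg / 2) + log(dg / 2)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  df_g <- ifelse(is.na(v$df), 0, v$df)
  s2 <- ifelse(is.na(v$sigma2), 0, v$sigma2)
  if (d0 == 0) {
    s_tilde_sq <- ifelse(df_g > 0, s2, NA_real_)
    df_total <- df_g
  } else if (is.infinite(d0)) {
    s_tilde_sq <- rep(s0_sq, nrow(v))
    df_total <- rep(Inf, nrow(v))
  } else {
    s_tilde_sq <- (d0 * s0_sq + df_g * s2) / (d0 + df_g)
    df_total <- d0 + df_g
  }
  v$s_tilde_sq <- s_tilde_sq
  vd <- tibble(protein = v$protein, s_tilde_sq = s_tilde_sq,
               df_total = df_total)
  tab <- dplyr::left_join(fit$effects, vd, by = "protein")
  tab$t_mod <- tab$effect / (tab$unscaled_se * sqrt(tab$s_tilde_sq))
  tab$p <- 2 * stats::pt(-abs(tab$t_mod), df = tab$df_total)
  out <- list(
    table = tibble(
      protein = tab$protein, condition = tab$condition,
      log2fc = tab$effect, t_mod = tab$t_mod, p = tab$p,
      df_total = tab$df_total
    ),
    d0 = d0, s0_sq = s0_sq,
    variances = v,
    conditions = fit$conditions
  )
  class(out) <- "ebayes_fit"
  out
}

#' Benjamini-Hochberg adjustment within groups
#'
#' Applies step-up FDR adjustment separately within each level of a grouping
#' column (per experimental condition in the stoichiometry pipeline).
#'
#' @param x A tibble with a p-value column.
#' @param p_col Name of the p-value column. Default `"p"`.
#' @param by Name of the grouping column; `NULL` adjusts globally. Default
#'   `"condition"`.
#' @return `x` with a `p_adj` column added.
#' @export
bh_adjust <- function(x, p_col = "p", by = "condition") {
  p <- x[[p_col]]
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  if (is.null(by)) {
    x$p_adj <- stats::p.adjust(p, method = "BH")
  } else {
    g <- x[[by]]
    x$p_adj <- stats::ave(p, g, FUN = function(v) stats::p.adjust(v, "BH"))
  }
  x
}

#' Call variable members and variable complexes
#'
#' A member is *variable* when its per-condition BH-adjusted p-value falls
#' below `member_alpha` in at least one condition; a complex is *variable*
#' when at least `complex_threshold` of its quantified members are variable
#' (boundary included), otherwise *stable*.
#'
#' @param moderated An [ebayes_moderate()] result (or its `table` tibble with
#'   columns `protein`, `condition`, `log2fc`, `p`).
#' @param resource A [complex_resource()] restricted to quantified proteins.
#' @param member_alpha Per-condition adjusted-p threshold. Default 0.05.
#' @param complex_threshold Minimum fraction of variable members for a
#'   variable-complex verdict. Default 0.20.
#' @return An object of class `member_calls`: a list of tibbles `conditions`
#'   (protein x condition calls), `proteins` (per-protein `is_variable`) and
#'   `complexes` (per-complex fraction and verdict).
#' @export
call_variable <- function(moderated, resource, member_alpha = 0.05,
                          complex_threshold = 0.20) {
  tab <- if (inherits(moderated, "ebayes_fit")) moderated$table else moderated
  tab <- bh_adjust(tab, p_col = "p", by = "condition")
  tab$is_variable_at_condition <- !is.na(tab$p_adj) & tab$p_adj < member_alpha
  proteins <- tab %>%
    dplyr::group_by(.data$protein) %>%
    dplyr::summarise(is_variable = any(.data$is_variable_at_condition),
                     .groups = "drop")
  variable_set <- proteins$protein[proteins$is_variable]
  quantified <- unique(tab$protein)
  complexes <- tibble(
    complex_id = resource$complex_id,
    n_quantified = vapply(resource$members,
                          function(m) length(intersect(m, quantified)),
                          integer(1)),
    n_variable = vapply(resource$members,
                        function(m) length(intersect(m, variable_set)),
                        integer(1))
  ) %>%
    dplyr::mutate(
      fraction_variable = ifelse(.data$n_quantified > 0,
                                 .data$n_variable / .data$n_quantified,
                                 NA_real_),
      verdict = ifelse(!is.na(.data$fraction_variable) &
                         .data$fraction_variable >= complex_threshold,
                       "variable", "stable")
    )
  out <- list(conditions = tab, proteins = proteins, complexes = complexes,
              member_alpha = member_alpha,
              complex_threshold = complex_threshold)
  class(out) <- "member_calls"
  out
}

#' Fisher's exact overlap test between two sets
#'
#' Builds the 2x2 membership table of two sets within a universe and returns
#' the sample odds ratio, the exact two-sided hypergeometric p-value (sum of
#' table probabilities not exceeding the observed one) and the Jaccard
#' overlap.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible identifiers.
#' @return A one-row tibble: `n_overlap`, `odds_ratio`, `p`, `jaccard`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("set_a and set_b must be subsets of universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  n11 <- sum(in_a & in_b); n10 <- sum(in_a & !in_b)
  n01 <- sum(!in_a & in_b); n00 <- sum(!in_a & !in_b)
  tab <- matrix(c(n11, n01, n10, n00), 2)
  p <- stats::fisher.test(tab)$p.value
  or <- (n11 * n00) / (n10 * n01)
  if (is.nan(or)) or <- ifelse(n11 * n00 > 0, Inf, 0)
  uni <- length(union(set_a, set_b))
  tibble(
    n_overlap = n11,
    odds_ratio = or,
    p = p,
    jaccard = ifelse(uni > 0, n11 / uni, NA_real_)
  )
}
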