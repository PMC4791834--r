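# Independent oracles used to validate the package's implementations.
# Each is written from the definition, not from the code path it checks.

# Step-up BH adjustment straight from the definition:
# adj_i = min over ranks t >= rank(i) of (m * p_(t) / t), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Exact two-sided rank-sum p by full enumeration of group assignments,
# computed on the Mann-Whitney U scale (pairwise wins + half-ties) so it is
# a genuinely different route from the rank-sum enumeration in the package.
oracle_wilcox_exact <- function(a, b, alternative = "two.sided") {
  vals <- c(a, b)
  n <- length(vals)
  na <- length(a)
  u_of <- function(ia) {
    av <- vals[ia]; bv <- vals[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(na))
  e_u <- na * (n - na) / 2
  switch(alternative,
    two.sided = mean(abs(u_all - e_u) >= abs(u_obs - e_u) - 1e-12),
    greater = mean(u_all >= u_obs - 1e-12),
    less = mean(u_all <= u_obs + 1e-12)
  )
}

# Two-sided Fisher p by hypergeometric enumeration: sum of probabilities of
# all tables with the observed margins no more probable than the observed.
oracle_fisher_p <- function(n11, n10, n01, n00) {
  m1 <- n11 + n10  # size of set a
  m2 <- n11 + n01  # size of set b
  n <- n11 + n10 + n01 + n00
  ks <- max(0, m1 + m2 - n):min(m1, m2)
  probs <- stats::dhyper(ks, m2, n - m2, m1)
  obs <- stats::dhyper(n11, m2, n - m2, m1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive complex-wise normalization: explicit loops over complexes, samples
# and members; averages across complexes for multi-membership proteins.
oracle_complexwise <- function(rel, members_list) {
  prots <- sort(unique(unlist(members_list)))
  prots <- intersect(rownames(rel), prots)
  total <- matrix(0, length(prots), ncol(rel),
                  dimnames = list(prots, colnames(rel)))
  count <- total
  for (mem in members_list) {
    mem <- intersect(mem, rownames(rel))
    if (length(mem) < 2) next
    for (s in seq_len(ncol(rel))) {
      present <- mem[!is.na(rel[mem, s])]
      if (length(present) < 2) next
      for (p in present) {
        others <- setdiff(present, p)
        corr <- rel[p, s] - mean(rel[others, s])
        total[p, s] <- total[p, s] + corr
        count[p, s] <- count[p, s] + 1
      }
    }
  }
  out <- total / count
  out[count == 0] <- NA_real_
  out
}

# Numeric maximum-likelihood fit of the variance prior (d0, s0_sq) under the
# hierarchical model s2 ~ s0_sq * F(df, d0); used as the oracle for the
# moment-matching estimator.
oracle_variance_prior_mle <- function(s2, df) {
  negll <- function(par) {
    d0 <- exp(par[1]); s0 <- exp(par[2])
    -sum(stats::df(s2 / s0, df, d0, log = TRUE) - log(s0))
  }
  fit <- stats::optim(c(log(4), log(stats::median(s2))), negll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(d0 = exp(fit$par[1]), s0_sq = exp(fit$par[2]))
}

# Small random complex resource for property tests.
random_small_resource <- function(seed, max_complexes = 12) {
  withr::with_seed(seed, {
    n <- sample(2:max_complexes, 1)
    pool <- sprintf("P%02d", 1:40)
    complex_resource(
      complex_id = sprintf("C%02d", seq_len(n)),
      source = sample(c("manual", "compleat", "corum", "user"), n, replace = TRUE),
      members = lapply(seq_len(n), function(i) sample(pool, sample(5:10, 1)))
    )
  })
}

# Tiny deterministic wide matrix + design used across tests.
tiny_matrix <- function(values, conditions, replicates = NULL,
                        proteins = NULL) {
  m <- as.matrix(values)
  if (is.null(proteins)) proteins <- sprintf("p%d", seq_len(nrow(m)))
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  }
  design <- tibble::tibble(
    sample_id = sprintf("s%d", seq_along(conditions)),
    condition = conditions,
    replicate = as.integer(replicates)
  )
  colnames(m) <- design$sample_id
  rownames(m) <- proteins
  list(x = tibble::as_tibble(m, rownames = "protein"), design = design)
}
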