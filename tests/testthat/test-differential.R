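test_that("condition-vs-rest contrasts follow the closed-form arithmetic", {
  # all values equal -> all effects 0
  d <- tiny_matrix(matrix(2, 3, 6), conditions = rep(c("A", "B", "C"), each = 2))
  fit <- fit_condition_contrasts(d$x, d$design)
  expect_true(all(fit$effects$effect == 0))

  # condition means (4,1,1), balanced -> contrast for A = 4 - 1 = 3
  set.seed(3)
  vals <- matrix(rnorm(1 * 6, 0, 1e-8), 1, 6) +
    rep(c(4, 1, 1), each = 2)
  d2 <- tiny_matrix(vals, conditions = rep(c("A", "B", "C"), each = 2))
  fit2 <- fit_condition_contrasts(d2$x, d2$design)
  expect_equal(fit2$effects$effect[fit2$effects$condition == "A"], 3,
               tolerance = 1e-6)

  # a single-replicate condition still receives an effect with pooled variance
  d3 <- tiny_matrix(matrix(c(1, 1.2, 2, 2.2, 5), 1),
                    conditions = c("A", "A", "B", "B", "C"))
  fit3 <- fit_condition_contrasts(d3$x, d3$design)
  eff_c <- fit3$effects[fit3$effects$condition == "C", ]
  expect_equal(nrow(eff_c), 1)
  expect_equal(eff_c$effect, 5 - mean(c(1.1, 2.1)))
  expect_true(is.finite(fit3$variances$sigma2))
})

test_that("effects and ordinary t p-values match a per-protein lm oracle", {
  set.seed(21)
  conds <- rep(c("A", "B", "C", "D"), each = 3)
  vals <- matrix(rnorm(5 * 12), 5, 12)
  d <- tiny_matrix(vals, conditions = conds)
  fit <- fit_condition_contrasts(d$x, d$design)
  mod <- ebayes_moderate(fit, d0 = 0)
  for (p in 1:5) {
    lmfit <- lm(vals[p, ] ~ 0 + factor(conds))
    cf <- coef(lmfit)
    V <- vcov(lmfit)
    for (ci in 1:4) {
      w <- rep(-1 / 3, 4); w[ci] <- 1
      eff <- sum(w * cf)
      se <- sqrt(drop(t(w) %*% V %*% w))
      t_ref <- eff / se
      p_ref <- 2 * pt(-abs(t_ref), df = df.residual(lmfit))
      row <- mod$table[mod$table$protein == sprintf("p%d", p) &
                         mod$table$condition == c("A", "B", "C", "D")[ci], ]
      expect_equal(row$log2fc, eff, tolerance = 1e-10)
      expect_equal(row$t_mod, t_ref, tolerance = 1e-10)
      expect_equal(row$p, p_ref, tolerance = 1e-10)
    }
  }
})

test_that("moderation limits behave as the shrinkage formula dictates", {
  set.seed(5)
  d <- tiny_matrix(matrix(rnorm(30 * 9), 30, 9),
                   conditions = rep(c("A", "B", "C"), each = 3))
  fit <- fit_condition_contrasts(d$x, d$design)
  plain <- ebayes_moderate(fit, d0 = 0)
  pooled <- ebayes_moderate(fit, d0 = Inf)
  # d0 = 0: moderated t equals ordinary t exactly
  expect_equal(plain$variances$s_tilde_sq, fit$variances$sigma2)
  # d0 = Inf: every posterior variance equals the prior
  expect_equal(unique(round(pooled$variances$s_tilde_sq, 12)),
               round(pooled$s0_sq, 12))
  # estimated d0 interpolates between the two
  est <- ebayes_moderate(fit)
  expect_true(est$d0 > 0)
  mid <- est$variances$s_tilde_sq
  lo <- pmin(fit$variances$sigma2, est$s0_sq)
  hi <- pmax(fit$variances$sigma2, est$s0_sq)
  expect_true(all(mid >= lo - 1e-10 & mid <= hi + 1e-10))
})

test_that("variance-prior hyperparameters are recovered from simulated draws", {
  set.seed(99)
  d0_true <- 4; s0_true <- 0.05; dg <- 6; n <- 5000
  s2 <- s0_true * rf(n, dg, d0_true)
  fake <- list(
    effects = tibble::tibble(protein = character(0), condition = character(0),
                             effect = numeric(0), unscaled_se = numeric(0)),
    variances = tibble::tibble(protein = sprintf("p%d", 1:n),
                               sigma2 = s2, df = dg, zero_df = FALSE),
    conditions = c("A", "B")
  )
  class(fake) <- "contrast_fit"
  mod <- ebayes_moderate(fake)
  expect_lt(abs(mod$d0 - d0_true) / d0_true, 0.2)
  expect_lt(abs(mod$s0_sq - s0_true) / s0_true, 0.1)
  # numeric-MLE oracle lands in the same place
  mle <- oracle_variance_prior_mle(s2, rep(dg, n))
  expect_lt(abs(mod$d0 - mle$d0) / mle$d0, 0.2)
  expect_lt(abs(mod$s0_sq - mle$s0_sq) / mle$s0_sq, 0.1)
  # independent cross-check against the established moderation fit
  ff <- limma::fitFDist(s2, df1 = dg)
  expect_equal(mod$d0, ff$df2, tolerance = 1e-6)
  expect_equal(mod$s0_sq, ff$scale, tolerance = 1e-6)
})

test_that("per-condition BH adjustment matches the step-up oracle", {
  tab <- tibble::tibble(condition = "A", p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_adjust(tab)$p_adj, rep(0.04, 4))
  one <- tibble::tibble(condition = "A", p = 0.3)
  expect_equal(bh_adjust(one)$p_adj, 0.3)
  same <- tibble::tibble(condition = "A", p = rep(0.2, 6))
  expect_equal(bh_adjust(same)$p_adj, rep(0.2, 6))

  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    tab <- tibble::tibble(condition = sample(c("A", "B"), length(p), TRUE),
                          p = p)
    got <- bh_adjust(tab)$p_adj
    for (cc in unique(tab$condition)) {
      sel <- tab$condition == cc
      expect_equal(got[sel], oracle_bh(p[sel]))
    }
    # monotone non-decreasing in p within a condition
    for (cc in unique(tab$condition)) {
      sel <- which(tab$condition == cc)
      o <- order(p[sel])
      expect_true(all(diff(got[sel][o]) >= -1e-12))
    }
  }
})

test_that("variable member and complex calling applies the 5 % / 20 % rules", {
  make_calls <- function(n_members, n_variable) {
    prot <- sprintf("m%02d", seq_len(n_members))
    tibble::tibble(
      protein = rep(prot, 2),
      condition = rep(c("A", "B"), each = n_members),
      log2fc = 1, t_mod = 1,
      p = c(ifelse(seq_len(n_members) <= n_variable, 1e-6, 0.9), rep(0.9, n_members))
    )
  }
  res10 <- complex_resource("C1", members = list(sprintf("m%02d", 1:10)))
  out <- call_variable(make_calls(10, 2), res10)
  expect_equal(out$complexes$verdict, "variable")   # 2/10 = 20 % boundary in
  res9 <- complex_resource("C1", members = list(sprintf("m%02d", 1:9)))
  expect_equal(call_variable(make_calls(9, 1), res9)$complexes$verdict,
               "stable")                             # 1/9 = 11 %
  res5 <- complex_resource("C1", members = list(sprintf("m%02d", 1:5)))
  expect_equal(call_variable(make_calls(5, 1), res5)$complexes$verdict,
               "variable")                           # 1/5 = 20 %
})

test_that("fisher overlap reproduces enumeration oracles", {
  # [[3,1],[1,3]]: universe of 8, sets of 4 overlapping in 3
  uni <- sprintf("u%d", 1:8)
  a <- uni[1:4]; b <- uni[c(1:3, 5)]
  got <- fisher_overlap(a, b, uni)
  expect_equal(got$odds_ratio, 9)
  expect_equal(got$p, 34 / 70, tolerance = 1e-12)
  expect_equal(got$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(got$jaccard, 3 / 5)

  # disjoint sets covering the universe -> odds ratio 0
  expect_equal(fisher_overlap(uni[1:4], uni[5:8], uni)$odds_ratio, 0)

  # identical sets achieve the minimal p over tables with those margins
  pid <- fisher_overlap(a, a, uni)$p
  for (k in 0:3) {
    other_b <- c(a[seq_len(k)], uni[5:8][seq_len(4 - k)])
    expect_gte(fisher_overlap(a, other_b, uni)$p, pid - 1e-12)
  }

  # random tables against the enumeration oracle
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    uni <- sprintf("x%d", seq_len(n))
    a <- sample(uni, sample(1:(n - 1), 1))
    b <- sample(uni, sample(1:(n - 1), 1))
    got <- fisher_overlap(a, b, uni)
    n11 <- length(intersect(a, b))
    expect_equal(got$p, oracle_fisher_p(
      n11, length(a) - n11, length(b) - n11,
      n - length(union(a, b))
    ), tolerance = 1e-9)
  }
})
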