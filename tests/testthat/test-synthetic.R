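test_that("resource generation honours sizes, membership rate and seeding", {
  gr <- generate_resource(10, 200, size_range = c(5, 5),
                          multi_membership_rate = 0, seed = 1)
  expect_equal(lengths(gr$resource$members), rep(5L, 10))
  # with rate 0, every member belongs to exactly one complex
  idx <- complex_index(gr$resource)
  expect_equal(max(table(idx$protein)), 1)
  expect_identical(generate_resource(10, 200, size_range = c(5, 5),
                                     multi_membership_rate = 0, seed = 1),
                   gr)
  gr2 <- generate_resource(10, 200, size_range = c(5, 10),
                           multi_membership_rate = 0.2, seed = 2)
  idx2 <- complex_index(gr2$resource)
  expect_true(any(table(idx2$protein) == 2))
  expect_true(all(table(idx2$protein) <= 2))
  # truth records the multiplicities
  expect_equal(sum(gr2$truth$n_complexes),
               sum(lengths(gr2$resource$members)))
})

test_that("proteome generation plants effects and co-regulation as stated", {
  gr <- generate_resource(10, 200, size_range = c(5, 8), seed = 3)
  # no variability, no complex term: pure baseline + noise
  quiet <- generate_proteome(gr$resource, n_conditions = 4,
                             variable_fraction = 0, complex_abundance_sd = 0,
                             noise_sd = 0.1, seed = 3)
  expect_false(any(quiet$truth$is_variable))
  m <- as.matrix(quiet$x[-1])
  expect_lt(max(apply(m, 1, sd)), 0.5)  # row spread is noise-only

  # same seed -> identical matrix
  again <- generate_proteome(gr$resource, n_conditions = 4,
                             variable_fraction = 0, complex_abundance_sd = 0,
                             noise_sd = 0.1, seed = 3)
  expect_identical(again$x, quiet$x)

  # strong complex term -> high within-complex correlation
  strong <- generate_proteome(gr$resource, n_conditions = 20, n_replicates = 1,
                              variable_fraction = 0,
                              complex_abundance_sd = 1, noise_sd = 0.25,
                              seed = 4)
  cors <- within_between_correlations(median_center(strong$x), gr$resource,
                                      seed = 1)
  expect_gt(median(cors$r[cors$same_complex]), 0.8)

  # planted effects recovered without bias by the estimation chain
  err <- numeric(0)
  for (seed in 1:10) {
    pr <- generate_proteome(gr$resource, n_conditions = 6, seed = seed)
    calls <- run_member_pipeline(median_center(pr$x), pr$design, pr$resource)
    est <- dplyr::inner_join(calls$conditions,
                             dplyr::filter(pr$truth, is_variable),
                             by = c("protein", "condition"))
    err <- c(err, est$log2fc - est$true_effect)
  }
  expect_lt(abs(mean(err)), 0.1)
})

test_that("paralog and transcriptome generators are deterministic and consistent", {
  gr <- generate_resource(15, 300, size_range = c(6, 10), seed = 5)
  pr <- generate_proteome(gr$resource, n_conditions = 5,
                          variable_fraction = 0, seed = 5)
  sw1 <- generate_paralog_switches(pr, n_pairs = 8, switch_fraction = 1,
                                   seed = 5)
  sw2 <- generate_paralog_switches(pr, n_pairs = 8, switch_fraction = 1,
                                   seed = 5)
  expect_identical(sw1$x, sw2$x)
  expect_identical(sw1$pair_truth, sw2$pair_truth)
  # switch_fraction 1 -> all effect pairs opposite-sign in truth
  planted <- sw1$pair_truth[sw1$pair_truth$planted != "null", ]
  expect_true(all(planted$planted == "switch"))
  ab <- dplyr::left_join(planted, sw1$truth,
                         by = c(protein_a = "protein"))
  ab <- dplyr::left_join(ab, sw1$truth, by = c(protein_b = "protein"),
                         suffix = c("_a", "_b"))
  expect_true(all(sign(ab$true_effect_a) * sign(ab$true_effect_b) == -1))

  tr1 <- generate_transcriptome(sw1, transcriptional_fraction = 0, seed = 6)
  # transcriptional_fraction 0 -> nothing transcriptional in truth
  expect_true(all(tr1$truth$class == "not_transcriptional"))
  expect_identical(generate_transcriptome(sw1, transcriptional_fraction = 0,
                                          seed = 6)$mrna, tr1$mrna)
})

test_that("cohort generation separates groups only through signature proteins", {
  co <- generate_cohort(n_proteins = 300, n_signature = 40, seed = 7)
  expect_equal(sum(co$truth$is_signature), 40)
  expect_identical(generate_cohort(n_proteins = 300, n_signature = 40,
                                   seed = 7)$raw, co$raw)
  m <- log2(as.matrix(co$raw[-(1:2)]))
  grp <- co$groups$group
  delta <- rowMeans(m[, grp == "cancer"]) - rowMeans(m[, grp == "normal"])
  sig <- co$truth$is_signature
  expect_gt(mean(abs(delta[sig])), 3 * mean(abs(delta[!sig])))
  # zero effect -> accuracy near the majority-class prior
  co0 <- generate_cohort(n_proteins = 100, n_signature = 20, effect = 0,
                         seed = 8)
  cohort0 <- preprocess_cohort(co0$raw, co0$groups, min_unique_peptides = 1)
  sig0 <- intersect(co0$truth$protein[co0$truth$is_signature],
                    cohort0$x$protein)
  acc <- nearest_centroid_loo(cohort0, sig0)$accuracy
  expect_lt(acc, 0.95)
})
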