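test_that("probe selection keeps the highest-variance probe per gene", {
  pt <- tibble::tibble(
    probe = c("pA", "pB", "pC", "pD", "pE"),
    gene = c("g1", "g2", "g2", "g3", "g3"),
    s1 = c(1, 1, 1, 2, 2), s2 = c(2, 1.1, 2, 2, 2), s3 = c(3, 1.2, 3, 2, 2)
  )
  out <- select_probesets(pt)
  expect_equal(nrow(out), 3)                       # one probe per gene
  expect_equal(out$probe[out$gene == "g1"], "pA")  # single probe kept
  expect_equal(out$probe[out$gene == "g2"], "pC")  # higher variance wins
  expect_equal(out$probe[out$gene == "g3"], "pD")  # tie -> lexicographic
})

make_variant_calls <- function(df) {
  tibble::tibble(
    protein = df$protein, condition = df$condition, log2fc = df$log2fc,
    p = 1e-6, p_adj = 1e-6, is_variable_at_condition = TRUE
  )
}

test_that("transcriptional classes follow the sign/floor/significance rules", {
  calls <- make_variant_calls(tibble::tibble(
    protein = c("P1", "P2", "P3", "P4", "P5"),
    condition = "D3",
    log2fc = c(1, 1, 1, 1, 1)
  ))
  mapping <- tibble::tibble(protein = sprintf("P%d", 1:4),
                            gene = sprintf("g%d", 1:4))  # P5 unmapped
  mrna <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    condition = "D3",
    log2fc = c(0.8, 0.8, -0.8, 0.3),
    p_adj = c(0.01, 0.2, 0.01, 0.01)
  )
  out <- classify_regulation(calls, mrna, mapping)
  cls <- setNames(out$class, out$protein)
  expect_equal(cls[["P1"]], "transcriptional_true")
  expect_equal(cls[["P2"]], "transcriptional_trend")
  expect_equal(cls[["P3"]], "not_transcriptional")  # sign-inconsistent
  expect_equal(cls[["P4"]], "not_transcriptional")  # below the floor
  expect_equal(cls[["P5"]], "unclassifiable")       # no gene mapping
  # partition property: every matched call gets exactly one class
  expect_equal(nrow(out), 5)
  expect_false(anyNA(out$class))

  # missing mRNA support at a condition -> unclassifiable, not zero
  mrna_gap <- mrna[mrna$gene != "g1", ]
  out_gap <- classify_regulation(calls, mrna_gap, mapping)
  expect_equal(out_gap$class[out_gap$protein == "P1"], "unclassifiable")
})

test_that("miRNA linking requires significance and anti-correlation", {
  reg <- tibble::tibble(
    protein = c("P1", "P2", "P3"), gene = c("g1", "g2", "g3"),
    condition = "D3", protein_fc = -1,
    mrna_fc = c(-0.8, -0.8, -0.8), mrna_p_adj = 0.01,
    class = "transcriptional_true"
  )
  mirna <- tibble::tibble(
    mirna = c("mir1", "mir2"), condition = "D3",
    log2fc = c(1, -1), p_adj = c(0.001, 0.001)
  )
  targets <- tibble::tibble(mirna = c("mir1", "mir2"),
                            gene = c("g1", "g2"))
  out <- link_mirna(reg, mirna, targets)
  expect_equal(out$mirna_linked, c(TRUE, FALSE, FALSE))
  # non-significant miRNA never links
  mirna_ns <- dplyr::mutate(mirna, p_adj = 0.5)
  expect_false(any(link_mirna(reg, mirna_ns, targets)$mirna_linked))
  # non-transcriptional calls never link
  reg_nt <- dplyr::mutate(reg, class = "not_transcriptional")
  expect_false(any(link_mirna(reg_nt, mirna, targets)$mirna_linked))
})

test_that("planted regulation classes and miRNA links are recovered", {
  gr <- generate_resource(25, 500, size_range = c(6, 12), seed = 8)
  pr <- generate_proteome(gr$resource, n_conditions = 8, n_replicates = 3,
                          variable_fraction = 0.25, seed = 8)
  tr <- generate_transcriptome(pr, transcriptional_fraction = 0.40,
                               trend_fraction = 0.06, seed = 8)
  calls <- run_member_pipeline(median_center(pr$x), pr$design, pr$resource)
  reg <- classify_regulation(calls, tr$mrna, tr$mapping)
  reg <- link_mirna(reg, tr$mirna, tr$targets)
  joined <- dplyr::inner_join(reg, tr$truth, by = c("protein", "condition"),
                              suffix = c("", ".truth"))
  # classes recovered exactly on noiseless-threshold transcript inputs
  expect_true(all(joined$class == joined$class.truth))
  expect_equal(joined$mirna_linked, joined$mirna_linked.truth)
  # recovered transcriptional fraction near the planted 40 %
  classified <- reg[reg$class != "unclassifiable", ]
  frac <- mean(classified$class %in% c("transcriptional_true",
                                       "transcriptional_trend"))
  planted_frac <- mean(tr$truth$class != "not_transcriptional")
  expect_lt(abs(frac - planted_frac), 0.10)
})
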