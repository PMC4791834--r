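test_that("GMT and long-TSV complex definitions parse with set semantics", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "C1\tdesc\tP1\tP2\tP3\tP4\tP5",
    "C2\tother\tP3\tP6\tP7\tP8\tP9"
  ), gmt)
  res <- read_complexes(gmt, source = "corum")
  expect_s3_class(res, "complex_resource")
  expect_equal(res$complex_id, c("C1", "C2"))
  expect_equal(res$members[[1]], c("P1", "P2", "P3", "P4", "P5"))
  expect_equal(res$source, c("corum", "corum"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tprotein_id",
               "C1\tP1", "C1\tP1", "C1\tP2", "C2\tP3"), tsv)
  res2 <- read_complexes(tsv)
  expect_equal(res2$members[[1]], c("P1", "P2"))  # duplicate row collapsed

  idx <- complex_index(res)
  expect_equal(sort(idx$complex_id[idx$protein == "P3"]), c("C1", "C2"))
  # index is the exact inverse of membership
  expect_equal(nrow(idx), sum(lengths(res$members)))
})

test_that("malformed and empty complex files raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("C1\tdesc\tP1", "C2\tonly-desc"), bad)
  expect_error(read_complexes(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_error(read_complexes(empty), "empty")
})

test_that("redundancy filtering keeps representatives and removes near-subsets", {
  # exact duplicate: the manual copy outranks the corum copy
  res <- complex_resource(
    c("dup_corum", "dup_manual"),
    source = c("corum", "manual"),
    members = list(sprintf("P%d", 1:5), sprintf("P%d", 1:5))
  )
  kept <- filter_redundant(res)
  expect_equal(kept$complex_id, "dup_manual")

  # worked example: B shares 3/5 = 60 % with A -> removed; C kept because
  # overlap with removed complexes does not count
  res2 <- complex_resource(
    c("A", "B", "C"),
    source = c("manual", "corum", "corum"),
    members = list(sprintf("P%d", 1:6), c("P1", "P2", "P3", "P7", "P8"),
                   sprintf("P%d", 7:11))
  )
  expect_equal(filter_redundant(res2)$complex_id, c("A", "C"))

  # size filter applies first
  small <- complex_resource("S", members = list(c("P1", "P2", "P3", "P4")))
  expect_equal(nrow(filter_redundant(small, min_members = 5)), 0)
})

test_that("no kept pair violates the overlap rule on random resources", {
  for (seed in 1:60) {
    res <- random_small_resource(seed)
    kept <- filter_redundant(res, min_members = 5)
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept) - 1)) {
      for (j in (i + 1):nrow(kept)) {
        frac <- length(intersect(kept$members[[i]], kept$members[[j]])) /
          length(kept$members[[j]])
        expect_lt(frac, 0.5)
      }
    }
    # deterministic ordering
    expect_identical(kept, filter_redundant(res, min_members = 5))
  }
})

test_that("decoys preserve sizes and the multiset of occurrences", {
  res <- complex_resource(
    c("A", "B", "C"),
    members = list(sprintf("P%d", 1:5), sprintf("P%d", 3:9),
                   sprintf("P%d", c(1:4, 10:14)))
  )
  dec <- generate_decoys(res, seed = 1)
  expect_equal(lengths(dec$members), lengths(res$members))
  expect_equal(sort(unlist(dec$members)), sort(unlist(res$members)))
  expect_true(all(vapply(dec$members, anyDuplicated, integer(1)) == 0))
  expect_identical(generate_decoys(res, seed = 1), dec)
  expect_false(identical(generate_decoys(res, seed = 2)$members, dec$members))

  one <- complex_resource("A", members = list(sprintf("P%d", 1:5)))
  expect_setequal(generate_decoys(one, seed = 5)$members[[1]],
                  one$members[[1]])

  # a protein in every complex is still feasible (once per complex)
  everywhere <- complex_resource(
    c("A", "B"),
    members = list(c("P1", "P2", "P3"), c("P1", "P4", "P5"))
  )
  dec2 <- generate_decoys(everywhere, seed = 3)
  expect_true(all(vapply(dec2$members, anyDuplicated, integer(1)) == 0))
  expect_equal(sum(unlist(dec2$members) == "P1"), 2)
})

test_that("decoy multiset/size preservation holds across seeds", {
  res <- random_small_resource(7)
  for (seed in 1:10) {
    dec <- generate_decoys(res, seed = seed)
    expect_equal(lengths(dec$members), lengths(res$members))
    expect_equal(sort(unlist(dec$members)), sort(unlist(res$members)))
    expect_true(all(vapply(dec$members, anyDuplicated, integer(1)) == 0))
  }
})

test_that("ortholog mapping drops, expands and deduplicates", {
  res <- complex_resource("A", members = list(c("P1", "P2", "P3")))
  identity_map <- tibble::tibble(from = c("P1", "P2", "P3"),
                                 to = c("P1", "P2", "P3"))
  expect_equal(map_orthologs(res, identity_map)$members[[1]],
               c("P1", "P2", "P3"))
  partial <- tibble::tibble(from = c("P1", "P2"), to = c("M1", "M2"))
  expect_equal(sort(map_orthologs(res, partial)$members[[1]]), c("M1", "M2"))
  one_to_many <- tibble::tibble(from = c("P1", "P1", "P2", "P3"),
                                to = c("M1a", "M1b", "M2", "M3"))
  expect_setequal(map_orthologs(res, one_to_many)$members[[1]],
                  c("M1a", "M1b", "M2", "M3"))
})

test_that("quantification restriction enforces the five-member rule", {
  res <- complex_resource(
    c("A", "B"),
    members = list(sprintf("P%d", 1:6), sprintf("Q%d", 1:6))
  )
  quantified <- c(sprintf("P%d", 1:5), sprintf("Q%d", 1:4))
  out <- restrict_to_quantified(res, quantified)
  expect_equal(out$complex_id, "A")         # B has only 4 quantified members
  expect_equal(length(out$members[[1]]), 5)
  all_q <- restrict_to_quantified(res, c(res$members[[1]], res$members[[2]]))
  expect_equal(all_q$members, res$members)  # identity when all quantified
})
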