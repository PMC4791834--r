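#' Protein complex resources
#'
#' A complex resource is a tibble with one row per complex and columns
#' `complex_id` (character, unique), `name` (character), `source` (one of
#' `"manual"`, `"compleat"`, `"corum"`, `"user"`; this order is the ranking
#' used during redundancy filtering) and `members` (list column of character
#' vectors, set semantics: deduplicated, no empties). Row order is meaningful
#' and preserved by all operations.
#'
#' @param complex_id,name,source,members Parallel vectors describing the
#'   complexes; `members` is a list of character vectors.
#' @return A `complex_resource` tibble.
#' @export
complex_resource <- function(complex_id, name = complex_id,
                             source = "user", members = list()) {
  source <- match.arg(source, complex_sources, several.ok = TRUE)
  res <- tibble(
    complex_id = as.character(complex_id),
    name = as.character(name),
    source = as.character(source),
    members = lapply(members, function(m) unique(as.character(m)))
  )
  validate_complex_resource(res)
}

complex_sources <- c("manual", "compleat", "corum", "user")

validate_complex_resource <- function(res) {
  if (anyDuplicated(res$complex_id)) {
    abort("complex_id must be unique within a resource")
  }
  if (any(lengths(res$members) == 0) && nrow(res) > 0) {
    abort("complexes must have at least one member")
  }
  if (!all(res$source %in% complex_sources)) {
    abort(paste0("source must be one of: ", paste(complex_sources, collapse = ", ")))
  }
  class(res) <- c("complex_resource", class(tibble()))
  res
}

#' Read complex definitions from GMT or long-format TSV
#'
#' GMT files carry one complex per line: id, description, then members, all
#' tab-separated. Long TSV files carry a header and two or three columns
#' (`complex_id`, `protein_id`, optional `source`). Members are deduplicated
#' (set semantics) and file order is preserved.
#'
#' @param path Path to the definitions file.
#' @param source Source label assigned to every complex (rank order
#'   `manual` < `compleat` < `corum` < `user`); a `source` column in a TSV
#'   file takes precedence.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return A [complex_resource()] tibble.
#' @export
read_complexes <- function(path, source = "user", format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  source <- match.arg(source, complex_sources)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) abort(paste0("empty complex file: ", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3)
    if (length(bad) > 0) {
      abort(paste0("malformed GMT line ", bad[1], " in ", path,
                   ": expected id, description and at least one member"))
    }
    complex_resource(
      complex_id = vapply(fields, `[[`, character(1), 1),
      name = vapply(fields, `[[`, character(1), 2),
      source = source,
      members = lapply(fields, function(f) f[-(1:2)])
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(tab) == 0) abort(paste0("empty complex file: ", path))
    if (ncol(tab) < 2) {
      abort(paste0("malformed TSV ", path, ": need complex_id and protein_id columns"))
    }
    names(tab)[1:2] <- c("complex_id", "protein_id")
    bad <- which(is.na(tab$complex_id) | is.na(tab$protein_id))
    if (length(bad) > 0) {
      abort(paste0("malformed TSV line ", bad[1] + 1, " in ", path,
                   ": missing complex_id or protein_id"))
    }
    ids <- unique(as.character(tab$complex_id))
    mem <- split(as.character(tab$protein_id), factor(tab$complex_id, levels = ids))
    src <- if ("source" %in% names(tab)) {
      vapply(split(as.character(tab$source), factor(tab$complex_id, levels = ids)),
             `[[`, character(1), 1)
    } else {
      rep(source, length(ids))
    }
    complex_resource(ids, ids, src, unname(mem))
  }
}

#' Write a complex resource as a GMT file
#'
#' @param resource A [complex_resource()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes_gmt <- function(resource, path) {
  lines <- mapply(function(id, nm, mem) {
    paste(c(id, nm, mem), collapse = "\t")
  }, resource$complex_id, resource$name, resource$members)
  writeLines(lines, path)
  invisible(path)
}

#' Protein-to-complex index
#'
#' The exact inverse of complex membership: one row per (protein, complex)
#' incidence, in resource order. A protein belonging to several complexes
#' appears once per complex.
#'
#' @param resource A [complex_resource()] tibble.
#' @return A tibble with columns `protein` and `complex_id`.
#' @export
complex_index <- function(resource) {
  tibble(
    protein = unlist(resource$members, use.names = FALSE),
    complex_id = rep(resource$complex_id, lengths(resource$members))
  )
}

#' Remove redundant complexes by greedy overlap filtering
#'
#' Complexes smaller than `min_members` are removed first. The remainder are
#' ranked by source (`manual` < `compleat` < `corum` < `user`), then by member
#' count (largest first), then lexicographically by `complex_id`. A single
#' greedy pass keeps the highest-ranked complex and drops every lower-ranked
#' complex that shares at least `overlap_threshold` of *its own* members with
#' any complex already kept (so near-subsets of a representative are removed).
#'
#' @param resource A [complex_resource()] tibble.
#' @param overlap_threshold Shared-member fraction (of the candidate's
#'   members) at or above which a candidate is removed. Default 0.5.
#' @param min_members Minimum complex size retained. Default 5.
#' @return The kept complexes, in rank order.
#' @export
filter_redundant <- function(resource, overlap_threshold = 0.5, min_members = 5) {
  if (!(overlap_threshold > 0 && overlap_threshold <= 1)) {
    abort("overlap_threshold must be in (0, 1]")
  }
  res <- resource[lengths(resource$members) >= min_members, , drop = FALSE]
  if (nrow(res) == 0) return(validate_complex_resource(res))
  rank_src <- match(res$source, complex_sources)
  ord <- order(rank_src, -lengths(res$members), res$complex_id)
  res <- res[ord, , drop = FALSE]
  kept <- logical(nrow(res))
  kept_members <- list()
  for (i in seq_len(nrow(res))) {
    cand <- res$members[[i]]
    redundant <- any(vapply(kept_members, function(km) {
      length(intersect(km, cand)) / length(cand) >= overlap_threshold
    }, logical(1)))
    if (!redundant) {
      kept[i] <- TRUE
      kept_members[[length(kept_members) + 1]] <- cand
    }
  }
  validate_complex_resource(res[kept, , drop = FALSE])
}

#' Generate size-preserving decoy complexes
#'
#' Builds a null resource by randomly permuting the concatenated membership
#' list and re-cutting it into complexes of the original sizes. The multiset
#' of protein occurrences and the vector of complex sizes are preserved
#' exactly; within-complex duplicates are repaired by swapping the duplicate
#' with a random position elsewhere in the assignment until every complex is
#' duplicate-free.
#'
#' @param resource A [complex_resource()] tibble.
#' @param seed Integer seed; the same seed yields identical decoys.
#' @return A `complex_resource` with the same ids, names and sources but
#'   permuted memberships.
#' @export
generate_decoys <- function(resource, seed = 1L) {
  if (nrow(resource) == 0) abort("cannot build decoys from an empty resource")
  sizes <- lengths(resource$members)
  pool <- unlist(resource$members, use.names = FALSE)
  if (max(table(pool)) > nrow(resource)) {
    abort("a protein occurs in more complexes than exist; duplicate-free decoys impossible")
  }
  with_seed(seed, {
    perm <- sample(pool)
    idx_complex <- rep(seq_along(sizes), sizes)
    max_iter <- 100L * length(perm)
    for (iter in seq_len(max_iter)) {
      dup_pos <- which(stats::ave(seq_along(perm), idx_complex, perm,
                                  FUN = seq_along) > 1)
      if (length(dup_pos) == 0) break
      for (p in dup_pos) {
        q <- sample.int(length(perm), 1)
        tmp <- perm[p]; perm[p] <- perm[q]; perm[q] <- tmp
      }
    }
    if (length(dup_pos) > 0 &&
        any(stats::ave(seq_along(perm), idx_complex, perm, FUN = seq_along) > 1)) {
      abort("decoy generation did not converge to a duplicate-free assignment")
    }
    out <- resource
    out$members <- unname(split(perm, idx_complex))
    validate_complex_resource(out)
  })
}

#' Map complex members through an ortholog table
#'
#' Each member is replaced by its mapped identifier(s); unmapped members are
#' dropped, one-to-many mappings expand to all targets, and memberships are
#' re-deduplicated. Complexes left with no members are removed.
#'
#' @param resource A [complex_resource()] tibble.
#' @param ortholog_table Data frame whose first two columns are source and
#'   target identifiers (possibly partial and one-to-many).
#' @return A mapped `complex_resource`.
#' @export
map_orthologs <- function(resource, ortholog_table) {
  stopifnot(is.data.frame(ortholog_table), ncol(ortholog_table) >= 2)
  from <- as.character(ortholog_table[[1]])
  to <- as.character(ortholog_table[[2]])
  targets <- split(to, from)
  out <- resource
  out$members <- lapply(resource$members, function(mem) {
    unique(unlist(targets[intersect(mem, names(targets))], use.names = FALSE))
  })
  out <- out[lengths(out$members) > 0, , drop = FALSE]
  validate_complex_resource(out)
}

#' Restrict a resource to quantified proteins
#'
#' Intersects every complex with the set of quantified protein identifiers and
#' drops complexes with fewer than `min_members` surviving members (the
#' "at least five quantified members" rule).
#'
#' @param resource A [complex_resource()] tibble.
#' @param quantified Character vector of quantified protein identifiers.
#' @param min_members Minimum surviving members. Default 5.
#' @return The restricted `complex_resource`.
#' @export
restrict_to_quantified <- function(resource, quantified, min_members = 5) {
  quantified <- as.character(quantified)
  out <- resource
  out$members <- lapply(resource$members, intersect, y = quantified)
  out <- out[lengths(out$members) >= min_members, , drop = FALSE]
  validate_complex_resource(out)
}
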