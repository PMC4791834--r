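# Internal helpers shared across modules.

# Convert a wide expression tibble (first column `protein`, remaining columns
# numeric samples) to a base matrix with protein rownames.
em_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"protein" %in% names(x)) {
    abort("expression table must have a `protein` column")
  }
  prot <- as.character(x$protein)
  if (anyDuplicated(prot)) {
    dup <- unique(prot[duplicated(prot)])
    abort(paste0(
      "duplicated protein ids: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  m <- as.matrix(x[setdiff(names(x), "protein")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- prot
  m
}

# Inverse of em_matrix().
em_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "protein")
}

# Check that a design tibble matches the sample columns of a wide matrix and
# return it with sample_id as character, ordered like the matrix columns.
check_design <- function(x, design) {
  required <- c("sample_id", "condition", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  design <- dplyr::mutate(design,
    sample_id = as.character(.data$sample_id),
    condition = as.character(.data$condition)
  )
  if (anyDuplicated(design[c("condition", "replicate")])) {
    abort("design rows must be unique in (condition, replicate)")
  }
  samples <- setdiff(names(x), "protein")
  extra_x <- setdiff(samples, design$sample_id)
  extra_d <- setdiff(design$sample_id, samples)
  if (length(extra_x) || length(extra_d)) {
    abort(paste0(
      "design/sample mismatch; in matrix only: [",
      paste(extra_x, collapse = ", "), "]; in design only: [",
      paste(extra_d, collapse = ", "), "]"
    ))
  }
  design[match(samples, design$sample_id), , drop = FALSE]
}

# Seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        suppressWarnings(rm(".Random.seed", envir = globalenv())),
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}
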