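#' Read and validate a pipeline configuration
#'
#' The YAML configuration names every analysis threshold (one key per
#' methods parameter) and either a `synthetic:` block (generator parameters)
#' or an `inputs:` block (paths to matrix/design/complex/paralog/transcript
#' tables). Defaults mirror the reference analysis: `member_alpha` 0.05,
#' `complex_threshold` 0.20, `fc_floor` 0.5, `mirna_alpha` 0.01,
#' `overlap_threshold` 0.5, `min_members` 5, `trim_fraction` 0.2.
#'
#' @param path YAML file path, or a list already holding the configuration.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    member_alpha = 0.05, complex_threshold = 0.20, fc_floor = 0.5,
    mirna_alpha = 0.01, overlap_threshold = 0.5, min_members = 5,
    trim_fraction = 0.2, seed = 1, min_reps = 1, decoy_seeds = 20
  )
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  check_range <- function(name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- config[[name]]
    ok <- is.numeric(v) && length(v) == 1 &&
      (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok) abort(paste0("config: ", name, " out of range [", lo, ", ", hi, "]"))
  }
  check_range("member_alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range("complex_threshold", 0, 1)
  check_range("fc_floor", 0, Inf)
  check_range("mirna_alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range("overlap_threshold", 0, 1, lo_open = TRUE)
  check_range("min_members", 2, Inf)
  check_range("trim_fraction", 0, 0.5, hi_open = TRUE)
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) abort(paste0("config input file not found: ", f))
    }
  }
  class(config) <- c("pipeline_config", "list")
  config
}

pipeline_provenance <- function(config) {
  paste0("# stoichiovar ",
         as.character(utils::packageVersion("stoichiovar")),
         " | config_hash=", rlang::hash(unclass(config)),
         " | seed=", config$seed)
}

write_stage_tsv <- function(tab, path, header) {
  writeLines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full stoichiometry pipeline
#'
#' Executes the stages in dependency order — resource construction,
#' preprocessing, complex-wise normalization, member/complex calling, paralog
#' switch detection, transcriptional classification, signature evaluation and
#' the decoy benchmark — and writes six artifacts to `out_dir`: `calls.tsv`,
#' `switches.tsv`, `regulation.tsv`, `signature_eval.tsv`,
#' `decoy_benchmark.tsv` and `run.log`. Every TSV carries a provenance
#' header (package version, config hash, seed); reruns with the same config
#' are byte-identical.
#'
#' @param config A [read_pipeline_config()] result, a YAML path, or a list.
#'   With a `synthetic:` block (possibly empty) all inputs are generated
#'   in-package with planted truth; otherwise `inputs:` paths are read.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    config <- read_pipeline_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  header <- pipeline_provenance(config)
  note(header)

  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    note("stage inputs: synthetic generation, seed ", config$seed)
    gr <- generate_resource(
      n_complexes = sy$n_complexes %||% 50,
      n_proteins = sy$n_proteins %||% 900,
      multi_membership_rate = sy$multi_membership_rate %||% 0.1,
      seed = config$seed
    )
    pr <- generate_proteome(
      gr$resource,
      n_conditions = sy$n_conditions %||% 8,
      n_replicates = sy$n_replicates %||% 3,
      variable_fraction = sy$variable_fraction %||% 0.22,
      effect_size = sy$effect_size %||% 1,
      noise_sd = sy$noise_sd %||% 0.25,
      seed = config$seed
    )
    pr <- generate_paralog_switches(pr, n_pairs = sy$n_pairs %||% 10,
                                    seed = config$seed)
    tr <- generate_transcriptome(pr, seed = config$seed)
    co <- generate_cohort(seed = config$seed)
    x <- pr$x; design <- pr$design; resource <- pr$resource
    pairs <- pr$pairs
    mrna <- tr$mrna; mirna <- tr$mirna; targets <- tr$targets
    mapping <- tr$mapping
    cohort_raw <- co$raw; cohort_groups <- co$groups
    signature_pool <- NULL
  } else {
    ins <- config$inputs
    if (is.null(ins$matrix) || is.null(ins$design) || is.null(ins$complexes)) {
      abort("config inputs must name matrix, design and complexes files")
    }
    note("stage inputs: reading user files")
    x <- read_expr_matrix(ins$matrix, log2_transform = isTRUE(ins$log2))
    design <- read_sample_design(ins$design)
    resource <- read_complexes(ins$complexes)
    pairs <- if (!is.null(ins$pairs)) {
      readr::read_tsv(ins$pairs, show_col_types = FALSE, progress = FALSE)
    }
    mrna <- if (!is.null(ins$mrna)) {
      readr::read_tsv(ins$mrna, show_col_types = FALSE, progress = FALSE)
    }
    mirna <- if (!is.null(ins$mirna)) {
      readr::read_tsv(ins$mirna, show_col_types = FALSE, progress = FALSE)
    }
    targets <- if (!is.null(ins$targets)) {
      readr::read_tsv(ins$targets, show_col_types = FALSE, progress = FALSE)
    }
    mapping <- if (!is.null(ins$mapping)) {
      readr::read_tsv(ins$mapping, show_col_types = FALSE, progress = FALSE)
    }
    cohort_raw <- if (!is.null(ins$cohort)) {
      readr::read_tsv(ins$cohort, show_col_types = FALSE, progress = FALSE)
    }
    cohort_groups <- if (!is.null(ins$groups)) {
      readr::read_tsv(ins$groups, show_col_types = FALSE, progress = FALSE)
    }
    signature_pool <- if (!is.null(ins$signature)) readLines(ins$signature)
  }

  note("stage resource: redundancy filter at overlap ",
       config$overlap_threshold, ", min members ", config$min_members)
  resource <- filter_redundant(resource, config$overlap_threshold,
                               config$min_members)
  note("  kept ", nrow(resource), " complexes")

  note("stage preprocess: median centering")
  x <- median_center(x)
  if (config$min_reps > 1) {
    x <- filter_by_replication(x, design, config$min_reps)
    note("  replication filter kept ", nrow(x), " proteins")
  }

  note("stage calls: complex-wise normalization and moderated testing")
  calls <- run_member_pipeline(
    x, design, resource,
    trim_fraction = config$trim_fraction,
    member_alpha = config$member_alpha,
    complex_threshold = config$complex_threshold,
    min_members = config$min_members
  )
  g <- glance(calls)
  note("  ", g$n_variable_members, "/", g$n_members, " variable members; ",
       g$n_variable_complexes, "/", g$n_complexes, " variable complexes")
  write_stage_tsv(tidy(calls), file.path(out_dir, "calls.tsv"), header)

  if (!is.null(pairs)) {
    note("stage paralog: switch classification")
    sw <- classify_switches(find_coregulated_pairs(calls, pairs,
                                                   config$member_alpha))
    write_stage_tsv(sw$conditions, file.path(out_dir, "switches.tsv"), header)
  } else {
    note("stage paralog: skipped (no pair table)")
    write_stage_tsv(tibble(), file.path(out_dir, "switches.tsv"), header)
  }

  if (!is.null(mrna) && !is.null(mapping)) {
    note("stage regulation: transcriptional classification")
    reg <- classify_regulation(calls, mrna, mapping,
                               fc_floor = config$fc_floor,
                               alpha = config$member_alpha)
    if (!is.null(mirna) && !is.null(targets)) {
      reg <- link_mirna(reg, mirna, targets, config$mirna_alpha)
    }
    write_stage_tsv(reg, file.path(out_dir, "regulation.tsv"), header)
  } else {
    note("stage regulation: skipped (no transcript inputs)")
    reg <- NULL
    write_stage_tsv(tibble(), file.path(out_dir, "regulation.tsv"), header)
  }

  if (!is.null(cohort_raw) && !is.null(cohort_groups)) {
    note("stage signature: nearest-centroid evaluation")
    cohort <- preprocess_cohort(cohort_raw, cohort_groups)
    if (is.null(signature_pool)) {
      if (!is.null(config$synthetic)) signature_pool <- co$truth$protein[co$truth$is_signature]
    }
    sig_eval <- feature_sampling_eval(cohort, signature_pool,
                                      n_samples = config$n_feature_samples %||% 100,
                                      seed = config$seed)
    write_stage_tsv(tidy(sig_eval), file.path(out_dir, "signature_eval.tsv"),
                    header)
  } else {
    note("stage signature: skipped (no cohort inputs)")
    sig_eval <- NULL
    write_stage_tsv(tibble(), file.path(out_dir, "signature_eval.tsv"), header)
  }

  note("stage decoy: benchmark over ", config$decoy_seeds, " decoy seeds")
  bench <- decoy_benchmark(
    x, design, resource, n_seeds = config$decoy_seeds, seed = config$seed,
    trim_fraction = config$trim_fraction,
    member_alpha = config$member_alpha,
    complex_threshold = config$complex_threshold,
    min_members = config$min_members
  )
  write_stage_tsv(dplyr::select(bench, -"decoy_counts"),
                  file.path(out_dir, "decoy_benchmark.tsv"), header)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(calls = calls, bench = bench,
                 regulation = reg, signature_eval = sig_eval,
                 resource = resource, config = config))
}
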