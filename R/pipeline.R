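#' Run configuration
#'
#' All analysis parameters with their standard defaults: log2 pseudocount
#' 1e-3, FDR alpha 0.05, motif-calling p-value threshold 2.5e-3, trim
#' fraction 0.2, scrambled percentiles 5/95, residual band percentile 80,
#' DNA floor 5 RPM, three replicates. The simulate block defines the
#' default synthetic study: 1000 CREs, 100 scrambled controls, 100
#' two-site cooperativity quads, depth 1e6, six genotypes.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param ... Named overrides merged into the defaults (top-level keys, or
#'   lists merged one level deep for `simulate`/`params`).
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genotypes = GENOTYPES,
    reference = "wt",
    conversion_genotypes = c("E168d2_hom", "null"),
    paths = list(design = NULL, counts = NULL, sample_sheet = NULL),
    simulate = list(enabled = TRUE, n_cres = 1000L, n_scrambled = 100L,
                    n_coop = 100L, depth = 1e6, dna_depth = 1e7,
                    replicates = 3L, dna_dispersion = 0.5),
    params = list(pseudocount = 1e-3, alpha = 0.05, trim_fraction = 0.2,
                  fimo_p = 2.5e-3, min_dna_rpm = 5, min_effect = 0.1,
                  n_boot = 200L, percentiles = c(5, 95),
                  band_percentile = 80)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip losslessly through the flat YAML file.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1L)
  for (nm in setdiff(names(cfg), "seed")) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Run the full MPRA analysis pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> classify -> compare ->
#' score -> cooperativity. Deterministic given the configuration seed.
#' When `out_dir` is given, writes the activity, classification,
#' comparison, conversion, scoring and cooperativity tables as TSV plus a
#' machine-readable JSON run manifest recording seeds, parameters,
#' versions and filtering counts.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Optional output directory.
#' @return List (invisible when writing) with design, truth (synthetic
#'   runs), counts, activity, classes, comparisons, comparison_summary,
#'   converted_all/converted_any, scores, coop, manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  p <- config$params
  sim <- isTRUE(config$simulate$enabled)
  if (!sim && (is.null(config$paths$counts) ||
               is.null(config$paths$design))) {
    stop("config must enable simulation or provide counts and design paths",
         call. = FALSE)
  }
  truth <- NULL
  if (sim) {
    s <- config$simulate
    design <- build_synthetic_design(
      n_cres = s$n_cres, n_scrambled = s$n_scrambled, n_coop = s$n_coop,
      rng_seed = child_seed(config$seed, 1L), p_threshold = p$fimo_p)
    truth <- simulate_true_activities(design,
                                      rng_seed = child_seed(config$seed, 2L))
    cnt <- simulate_counts(truth, design, depth = s$depth,
                           replicates = s$replicates,
                           dna_depth = s$dna_depth,
                           dna_dispersion = s$dna_dispersion,
                           rng_seed = child_seed(config$seed, 3L))
    counts <- cnt$counts
    sample_sheet <- cnt$sample_sheet
  } else {
    design <- read_design(config$paths$design)
    counts <- as_tibble(utils::read.delim(config$paths$counts,
                                          check.names = FALSE))
    sample_sheet <- as_tibble(utils::read.delim(config$paths$sample_sheet))
  }

  activity <- compute_activity(counts, sample_sheet, design,
                               min_dna_rpm = p$min_dna_rpm,
                               pseudocount = p$pseudocount)
  classes <- classify_elements(activity, design, alpha = p$alpha,
                               percentiles = p$percentiles)

  genotypes <- intersect(config$genotypes,
                         unique(activity$elements$genotype))
  reference <- config$reference
  comparisons <- list()
  for (g in setdiff(genotypes, reference)) {
    comparisons[[g]] <- compare_genotypes(
      activity, classes, design, reference, g,
      trim_fraction = p$trim_fraction,
      band_percentile = p$band_percentile)
  }
  comparison_summary <- dplyr::bind_rows(lapply(comparisons, function(cmp) {
    tibble(reference = cmp$reference, test = cmp$test, slope = cmp$slope,
           intercept = cmp$intercept, r_squared = cmp$r_squared,
           residual_band = cmp$residual_band,
           n_lost_enhancers = length(cmp$lost_enhancer_ids),
           n_amplified_weak = length(cmp$amplified_weak_enhancer_ids),
           n_converted = length(cmp$converted_silencer_ids),
           n_excluded = cmp$n_excluded)
  }))
  conv_genos <- intersect(config$conversion_genotypes, genotypes)
  converted_all <- converted_any <- character(0)
  if (length(conv_genos)) {
    converted_all <- find_converted_silencers(classes, reference,
                                              conv_genos,
                                              require_all = TRUE)
    converted_any <- find_converted_silencers(classes, reference,
                                              conv_genos,
                                              require_all = FALSE)
  }

  motif_set <- if (length(design$motif_models) &&
                   "CRX" %in% names(design$motif_models)) {
    design$motif_models
  } else {
    default_motif_set()
  }
  scores <- score_sequences(design, motif_set)

  coop_records <- cooperativity_records(
    activity, design, genotypes = genotypes,
    rng_seed = child_seed(config$seed, 4L),
    min_effect = p$min_effect, n_boot = p$n_boot)
  coop_summary <- if (nrow(coop_records)) {
    cooperativity_sweep(coop_records)
  } else {
    NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("crxmpra")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameter_hash = rlang::hash(config[c("params", "simulate",
                                          "genotypes", "reference")]),
    genotypes = genotypes,
    reference = reference,
    replicates = if (sim) config$simulate$replicates else
      max(sample_sheet$replicate, na.rm = TRUE),
    n_elements = nrow(design$elements),
    n_barcodes = nrow(design$barcode_map),
    n_barcodes_excluded_dna_floor =
      sum(!activity$barcodes$used[!duplicated(activity$barcodes$barcode)]),
    n_elements_missing =
      sum(activity$elements$missing[!duplicated(
        activity$elements$element_id)]),
    n_unclassified = sum(is.na(classes$class))
  )

  result <- list(design = design, truth = truth, counts = counts,
                 sample_sheet = sample_sheet, activity = activity,
                 classes = classes, comparisons = comparisons,
                 comparison_summary = comparison_summary,
                 converted_all = converted_all,
                 converted_any = converted_any, scores = scores,
                 coop_records = coop_records, coop_summary = coop_summary,
                 manifest = manifest, config = config)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

# Write all canonical pipeline tables + manifest to a directory.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design(result$design, file.path(out_dir, "design"))
  write_tsv_plain(result$counts, file.path(out_dir, "counts.tsv"))
  write_tsv_plain(result$sample_sheet, file.path(out_dir, "sample_sheet.tsv"))
  write_tsv_plain(result$activity$elements, file.path(out_dir, "activity.tsv"))
  write_tsv_plain(result$classes, file.path(out_dir, "classification.tsv"))
  if (nrow(result$comparison_summary %||% tibble())) {
    write_tsv_plain(result$comparison_summary,
                    file.path(out_dir, "comparisons.tsv"))
    trans <- dplyr::bind_rows(lapply(result$comparisons, function(cmp) {
      df <- as.data.frame(cmp$transition_matrix)
      names(df) <- c("reference_class", "test_class", "n")
      df$test <- cmp$test
      df
    }))
    write_tsv_plain(trans, file.path(out_dir, "transitions.tsv"))
  }
  writeLines(result$converted_all, file.path(out_dir, "converted_ids.txt"))
  write_tsv_plain(result$scores, file.path(out_dir, "scores.tsv"))
  if (nrow(result$coop_records)) {
    write_tsv_plain(result$coop_records,
                    file.path(out_dir, "cooperativity.tsv"))
  }
  if (!is.null(result$truth)) {
    write_tsv_plain(result$truth$activities,
                    file.path(out_dir, "ground_truth.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_config(result$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
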