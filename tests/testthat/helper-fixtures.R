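# Shared fixtures, built in code at test time.

# Sharp probability matrix from a consensus string (test-local builder,
# independent of the package's internal constructor).
sharp_prob <- function(consensus, p_match = 0.997) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  m <- matrix((1 - p_match) / 3, length(idx), 4,
              dimnames = list(NULL, bases))
  for (k in seq_along(idx)) m[k, idx[k]] <- p_match
  m
}

toy_taatcc <- function() motif_model("toyCRX", sharp_prob("TAATCC"))

# Medium synthetic dataset reused across test files (built once per run).
.fixtures <- new.env()

medium_run <- function() {
  if (is.null(.fixtures$med)) {
    design <- build_synthetic_design(150, n_scrambled = 40, n_coop = 8,
                                     rng_seed = 101)
    truth <- simulate_true_activities(design, rng_seed = 102)
    cnt <- simulate_counts(truth, design, depth = 3e5, dna_depth = 3e6,
                           replicates = 3, rng_seed = 103)
    activity <- compute_activity(cnt$counts, cnt$sample_sheet, design)
    classes <- classify_elements(activity, design)
    .fixtures$med <- list(design = design, truth = truth, counts = cnt,
                          activity = activity, classes = classes)
  }
  .fixtures$med
}

# Tiny hand-built design: n wild-type elements (4 barcodes each) + basal
# (16 barcodes). Sequences are arbitrary valid DNA.
micro_design <- function(n = 3, ids = sprintf("EL%02d", seq_len(n)),
                         variant = rep("wild_type", n)) {
  elements <- tibble::tibble(
    element_id = c(ids, "BASAL"),
    sequence = c(vapply(seq_len(n), function(i) {
      paste(rep(c("A", "C", "G", "T"), 5)[1:20], collapse = "")
    }, character(1)), NA_character_),
    variant_class = c(variant, "basal"),
    parent_id = NA_character_
  )
  barcode_map <- tibble::tibble(
    barcode = make_barcodes(4L * n + 16L),
    element_id = rep(elements$element_id, c(rep(4L, n), 16L))
  )
  library_design(elements, barcode_map)
}
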