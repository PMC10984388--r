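#' Normalize barcode counts to reads per million
#'
#' @param counts Tibble or data frame with a `barcode` column and one
#'   numeric column per sample.
#' @return The same table with each sample column scaled so it sums to
#'   1e6. An all-zero sample is an error naming the sample.
#' @export
rpm_normalize <- function(counts) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "barcode")
  for (s in samples) {
    total <- sum(counts[[s]])
    if (!is.finite(total) || total <= 0) {
      stop("sample '", s, "' has zero total counts", call. = FALSE)
    }
    counts[[s]] <- counts[[s]] / total * 1e6
  }
  counts
}

#' Compute per-element activities from RNA and DNA barcode counts
#'
#' Activity is the RNA/DNA ratio of RPM-normalised barcode counts.
#' Averaging follows ratio -> replicates -> barcodes: each barcode's
#' RNA/DNA ratio is computed per replicate, averaged across replicates,
#' and the element activity is the mean over its barcodes that pass the
#' DNA representation floor. Log2 activity uses the standard pseudocount
#' (default 1e-3).
#'
#' @param counts Raw count table (tibble: `barcode` + one column per
#'   sample).
#' @param sample_sheet Tibble with columns `sample`, `type`
#'   (`"DNA"`/`"RNA"`), `genotype`, `replicate` mapping count columns to
#'   samples. Multiple DNA samples are averaged.
#' @param design A `library_design`; RNA barcodes must be a subset of the
#'   design's barcodes and the DNA table must cover all of them.
#' @param min_dna_rpm Barcodes below this DNA RPM floor are excluded from
#'   element means (0 reproduces the unfiltered method; barcodes with
#'   zero DNA are always excluded since their ratio is undefined).
#' @param pseudocount Added inside log2.
#' @return Object of class `activity_table`: list with `elements`
#'   (element_id, genotype, activity, log2_activity, n_barcodes_used,
#'   missing), `barcodes` (per-barcode replicate-averaged ratios and
#'   their log2 values, used flag), `replicates` (per-replicate element
#'   means) plus the parameters used.
#' @export
compute_activity <- function(counts, sample_sheet, design,
                             min_dna_rpm = 5, pseudocount = 1e-3) {
  sample_sheet <- as_tibble(sample_sheet)
  stopifnot(all(c("sample", "type", "genotype", "replicate")
                %in% names(sample_sheet)),
            all(sample_sheet$sample %in% names(counts)))
  rpm <- rpm_normalize(counts)
  bm <- design$barcode_map
  if (!all(counts$barcode %in% bm$barcode)) {
    stop("count table contains barcodes absent from the design",
         call. = FALSE)
  }
  dna_samples <- sample_sheet$sample[sample_sheet$type == "DNA"]
  if (length(dna_samples) == 0L) stop("no DNA sample in sample sheet")
  if (!all(bm$barcode %in% rpm$barcode)) {
    stop("DNA table must cover all design barcodes", call. = FALSE)
  }
  ord <- match(bm$barcode, rpm$barcode)
  dna_rpm <- rowMeans(as.matrix(rpm[ord, dna_samples, drop = FALSE]))
  usable <- dna_rpm >= max(min_dna_rpm, .Machine$double.eps) & dna_rpm > 0

  rna_sheet <- sample_sheet[sample_sheet$type == "RNA", ]
  genotypes <- unique(rna_sheet$genotype)

  bc_rows <- list()
  rep_rows <- list()
  el_rows <- list()
  for (g in genotypes) {
    g_samples <- rna_sheet$sample[rna_sheet$genotype == g]
    g_reps <- rna_sheet$replicate[rna_sheet$genotype == g]
    ratios <- as.matrix(rpm[ord, g_samples, drop = FALSE]) / dna_rpm
    mean_ratio <- rowMeans(ratios)
    bc <- tibble(
      element_id = bm$element_id, genotype = g, barcode = bm$barcode,
      dna_rpm = dna_rpm, mean_ratio = mean_ratio,
      log2_ratio = log2(mean_ratio + pseudocount), used = usable
    )
    bc_rows[[g]] <- bc
    for (j in seq_along(g_samples)) {
      rep_means <- tapply(ratios[usable, j], bm$element_id[usable], mean)
      rep_rows[[paste(g, j)]] <- tibble(
        element_id = names(rep_means), genotype = g,
        replicate = g_reps[j], activity = as.numeric(rep_means)
      )
    }
    el_act <- tapply(mean_ratio[usable], bm$element_id[usable], mean)
    n_used <- table(bm$element_id[usable])
    el <- tibble(element_id = design$elements$element_id, genotype = g)
    el$activity <- as.numeric(el_act[el$element_id])
    el$n_barcodes_used <- as.integer(n_used[el$element_id])
    el$n_barcodes_used[is.na(el$n_barcodes_used)] <- 0L
    el$missing <- el$n_barcodes_used == 0L
    el$log2_activity <- log2(el$activity + pseudocount)
    el_rows[[g]] <- el
  }
  structure(
    list(elements = dplyr::bind_rows(el_rows),
         barcodes = dplyr::bind_rows(bc_rows),
         replicates = dplyr::bind_rows(rep_rows),
         pseudocount = pseudocount, min_dna_rpm = min_dna_rpm),
    class = "activity_table"
  )
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf(paste0("<activity_table> %d elements x %d genotypes ",
                     "(pseudocount %g, DNA floor %g RPM)\n"),
              length(unique(x$elements$element_id)),
              length(unique(x$elements$genotype)),
              x$pseudocount, x$min_dna_rpm))
  invisible(x)
}
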