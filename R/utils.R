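#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param sequence Character scalar over A/C/G/T.
#' @return Character scalar, the reverse complement.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  comp <- chartr("ACGTacgt", "TGCAtgca", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Encode a DNA string as integers 1..4 (A,C,G,T); errors on anything else,
# naming the first offending position (no silent N-handling).
encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("non-ACGT symbol '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  idx
}

# Random DNA string of length n with the given base composition.
random_dna <- function(n, composition = rep(0.25, 4)) {
  stopifnot(length(composition) == 4L, all(composition >= 0))
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition),
        collapse = "")
}

# Mononucleotide composition of one or more sequences (pooled).
base_composition <- function(sequences) {
  chars <- unlist(strsplit(toupper(paste(sequences, collapse = "")), "",
                           fixed = TRUE))
  counts <- table(factor(chars, levels = DNA_BASES))
  as.numeric(counts) / sum(counts)
}

# Substring replacement keeping total length.
replace_substring <- function(sequence, start, replacement) {
  end <- start + nchar(replacement) - 1L
  stopifnot(start >= 1L, end <= nchar(sequence))
  paste0(substr(sequence, 1L, start - 1L), replacement,
         substr(sequence, end + 1L, nchar(sequence)))
}

# Derive a 32-bit-safe child seed from a base seed and a stage offset.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
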