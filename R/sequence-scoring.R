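#' Motif scanning and sequence scoring
#'
#' The scan uses log2-odds scores discretised into fixed-width bins; the
#' null distribution of the window score under the background model is
#' computed exactly by dynamic programming over the discretised score
#' distribution, so each occurrence's p-value `Pr(score >= observed)` is
#' exact up to the discretisation. Minus-strand windows are scored as the
#' reverse complement of the plus-strand text under the same null.
#'
#' @name sequence-scoring
NULL

# Cache of null score distributions, keyed by motif content + bin width.
.score_dp_cache <- new.env(parent = emptyenv())

# Integer (binned) log2-odds score matrix for a motif.
motif_int_scores <- function(motif, bin) {
  lo <- log2(motif$prob / matrix(motif$background, motif$length, 4,
                                 byrow = TRUE))
  round(lo / bin)
}

# Exact null distribution of the binned window score: returns list with
# `min` (smallest achievable integer score) and `sf`, where sf[i] =
# Pr(score >= min + i - 1) under iid background bases.
score_null_sf <- function(motif, bin) {
  key <- rlang::hash(list(motif$prob, motif$background, bin))
  hit <- .score_dp_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- motif_int_scores(motif, bin)
  mins <- apply(s, 1L, min)
  maxs <- apply(s, 1L, max)
  width <- sum(maxs - mins) + 1L
  dist <- numeric(width)
  dist[1L] <- 1
  filled <- 1L
  bg <- motif$background
  for (k in seq_len(motif$length)) {
    offs <- s[k, ] - mins[k]
    span <- filled + max(offs)
    new <- numeric(width)
    for (b in 1:4) {
      o <- offs[b]
      new[(1L + o):(filled + o)] <- new[(1L + o):(filled + o)] +
        bg[b] * dist[1:filled]
    }
    dist <- new
    filled <- span
  }
  out <- list(min = sum(mins), sf = rev(cumsum(rev(dist))))
  .score_dp_cache[[key]] <- out
  out
}

# Binned scores of all windows of `idx` (integer-encoded sequence) under the
# integer score matrix `s` (K x 4).
window_int_scores <- function(idx, s) {
  K <- nrow(s)
  nw <- length(idx) - K + 1L
  if (nw < 1L) return(integer(0))
  sc <- integer(nw)
  for (k in seq_len(K)) {
    sc <- sc + s[k, idx[k:(k + nw - 1L)]]
  }
  unname(sc)
}

# p-values for integer window scores given a null survival function.
int_score_pvalues <- function(scores, null) {
  i <- scores - null$min + 1L
  i <- pmin(pmax(i, 1L), length(null$sf))
  null$sf[i]
}

#' Scan a sequence for motif occurrences with exact p-values
#'
#' Scans both strands and reports windows whose score p-value (probability
#' of an equal or larger log-odds score under the background model,
#' computed exactly by dynamic programming) is at or below `p_threshold`.
#'
#' @param sequence DNA string (A/C/G/T only; anything else is an error
#'   naming the offending position).
#' @param motif A [motif_model()].
#' @param p_threshold Occurrences with `p <= p_threshold` are reported.
#'   The field-standard threshold for calling CRX sites is 2.5e-3.
#' @param bin Width of the log2-odds discretisation bins.
#' @return Tibble with columns `position` (1-based plus-strand start of the
#'   window), `strand` ("+"/"-"), `score` (log2-odds) and `p_value`,
#'   sorted by position.
#' @export
scan_motif <- function(sequence, motif, p_threshold = 2.5e-3, bin = 1e-4) {
  stopifnot(p_threshold >= 0, p_threshold <= 1)
  idx <- encode_dna(sequence)
  if (length(idx) < motif$length) {
    stop("sequence shorter than motif", call. = FALSE)
  }
  null <- score_null_sf(motif, bin)
  s_fwd <- motif_int_scores(motif, bin)
  # Minus strand: score of the reverse-complemented window under the motif.
  s_rev <- s_fwd[rev(seq_len(nrow(s_fwd))), c(4L, 3L, 2L, 1L), drop = FALSE]
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s_fwd else s_rev
    sc <- window_int_scores(idx, s)
    p <- int_score_pvalues(sc, null)
    keep <- which(p <= p_threshold)
    if (length(keep)) {
      hits[[strand]] <- tibble(
        position = keep, strand = strand,
        score = sc[keep] * bin, p_value = p[keep]
      )
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else {
    tibble(position = integer(0), strand = character(0),
           score = numeric(0), p_value = numeric(0))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Predicted TF occupancy of a sequence from an energy weight matrix
#'
#' Threshold-free occupancy: every K-mer window on both strands is assigned
#' a binding energy `E = sum_k ewm[k, base_k]` and a logistic binding
#' probability `p = 1 / (1 + exp(E - mu))`; probabilities are summed over
#' all windows to give the expected number of bound TF molecules on the
#' sequence.
#'
#' @inheritParams scan_motif
#' @param element_id Optional id recorded in the result.
#' @return List of class `occupancy_result` with `element_id`,
#'   `total_occupancy` and `per_position` (tibble: position, strand,
#'   energy, probability).
#' @export
predicted_occupancy <- function(sequence, motif, element_id = NA_character_) {
  idx <- encode_dna(sequence)
  if (length(idx) < motif$length) {
    stop("sequence shorter than motif", call. = FALSE)
  }
  e_fwd <- motif$ewm
  e_rev <- e_fwd[rev(seq_len(nrow(e_fwd))), c(4L, 3L, 2L, 1L), drop = FALSE]
  per <- lapply(c("+", "-"), function(strand) {
    ew <- if (strand == "+") e_fwd else e_rev
    K <- nrow(ew)
    nw <- length(idx) - K + 1L
    E <- numeric(nw)
    for (k in seq_len(K)) E <- E + ew[k, idx[k:(k + nw - 1L)]]
    E <- unname(E)
    tibble(position = seq_len(nw), strand = strand, energy = E,
           probability = 1 / (1 + exp(E - motif$mu)))
  })
  per <- dplyr::bind_rows(per)
  structure(
    list(element_id = element_id, total_occupancy = sum(per$probability),
         per_position = per),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> %s: total = %.3f over %d windows\n",
              x$element_id, x$total_occupancy, nrow(x$per_position)))
  invisible(x)
}

#' Boltzmann-entropy information content from per-TF occupancies
#'
#' The information content of a CRE is the log2 number of distinguishable
#' arrangements of its predicted TF occupancies `n_j` across motif
#' families: `IC = log2( Gamma(N+1) / prod_j Gamma(n_j+1) )` with
#' `N = sum n_j`. At integer occupancies this is the multinomial
#' microstate count `log2(N! / prod n_j!)`; the Gamma form extends it
#' continuously. `mode = "integer"` rounds occupancies first.
#'
#' @param n Named or unnamed non-negative numeric vector of per-TF
#'   occupancies.
#' @param mode `"continuous"` (default) or `"integer"`.
#' @return Numeric scalar (bits, >= 0). If all occupancies are zero the
#'   value is 0 and carries attribute `zero_occupancy = TRUE` (with a
#'   warning).
#' @export
boltzmann_ic <- function(n, mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(n)), all(n >= 0))
  if (mode == "integer") n <- round(n)
  N <- sum(n)
  if (N == 0) {
    warning("all per-TF occupancies are zero; information content is 0",
            call. = FALSE)
    return(structure(0, zero_occupancy = TRUE))
  }
  ic <- (lgamma(N + 1) - sum(lgamma(n + 1))) / log(2)
  max(ic, 0)
}

#' Information content of a sequence over a motif set
#'
#' Computes the predicted occupancy of each motif in `motif_set` (see
#' [predicted_occupancy()]) and summarises motif diversity as Boltzmann
#' information content via [boltzmann_ic()].
#'
#' @inheritParams predicted_occupancy
#' @param motif_set Named list of [motif_model()] objects (the standard set
#'   has 8 lineage-specific TF families, see [default_motif_set()]).
#' @param mode Passed to [boltzmann_ic()].
#' @return List of class `information_content` with `element_id`,
#'   `per_tf_occupancy` (named numeric) and `ic_bits`.
#' @export
information_content <- function(sequence, motif_set,
                                mode = c("continuous", "integer"),
                                element_id = NA_character_) {
  mode <- match.arg(mode)
  occ <- vapply(motif_set, function(m) {
    predicted_occupancy(sequence, m)$total_occupancy
  }, numeric(1))
  structure(
    list(element_id = element_id, per_tf_occupancy = occ,
         ic_bits = as.numeric(boltzmann_ic(occ, mode = mode))),
    class = "information_content"
  )
}

#' Score every element sequence in a design
#'
#' Convenience wrapper computing CRX predicted occupancy and information
#' content for all non-basal elements of a library design.
#'
#' @param design A `library_design` (see [build_synthetic_design()]).
#' @param motif_set Named list of motif models; the first entry named
#'   `"CRX"` (case-insensitive) is used for the occupancy column.
#' @param mode Passed to [boltzmann_ic()].
#' @return Tibble with columns `element_id`, `crx_occupancy`, `ic_bits`.
#' @export
score_sequences <- function(design, motif_set = default_motif_set(),
                            mode = "continuous") {
  el <- design$elements
  el <- el[!is.na(el$sequence), ]
  crx_name <- names(motif_set)[tolower(names(motif_set)) == "crx"][1]
  if (is.na(crx_name)) crx_name <- names(motif_set)[1L]
  res <- lapply(seq_len(nrow(el)), function(i) {
    occ <- vapply(motif_set, function(m) {
      predicted_occupancy(el$sequence[i], m)$total_occupancy
    }, numeric(1))
    tibble(element_id = el$element_id[i],
           crx_occupancy = occ[[crx_name]],
           ic_bits = as.numeric(suppressWarnings(boltzmann_ic(occ,
                                                              mode = mode))))
  })
  dplyr::bind_rows(res)
}
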