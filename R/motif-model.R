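#' Construct a motif model
#'
#' A `motif_model` couples a position probability matrix (used for log-odds
#' scanning with exact p-values) with an energy weight matrix (EWM, used for
#' threshold-free predicted occupancy). The EWM stores per-position energy
#' penalties relative to the optimal base (optimal base = 0 at every
#' position, in arbitrary energy units); together with the chemical
#' potential `mu` it yields a logistic binding probability per window,
#' `p = 1 / (1 + exp(E - mu))`.
#'
#' When `ewm` is not supplied it is derived from the probability matrix as
#' `ewm[k, b] = -ln(p[k, b] / max_b p[k, b])`. When `mu` is not supplied it
#' defaults to the value at which the consensus site (E = 0) is bound with
#' probability `consensus_occupancy` (default 0.99), i.e.
#' `mu = ln(p0 / (1 - p0))`.
#'
#' @param name Motif name (e.g. the TF or TF family it models).
#' @param prob K x 4 matrix of base probabilities, columns A, C, G, T; each
#'   row must sum to 1.
#' @param background Length-4 background base frequencies (sums to 1).
#' @param ewm Optional K x 4 energy penalty matrix (row minima must be 0).
#' @param mu Optional chemical potential (same units as `ewm`).
#' @param consensus_occupancy Occupancy of the consensus site used to set
#'   the default `mu`.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, prob, background = rep(0.25, 4), ewm = NULL,
                        mu = NULL, consensus_occupancy = 0.99) {
  prob <- as.matrix(prob)
  stopifnot(ncol(prob) == 4L, nrow(prob) >= 1L)
  colnames(prob) <- DNA_BASES
  if (any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop("each probability matrix row must sum to 1", call. = FALSE)
  }
  if (any(prob <= 0)) {
    stop("probability matrix entries must be strictly positive; ",
         "apply a pseudocount before constructing the model", call. = FALSE)
  }
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  if (is.null(ewm)) {
    ewm <- -log(prob / apply(prob, 1L, max))
  }
  ewm <- as.matrix(ewm)
  colnames(ewm) <- DNA_BASES
  stopifnot(nrow(ewm) == nrow(prob), ncol(ewm) == 4L)
  if (any(abs(apply(ewm, 1L, min)) > 1e-9) || any(ewm < 0)) {
    stop("ewm rows must be non-negative with minimum exactly 0",
         call. = FALSE)
  }
  if (is.null(mu)) {
    stopifnot(consensus_occupancy > 0, consensus_occupancy < 1)
    mu <- log(consensus_occupancy / (1 - consensus_occupancy))
  }
  structure(
    list(name = name, length = nrow(prob), prob = prob,
         background = as.numeric(background), ewm = ewm, mu = mu),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: K = %d, mu = %.3f\nconsensus: %s\n",
              x$name, x$length, x$mu, motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif (argmax base per position)
#'
#' @param motif A `motif_model`.
#' @return Character scalar of length K.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$prob, 1L, which.max)], collapse = "")
}

# Motif with the probability/energy matrices reversed and complemented,
# used to scan the minus strand of the plus-strand text.
motif_revcomp <- function(motif) {
  flip <- function(m) {
    m <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
    colnames(m) <- DNA_BASES
    m
  }
  out <- motif
  out$prob <- flip(motif$prob)
  out$ewm <- flip(motif$ewm)
  out$background <- rev(motif$background)
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME minimal-format file into
#' a named list of [motif_model()] objects. Zero probabilities are replaced
#' by `pseudo` and rows renormalised so models remain scannable.
#'
#' @param path Path to a MEME minimal motif file.
#' @param pseudo Pseudo-probability applied to zero entries.
#' @param ... Passed to [motif_model()] (e.g. `mu`).
#' @return Named list of `motif_model` objects.
#' @export
read_meme_motifs <- function(path, pseudo = 1e-3, ...) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    fields <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(fields[c(FALSE, TRUE)])
    names(vals) <- fields[c(TRUE, FALSE)]
    bg <- as.numeric(vals[DNA_BASES])
  }
  starts <- grep("^MOTIF", lines)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    prob <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }))
    prob[prob == 0] <- pseudo
    prob <- prob / rowSums(prob)
    motifs[[name]] <- motif_model(name, prob, background = bg, ...)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param motifs Named list of `motif_model` objects.
#' @param path Output file path.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- motifs[[1L]]$background
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
             con)
  for (m in motifs) {
    writeLines(c("", sprintf("MOTIF %s", m$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         m$length)), con)
    writeLines(apply(m$prob, 1L, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
  }
  invisible(path)
}

#' Read / write an energy weight matrix as TSV
#'
#' The table has columns `position`, `A`, `C`, `G`, `T` holding energy
#' penalties (optimal base 0 per position).
#'
#' @param path File path.
#' @return `read_ewm_tsv` returns a K x 4 numeric matrix.
#' @export
read_ewm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, DNA_BASES])
  rownames(m) <- NULL
  m
}

#' @rdname read_ewm_tsv
#' @param ewm K x 4 energy penalty matrix.
#' @export
write_ewm_tsv <- function(ewm, path) {
  df <- data.frame(position = seq_len(nrow(ewm)), ewm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Build a sharp probability matrix from a consensus string. `core` marks
# positions (1-based within the consensus) that get near-deterministic
# probabilities; remaining positions are softer.
consensus_prob_matrix <- function(consensus, core = NULL,
                                  p_core = 0.997, p_flank = 0.55) {
  idx <- encode_dna(consensus)
  K <- length(idx)
  prob <- matrix(0, K, 4, dimnames = list(NULL, DNA_BASES))
  for (k in seq_len(K)) {
    if (!is.null(core) && k %in% core) {
      prob[k, ] <- (1 - p_core) / 3
      prob[k, idx[k]] <- p_core
    } else {
      prob[k, ] <- (1 - p_flank) / 3
      prob[k, idx[k]] <- p_flank
    }
  }
  prob
}

#' Built-in CRX motif model (synthetic stand-in)
#'
#' An 8-bp K50 homeodomain-style motif with consensus `CTAATCCC` and a
#' near-deterministic TAAT core (positions 2-5). This is a synthetic
#' stand-in constructed in code with the qualitative shape of the CRX/OTX2
#' specificity (TAATCC consensus core), not a published matrix; supply your
#' own via [read_meme_motifs()] or [read_ewm_tsv()] to reproduce results
#' that depend on the exact energies.
#'
#' @param ... Passed to [motif_model()].
#' @return A `motif_model`.
#' @export
crx_motif <- function(...) {
  motif_model("CRX", consensus_prob_matrix("CTAATCCC", core = 2:5), ...)
}

#' Built-in 8-TF motif set for information content (synthetic stand-ins)
#'
#' Named list of eight motif models for the lineage-specific TF families
#' used in the information-content score: CRX/OTX2, NRL, NEUROD1, RORB,
#' MAZ/SP4, MEF2D, RAX and GFI1. All are synthetic stand-ins built in code
#' from field-standard consensus sequences (see [crx_motif()]); their
#' occupancy regimes are qualitatively realistic but the energies are not
#' the historically used matrices.
#'
#' @param ... Passed to [motif_model()].
#' @return Named list of 8 `motif_model` objects.
#' @export
default_motif_set <- function(...) {
  cons <- c(
    NRL     = "TGCTGACT",  # bZIP half-site context
    NEUROD1 = "CCAGCTGG",  # E-box
    RORB    = "AAGTAGGT",  # nuclear receptor RORE-like
    MAZ_SP4 = "GGGAGGGG",  # C2H2 zinc finger GC-box
    MEF2D   = "CTATTTAT",  # MADS-box A/T-rich
    RAX     = "CTAATTAG",  # Q50 homeodomain
    GFI1    = "TGATTTGC"   # C2H2 repressor AATC core (minus strand)
  )
  out <- list(CRX = crx_motif(...))
  for (nm in names(cons)) {
    out[[nm]] <- motif_model(nm, consensus_prob_matrix(cons[[nm]],
                                                       core = NULL,
                                                       p_flank = 0.90),
                             ...)
  }
  out
}
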