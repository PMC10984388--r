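#' Library design: elements, variants, barcodes
#'
#' A `library_design` holds the element table (one row per element:
#' wild-type CREs, their motif-mutant partners, scrambled controls and the
#' basal promoter), the barcode-to-element map, and the motif models used
#' to construct it.
#'
#' @name library-design
NULL

ELEMENT_CLASSES <- c("wild_type", "motif_mutant", "scrambled", "basal")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a library design
#'
#' @param elements Tibble with at least `element_id`, `sequence`
#'   (NA allowed for the basal element), `variant_class`
#'   (wild_type/motif_mutant/scrambled/basal) and `parent_id`.
#' @param barcode_map Tibble with columns `barcode`, `element_id`.
#' @param motif_models Named list of [motif_model()] objects.
#' @param barcodes_per_element,basal_barcodes Expected barcode counts used
#'   by [validate_design()].
#' @return Object of class `library_design`.
#' @export
library_design <- function(elements, barcode_map, motif_models = list(),
                           barcodes_per_element = 4L, basal_barcodes = 16L) {
  elements <- as_tibble(elements)
  barcode_map <- as_tibble(barcode_map)
  design <- structure(
    list(elements = elements, barcode_map = barcode_map,
         motif_models = motif_models,
         basal_id = elements$element_id[elements$variant_class == "basal"],
         scrambled_ids =
           elements$element_id[elements$variant_class == "scrambled"],
         barcodes_per_element = as.integer(barcodes_per_element),
         basal_barcodes = as.integer(basal_barcodes)),
    class = "library_design"
  )
  validate_design(design)
  design
}

#' Validate a library design's invariants
#'
#' Checks: known variant classes; exactly one basal element; unique
#' barcodes mapping to existing elements; expected barcode counts per
#' element; motif-mutant elements name an existing wild-type parent of
#' identical sequence length.
#'
#' @param design A `library_design`.
#' @return The design, invisibly; errors describe the violated invariant.
#' @export
validate_design <- function(design) {
  el <- design$elements
  bm <- design$barcode_map
  stopifnot(all(c("element_id", "sequence", "variant_class", "parent_id")
                %in% names(el)))
  if (anyDuplicated(el$element_id)) stop("duplicate element ids")
  if (!all(el$variant_class %in% ELEMENT_CLASSES)) {
    stop("unknown variant_class values: ",
         paste(setdiff(el$variant_class, ELEMENT_CLASSES), collapse = ", "))
  }
  if (sum(el$variant_class == "basal") != 1L) {
    stop("design must contain exactly one basal element")
  }
  if (anyDuplicated(bm$barcode)) {
    stop("barcodes are not unique across the library")
  }
  if (!all(bm$element_id %in% el$element_id)) {
    stop("barcode map references unknown elements")
  }
  n_bc <- table(factor(bm$element_id, levels = el$element_id))
  expected <- ifelse(el$variant_class == "basal", design$basal_barcodes,
                     design$barcodes_per_element)
  off <- el$element_id[as.integer(n_bc) != expected]
  if (length(off)) {
    stop("elements with unexpected barcode count: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  mut <- el[el$variant_class == "motif_mutant", ]
  if (nrow(mut)) {
    parent <- el[match(mut$parent_id, el$element_id), ]
    if (anyNA(parent$element_id) ||
        !all(parent$variant_class == "wild_type")) {
      stop("motif_mutant elements must name an existing wild_type parent")
    }
    if (!all(nchar(mut$sequence) == nchar(parent$sequence))) {
      stop("motif_mutant sequences must match their parent's length")
    }
  }
  invisible(design)
}

#' @export
print.library_design <- function(x, ...) {
  tab <- table(x$elements$variant_class)
  cat("<library_design>\n")
  cat(sprintf("  elements: %d (%s)\n", nrow(x$elements),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  barcodes: %d\n", nrow(x$barcode_map)))
  cat(sprintf("  motifs:   %s\n",
              paste(names(x$motif_models), collapse = ", ")))
  invisible(x)
}

# 1-based offset of the TAAT core within a motif's consensus; error if the
# motif has no TAAT core (signals a motif/consensus mismatch).
taat_core_offset <- function(motif) {
  cons <- motif_consensus(motif)
  off <- regexpr("TAAT", cons, fixed = TRUE)[1L]
  if (off < 0) {
    stop(sprintf("motif '%s' (consensus %s) has no TAAT core", motif$name,
                 cons), call. = FALSE)
  }
  off
}

#' Abolish CRX motif occurrences by mutating the core TAAT to TACT
#'
#' Scans the sequence on both strands (see [scan_motif()]) and, for every
#' occurrence with `p <= p_threshold`, replaces the core TAAT by TACT in
#' the motif's own orientation; on minus-strand occurrences the
#' reverse-complement edit is applied, so the plus-strand text changes
#' ATTA to AGTA. Because editing one of two overlapping occurrences can
#' leave the other callable, scan-and-edit is iterated until no occurrence
#' remains at the threshold (bounded by `max_rounds`), unless a specific
#' `site_subset` is requested, in which case exactly one round edits the
#' selected occurrences (counted in scan order, leftmost first).
#'
#' @inheritParams scan_motif
#' @param site_subset Optional integer indices of the occurrences to
#'   mutate (e.g. `1` for a single-site mutant of a two-site CRE).
#' @param max_rounds Maximum scan-and-edit iterations.
#' @return List with `sequence` (edited string, same length) and `edits`
#'   (tibble: round, site_index, position, strand, original_window,
#'   edited_window).
#' @export
mutate_crx_motifs <- function(sequence, motif, p_threshold = 2.5e-3,
                              site_subset = NULL, max_rounds = 10L) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  core <- taat_core_offset(motif)
  K <- motif$length
  edits <- list()
  seq_cur <- sequence
  for (round in seq_len(max_rounds)) {
    occ <- scan_motif(seq_cur, motif, p_threshold)
    if (!is.null(site_subset)) {
      bad <- setdiff(site_subset, seq_len(nrow(occ)))
      if (length(bad)) {
        stop("site_subset indices out of range: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      occ <- occ[site_subset, , drop = FALSE]
    }
    if (nrow(occ) == 0L) break
    # Plus-strand position of the edited base (third base of the TAAT core)
    # and its replacement, for every occurrence called this round.
    pos_edit <- integer(nrow(occ))
    base_new <- character(nrow(occ))
    for (i in seq_len(nrow(occ))) {
      p <- occ$position[i]
      window_plus <- substr(seq_cur, p, p + K - 1L)
      window_motif <- if (occ$strand[i] == "+") window_plus else
        reverse_complement(window_plus)
      if (substr(window_motif, core, core + 3L) != "TAAT") {
        stop(sprintf(paste0("occurrence at position %d (%s) lacks a TAAT ",
                            "core at offset %d (window %s); motif/consensus ",
                            "mismatch"),
                     p, occ$strand[i], core, window_motif), call. = FALSE)
      }
      if (occ$strand[i] == "+") {
        pos_edit[i] <- p + core + 1L      # third base of TAAT
        base_new[i] <- "C"
      } else {
        pos_edit[i] <- p + K - (core + 2L) # same base on the plus text
        base_new[i] <- "G"
      }
      edited_motif <- replace_substring(window_motif, core, "TACT")
      edits[[length(edits) + 1L]] <- tibble(
        round = round, site_index = i, position = p, strand = occ$strand[i],
        original_window = window_motif, edited_window = edited_motif
      )
    }
    clash <- duplicated(pos_edit) & !duplicated(paste(pos_edit, base_new))
    if (any(clash)) {
      stop("colliding edits from overlapping occurrences at plus-strand ",
           "position(s) ", paste(unique(pos_edit[clash]), collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(occ))) {
      seq_cur <- replace_substring(seq_cur, pos_edit[i], base_new[i])
    }
    if (!is.null(site_subset)) break
    if (round == max_rounds &&
        nrow(scan_motif(seq_cur, motif, p_threshold)) > 0L) {
      stop("motif occurrences remain after ", max_rounds,
           " edit rounds", call. = FALSE)
    }
  }
  edits <- if (length(edits)) dplyr::bind_rows(edits) else {
    tibble(round = integer(0), site_index = integer(0),
           position = integer(0), strand = character(0),
           original_window = character(0), edited_window = character(0))
  }
  list(sequence = seq_cur, edits = edits)
}

# Dinucleotide-preserving shuffle of one sequence (random Eulerian walk on
# the dinucleotide graph; retries until a full-length walk is found).
dinuc_shuffle <- function(sequence, max_walk_tries = 200L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 3L) return(sequence)
  for (try in seq_len(max_walk_tries)) {
    edges <- split(chars[-1L], chars[-n])
    edges <- lapply(edges, sample)
    used <- lapply(edges, function(e) 0L)
    out <- character(n)
    out[1L] <- chars[1L]
    ok <- TRUE
    for (i in 2:n) {
      prev <- out[i - 1L]
      k <- used[[prev]] + 1L
      if (is.null(edges[[prev]]) || k > length(edges[[prev]])) {
        ok <- FALSE
        break
      }
      out[i] <- edges[[prev]][k]
      used[[prev]] <- k
    }
    if (ok) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find a full-length walk",
       call. = FALSE)
}

#' Generate a scrambled (motif-free) control sequence
#'
#' Draws composition-matched sequences and rejects any with a detectable
#' motif occurrence (`p <= p_threshold` on either strand, [scan_motif()]),
#' mirroring the construction of scrambled negative controls whose
#' composition matches the average CRE but which carry no callable CRX
#' site.
#'
#' @param template Either a length-4 nucleotide frequency vector (A,C,G,T)
#'   or one/more template sequences whose pooled composition (and, for a
#'   single template, length) is used.
#' @inheritParams scan_motif
#' @param rng_seed Optional integer seed; generation is reproducible given
#'   the seed.
#' @param max_tries Attempts before giving up.
#' @param length Sequence length when `template` is a frequency vector.
#' @param method `"iid"` (independent draws from the mononucleotide
#'   composition, the default) or `"dinuc"` (dinucleotide-preserving
#'   shuffle of a template sequence).
#' @return A DNA string with no motif occurrence at the threshold.
#' @export
make_scrambled_control <- function(template, motif, p_threshold = 0.0025,
                                   rng_seed = NULL, max_tries = 1000L,
                                   length = 164L,
                                   method = c("iid", "dinuc")) {
  method <- match.arg(method)
  stopifnot(max_tries >= 1L)
  if (is.character(template)) {
    composition <- base_composition(template)
    if (base::length(template) == 1L) length <- nchar(template)
  } else {
    stopifnot(base::length(template) == 4L, all(template >= 0),
              abs(sum(template) - 1) < 1e-6)
    composition <- as.numeric(template)
  }
  if (method == "dinuc" && !is.character(template)) {
    stop("method 'dinuc' requires a template sequence", call. = FALSE)
  }
  with_seed(rng_seed, {
    for (try in seq_len(max_tries)) {
      cand <- if (method == "iid") random_dna(length, composition) else
        dinuc_shuffle(template[[1L]])
      if (nrow(scan_motif(cand, motif, p_threshold)) == 0L) return(cand)
    }
    stop(sprintf(paste0("no motif-free sequence found in %d attempts at ",
                        "p <= %g (threshold too permissive?)"),
                 max_tries, p_threshold), call. = FALSE)
  })
}

#' Generate unique barcodes with pairwise Hamming distance >= 2
#'
#' Barcodes are `length - 1` random bases plus one checksum base (sum of
#' base indices mod 4), a single-error-detecting code: any two distinct
#' barcodes differ at two or more positions.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 12).
#' @return Character vector of `n` unique barcodes.
#' @export
make_barcodes <- function(n, length = 12L) {
  stopifnot(length >= 2L)
  out <- character(0)
  while (base::length(out) < n) {
    need <- n - base::length(out)
    data <- matrix(sample.int(4L, need * (length - 1L), replace = TRUE),
                   nrow = need)
    check <- (rowSums(data - 1L) %% 4L) + 1L
    bc <- apply(cbind(data, check), 1L, function(i) {
      paste(DNA_BASES[i], collapse = "")
    })
    out <- unique(c(out, bc))
  }
  out[seq_len(n)]
}

#' Default motif-planting plan for synthetic designs
#'
#' Ranges of planted CRX and other-TF site counts per planted activity
#' class. Silencers carry more CRX sites and fewer other-TF sites than
#' enhancers (silencers are CRX-dominated, enhancers motif-diverse);
#' conversion-flagged silencers get both high CRX site counts and extra
#' other-TF sites, giving them the mixed high-occupancy/high-information
#' profile of bifunctional elements.
#'
#' @return Named list of integer ranges consumed by
#'   [build_synthetic_design()].
#' @export
default_motif_plan <- function() {
  list(
    crx = list(strong_enhancer = 1:2, weak_enhancer = 1:2, inactive = 0:2,
               weak_silencer = 3:4, strong_silencer = 3:4),
    other = list(strong_enhancer = 2:3, weak_enhancer = 2:3, inactive = 0:2,
                 weak_silencer = 0:1, strong_silencer = 0:1),
    other_converted = 2:3
  )
}

# Sample planted-site counts for one element.
plan_sites <- function(plan, class, converted) {
  pick <- function(r) if (base::length(r) == 1L) r else sample(r, 1L)
  n_crx <- pick(plan$crx[[class]])
  n_other <- if (isTRUE(converted)) pick(plan$other_converted) else
    pick(plan$other[[class]])
  c(crx = n_crx, other = n_other)
}

# Plant `consensi` (named by motif) at random non-overlapping positions and
# strands in `background`; returns NULL if no placement fits.
plant_sites <- function(background, consensi, max_place_tries = 200L) {
  L <- nchar(background)
  widths <- nchar(consensi)
  for (try in seq_len(max_place_tries)) {
    starts <- integer(0)
    ok <- TRUE
    for (w in widths) {
      cand_ok <- FALSE
      for (inner in seq_len(50L)) {
        s <- sample.int(L - w + 1L, 1L)
        if (!any(abs(starts - s) < 8L)) { # non-overlapping 8-bp slots
          starts <- c(starts, s)
          cand_ok <- TRUE
          break
        }
      }
      if (!cand_ok) { ok <- FALSE; break }
    }
    if (!ok) next
    seq_out <- background
    for (i in seq_along(consensi)) {
      ins <- if (stats::runif(1) < 0.5) consensi[i] else
        reverse_complement(consensi[i])
      seq_out <- replace_substring(seq_out, starts[i], ins)
    }
    return(seq_out)
  }
  NULL
}

DEFAULT_CLASS_PROBS <- c(strong_enhancer = 0.22, weak_enhancer = 0.28,
                         inactive = 0.20, weak_silencer = 0.16,
                         strong_silencer = 0.14)

#' Build a synthetic MPRA library design with planted motifs
#'
#' Constructs `n_cres` wild-type 164-bp elements with planted CRX and
#' other-TF motif sites (counts per `motif_plan`, conditioned on each
#' element's planted activity class), one CRX-motif-mutant partner per
#' wild-type element (all CRX sites killed, TAAT to TACT), single/double
#' mutant quads for the first `n_coop` elements (which carry exactly two
#' CRX sites), `n_scrambled` scrambled controls and one basal element.
#' Non-basal elements get 4 barcodes, the basal element 16.
#'
#' Planted ground-truth attributes (activity class in the wild-type
#' genotype, silencer conversion flags, cooperativity ratios, chromatin
#' group and rod/cone proximity labels) are stored as metadata columns and
#' consumed by [simulate_true_activities()].
#'
#' @param n_cres Number of wild-type CREs (>= 1).
#' @param n_scrambled Number of scrambled negative controls.
#' @param n_coop Number of two-CRX-site cooperativity quads (first
#'   `n_coop` CREs). The study design uses 100.
#' @param rng_seed Integer seed; the same seed yields an identical design.
#' @param motif_set Named motif models; the entry named `"CRX"` is planted
#'   and mutated, the rest are the "other TF" pool.
#' @param motif_plan See [default_motif_plan()].
#' @param class_probs Named probabilities of the five planted classes for
#'   non-cooperativity CREs.
#' @param conversion_fraction Fraction of planted silencers flagged as
#'   converting to enhancers in effector-domain-null genotypes.
#' @param coop_fraction Fraction of cooperativity quads planted with a
#'   cooperative ratio (rho = 2); the rest are additive (rho = 1).
#' @param length Element length in bp.
#' @param composition Background mononucleotide composition.
#' @param p_threshold Motif-calling threshold used for background
#'   rejection, site verification and mutant construction.
#' @return A validated `library_design`.
#' @export
build_synthetic_design <- function(n_cres, n_scrambled = 100L, n_coop = 0L,
                                   rng_seed = 1L,
                                   motif_set = default_motif_set(),
                                   motif_plan = default_motif_plan(),
                                   class_probs = DEFAULT_CLASS_PROBS,
                                   conversion_fraction = 0.48,
                                   coop_fraction = 0.1,
                                   length = 164L,
                                   composition = rep(0.25, 4),
                                   p_threshold = 2.5e-3) {
  stopifnot(n_cres >= 1L, n_coop <= n_cres,
            abs(sum(class_probs) - 1) < 1e-6)
  crx <- motif_set[["CRX"]]
  if (is.null(crx)) stop("motif_set must contain a 'CRX' motif")
  others <- motif_set[setdiff(names(motif_set), "CRX")]
  max_sites <- max(vapply(motif_plan$crx, max, numeric(1))) +
    max(vapply(motif_plan$other, max, numeric(1)))
  if (max_sites * 8L > length) {
    stop("motif_plan asks for more sites than fit in ", length, " bp")
  }
  with_seed(rng_seed, {
    classes <- sample(names(class_probs), n_cres, replace = TRUE,
                      prob = class_probs)
    is_coop <- seq_len(n_cres) <= n_coop
    classes[is_coop] <- "strong_enhancer"
    is_sil <- classes %in% c("weak_silencer", "strong_silencer") & !is_coop
    converted <- is_sil & stats::runif(n_cres) < conversion_fraction
    rho <- rep(NA_real_, n_cres)
    rho[is_coop] <- ifelse(stats::runif(sum(is_coop)) < coop_fraction, 2, 1)

    # Metadata labels, lightly conditioned on planted class so the
    # synthetic library reproduces the field's qualitative structure
    # (silencers enriched near cone genes and in late-accessible distal
    # chromatin).
    prox_probs <- function(cl) {
      if (cl %in% c("weak_silencer", "strong_silencer")) {
        c(cone = 0.10, rod = 0.04, none = 0.86)
      } else if (cl %in% c("weak_enhancer", "strong_enhancer")) {
        c(cone = 0.02, rod = 0.09, none = 0.89)
      } else c(cone = 0.03, rod = 0.06, none = 0.91)
    }
    chrom_probs <- function(cl) {
      if (cl %in% c("weak_silencer", "strong_silencer")) {
        c(A_independent = 0.05, A_dependent = 0.38, C_independent = 0.14,
          C_dependent = 0.24, D_independent = 0.08, D_dependent = 0.11)
      } else {
        c(A_independent = 0.18, A_dependent = 0.36, C_independent = 0.20,
          C_dependent = 0.20, D_independent = 0.03, D_dependent = 0.03)
      }
    }
    proximity <- vapply(classes, function(cl) {
      p <- prox_probs(cl)
      sample(names(p), 1L, prob = p)
    }, character(1))
    chromatin <- vapply(classes, function(cl) {
      p <- chrom_probs(cl)
      sample(names(p), 1L, prob = p)
    }, character(1))

    make_cre <- function(i) {
      n_sites <- plan_sites(motif_plan, classes[i], converted[i])
      if (is_coop[i]) n_sites["crx"] <- 2L
      for (attempt in seq_len(25L)) {
        bg <- make_scrambled_control(composition, crx, p_threshold,
                                     length = length)
        consensi <- c(rep(motif_consensus(crx), n_sites["crx"]),
                      vapply(sample(base::length(others), n_sites["other"],
                                    replace = TRUE),
                             function(j) motif_consensus(others[[j]]),
                             character(1)))
        if (base::length(consensi) == 0L) return(bg)
        planted <- plant_sites(bg, consensi)
        if (is.null(planted)) next
        if (nrow(scan_motif(planted, crx, p_threshold)) ==
            n_sites[["crx"]]) {
          return(planted)
        }
      }
      stop("failed to construct CRE ", i, " with the requested site plan")
    }

    wt_seq <- vapply(seq_len(n_cres), make_cre, character(1))
    wt_id <- sprintf("CRE%04d", seq_len(n_cres))

    rows <- list()
    add_row <- function(id, seq, vclass, parent = NA_character_,
                        mutated = "", role = NA_character_, idx = NA_integer_) {
      rows[[base::length(rows) + 1L]] <<- tibble(
        element_id = id, sequence = seq, variant_class = vclass,
        parent_id = parent, mutated_site_indices = mutated, coop_role = role,
        planted_class = if (is.na(idx)) NA_character_ else classes[idx],
        planted_conversion = if (is.na(idx)) NA else converted[idx],
        planted_rho = if (is.na(idx)) NA_real_ else rho[idx],
        chromatin_group = if (is.na(idx)) NA_character_ else chromatin[idx],
        proximity_label = if (is.na(idx)) NA_character_ else proximity[idx]
      )
    }

    for (i in seq_len(n_cres)) {
      role <- if (is_coop[i]) "wt" else NA_character_
      add_row(wt_id[i], wt_seq[i], "wild_type", role = role, idx = i)
      n_crx_i <- nrow(scan_motif(wt_seq[i], crx, p_threshold))
      if (is_coop[i]) {
        m1 <- mutate_crx_motifs(wt_seq[i], crx, p_threshold, site_subset = 1L)
        m2 <- mutate_crx_motifs(wt_seq[i], crx, p_threshold, site_subset = 2L)
        m12 <- mutate_crx_motifs(wt_seq[i], crx, p_threshold)
        add_row(paste0(wt_id[i], "_M1"), m1$sequence, "motif_mutant",
                wt_id[i], "1", "m1", i)
        add_row(paste0(wt_id[i], "_M2"), m2$sequence, "motif_mutant",
                wt_id[i], "2", "m2", i)
        add_row(paste0(wt_id[i], "_MUT"), m12$sequence, "motif_mutant",
                wt_id[i], "1,2", "m12", i)
      } else {
        mut <- mutate_crx_motifs(wt_seq[i], crx, p_threshold)
        killed <- if (n_crx_i) paste(seq_len(n_crx_i), collapse = ",") else ""
        add_row(paste0(wt_id[i], "_MUT"), mut$sequence, "motif_mutant",
                wt_id[i], killed, NA_character_, i)
      }
    }
    for (j in seq_len(n_scrambled)) {
      add_row(sprintf("SCRAM%03d", j),
              make_scrambled_control(composition, crx, p_threshold,
                                     length = length),
              "scrambled")
    }
    add_row("BASAL", NA_character_, "basal")
    elements <- dplyr::bind_rows(rows)

    n_bc <- 4L * (nrow(elements) - 1L) + 16L
    barcodes <- make_barcodes(n_bc)
    counts <- ifelse(elements$variant_class == "basal", 16L, 4L)
    barcode_map <- tibble(
      barcode = barcodes,
      element_id = rep(elements$element_id, counts)
    )
    library_design(elements, barcode_map, motif_models = motif_set)
  })
}

#' Write / read a library design as plain-text interchange files
#'
#' Writes `design.tsv` (one row per barcode: element_id, variant_class,
#' parent_id, barcode plus metadata columns), `sequences.fa` (FASTA,
#' element_id as record id), `motifs.meme` (MEME minimal format) and
#' `motif_params.yaml` (per-motif chemical potentials). [read_design()]
#' reconstructs the design from such a directory.
#'
#' @param design A `library_design`.
#' @param dir Directory (created if needed).
#' @return The directory path (write) or a `library_design` (read).
#' @export
write_design <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- dplyr::left_join(design$barcode_map, design$elements,
                          by = "element_id")
  tab$sequence <- NULL
  utils::write.table(tab, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  el <- design$elements[!is.na(design$elements$sequence), ]
  seqs <- Biostrings::DNAStringSet(el$sequence)
  names(seqs) <- el$element_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fa"))
  if (length(design$motif_models)) {
    write_meme_motifs(design$motif_models, file.path(dir, "motifs.meme"))
    yaml::write_yaml(lapply(design$motif_models, function(m) m$mu),
                     file.path(dir, "motif_params.yaml"))
  }
  invisible(dir)
}

#' @rdname write_design
#' @export
read_design <- function(dir) {
  tab <- as_tibble(utils::read.delim(file.path(dir, "design.tsv"),
                                     na.strings = "NA"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
  el <- dplyr::distinct(tab[setdiff(names(tab), "barcode")])
  el$sequence <- as.character(seqs)[el$element_id]
  el <- el[, union(c("element_id", "sequence", "variant_class", "parent_id"),
                   names(el))]
  motifs <- list()
  meme_path <- file.path(dir, "motifs.meme")
  if (file.exists(meme_path)) {
    motifs <- read_meme_motifs(meme_path)
    params_path <- file.path(dir, "motif_params.yaml")
    if (file.exists(params_path)) {
      mus <- yaml::read_yaml(params_path)
      for (nm in names(mus)) if (nm %in% names(motifs)) {
        motifs[[nm]]$mu <- mus[[nm]]
      }
    }
  }
  library_design(el, tab[, c("barcode", "element_id")],
                 motif_models = motifs)
}
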