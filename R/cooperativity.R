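#' Homotypic cooperativity between two CRX sites
#'
#' For a CRE with exactly two CRX motifs, compare the wild type, the two
#' single-motif mutants and the double mutant. With effects measured as
#' losses of mean log2 activity, the cooperativity ratio is
#' `rho = (delta_m1 + delta_m2) / delta_m12`: a ratio above one indicates
#' the sites act cooperatively, near one additively, and below one
#' redundantly or anticooperatively.
#'
#' @name cooperativity
NULL

#' Cooperativity ratio for one two-site element
#'
#' Deltas are computed on mean log2 activities (wild type minus mutant); a
#' percentile bootstrap over barcode-level values yields the confidence
#' interval used for the call: `cooperative` if the CI lies above 1,
#' `sub_additive` if below 1, `additive` if the CI is contained in
#' `1 +/- additive_band`, `undetermined` otherwise (including when the
#' double-mutant effect is below `min_effect`, which makes the ratio
#' unstable).
#'
#' @param wt,m1,m2,m12 Numeric vectors of barcode-level log2 activity
#'   values for the wild type, single mutants and double mutant. A
#'   missing variant is an error naming it.
#' @param min_effect Smallest |delta_m12| (log2 units) for which the ratio
#'   is reported.
#' @param n_boot Bootstrap resamples.
#' @param rng_seed Optional seed for the bootstrap.
#' @param ci_level Confidence level of the percentile interval.
#' @param additive_band Half-width of the CI envelope around 1 accepted as
#'   additive.
#' @param element_id,genotype Optional identifiers carried into the
#'   record.
#' @return One-row tibble: element_id, genotype, delta_m1, delta_m2,
#'   delta_m12, ratio, ci_lower, ci_upper, call, n_boot_used.
#' @export
cooperativity_ratio <- function(wt, m1, m2, m12, min_effect = 0.1,
                                n_boot = 1000L, rng_seed = NULL,
                                ci_level = 0.95, additive_band = 0.25,
                                element_id = NA_character_,
                                genotype = NA_character_) {
  vars <- list(wt = wt, m1 = m1, m2 = m2, m12 = m12)
  for (nm in names(vars)) {
    if (is.null(vars[[nm]]) || length(vars[[nm]]) == 0L ||
        !any(is.finite(vars[[nm]]))) {
      stop("missing variant measurements: ", nm, call. = FALSE)
    }
    vars[[nm]] <- vars[[nm]][is.finite(vars[[nm]])]
  }
  means <- vapply(vars, mean, numeric(1))
  d1 <- means[["wt"]] - means[["m1"]]
  d2 <- means[["wt"]] - means[["m2"]]
  d12 <- means[["wt"]] - means[["m12"]]
  ratio <- if (abs(d12) > min_effect) (d1 + d2) / d12 else NA_real_

  boot <- with_seed(rng_seed, {
    draw <- function(v) {
      matrix(sample(v, length(v) * n_boot, replace = TRUE),
             nrow = length(v))
    }
    bm <- lapply(vars, function(v) colMeans(draw(v)))
    b1 <- bm$wt - bm$m1
    b2 <- bm$wt - bm$m2
    b12 <- bm$wt - bm$m12
    r <- (b1 + b2) / b12
    r[abs(b12) > min_effect & is.finite(r)]
  })
  alpha2 <- (1 - ci_level) / 2
  if (length(boot) >= max(10L, n_boot / 2) && !is.na(ratio)) {
    ci <- stats::quantile(boot, c(alpha2, 1 - alpha2), type = 7,
                          names = FALSE)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  call <- if (is.na(ratio) || anyNA(ci)) {
    "undetermined"
  } else if (ci[1] > 1) {
    "cooperative"
  } else if (ci[2] < 1) {
    "sub_additive"
  } else if (ci[1] >= 1 - additive_band && ci[2] <= 1 + additive_band) {
    "additive"
  } else {
    "undetermined"
  }
  tibble(element_id = element_id, genotype = genotype,
         delta_m1 = unname(d1), delta_m2 = unname(d2),
         delta_m12 = unname(d12), ratio = unname(ratio),
         ci_lower = ci[1], ci_upper = ci[2], call = call,
         n_boot_used = length(boot))
}

#' Cooperativity records for all two-site quads in a design
#'
#' Locates the wild-type/single/single/double quads via the design's
#' `coop_role` column and computes [cooperativity_ratio()] per element and
#' genotype from barcode-level log2 activity values.
#'
#' @param activity An `activity_table`.
#' @param design A `library_design` with cooperativity quads.
#' @param genotypes Genotypes to process (default: all in the table).
#' @param rng_seed Base seed; each record derives its own.
#' @param ... Passed to [cooperativity_ratio()].
#' @return Tibble of cooperativity records.
#' @export
cooperativity_records <- function(activity, design, genotypes = NULL,
                                  rng_seed = 1L, ...) {
  el <- design$elements
  if (!"coop_role" %in% names(el) || !any(!is.na(el$coop_role))) {
    return(tibble(element_id = character(0), genotype = character(0),
                  delta_m1 = numeric(0), delta_m2 = numeric(0),
                  delta_m12 = numeric(0), ratio = numeric(0),
                  ci_lower = numeric(0), ci_upper = numeric(0),
                  call = character(0), n_boot_used = integer(0)))
  }
  wt_ids <- el$element_id[!is.na(el$coop_role) & el$coop_role == "wt"]
  bc <- activity$barcodes[activity$barcodes$used, ]
  genotypes <- genotypes %||% unique(bc$genotype)
  vals <- split(bc$log2_ratio, paste(bc$element_id, bc$genotype))
  member_id <- function(wt_id, role) {
    if (role == "wt") return(wt_id)
    el$element_id[!is.na(el$coop_role) & el$coop_role == role &
                    el$parent_id == wt_id][1L]
  }
  out <- list()
  i <- 0L
  for (id in wt_ids) {
    ids <- vapply(c("wt", "m1", "m2", "m12"), member_id, character(1),
                  wt_id = id)
    for (g in genotypes) {
      i <- i + 1L
      v <- lapply(ids, function(e) vals[[paste(e, g)]])
      out[[i]] <- cooperativity_ratio(
        v[[1L]], v[[2L]], v[[3L]], v[[4L]],
        rng_seed = child_seed(rng_seed, i), element_id = id, genotype = g,
        ...)
    }
  }
  dplyr::bind_rows(out)
}

#' Per-genotype cooperativity summary
#'
#' Median ratio and fraction of cooperative calls per genotype, plus a
#' descriptive paired sign test of ratio shifts between the first
#' (reference) genotype and each other genotype over shared elements.
#' With a single genotype the pairwise table is empty.
#'
#' @param records Tibble from [cooperativity_records()] (or row-bound
#'   [cooperativity_ratio()] results with `genotype` filled in).
#' @return List with `summary` (genotype, n, median_ratio,
#'   fraction_cooperative) and `pairwise` (genotype, n_pairs, n_higher,
#'   sign_test_p).
#' @export
cooperativity_sweep <- function(records) {
  stopifnot(nrow(records) >= 1L)
  summary <- records |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_ratio = stats::median(.data$ratio, na.rm = TRUE),
      fraction_cooperative = mean(.data$call == "cooperative"),
      .groups = "drop"
    )
  genotypes <- unique(records$genotype)
  pairwise <- tibble(genotype = character(0), n_pairs = integer(0),
                     n_higher = integer(0), sign_test_p = numeric(0))
  if (length(genotypes) > 1L) {
    ref <- records[records$genotype == genotypes[1L], ]
    rows <- list()
    for (g in genotypes[-1L]) {
      tg <- records[records$genotype == g, ]
      shared <- intersect(ref$element_id, tg$element_id)
      dr <- tg$ratio[match(shared, tg$element_id)] -
        ref$ratio[match(shared, ref$element_id)]
      dr <- dr[is.finite(dr) & dr != 0]
      p <- if (length(dr) >= 1L) {
        stats::binom.test(sum(dr > 0), length(dr))$p.value
      } else NA_real_
      rows[[g]] <- tibble(genotype = g, n_pairs = length(dr),
                          n_higher = sum(dr > 0), sign_test_p = p)
    }
    pairwise <- dplyr::bind_rows(rows)
  }
  list(summary = summary, pairwise = pairwise)
}
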