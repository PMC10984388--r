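#' Cross-genotype dysregulation analysis
#'
#' Each mutant genotype is compared with the reference by (i) a robust
#' regression of log2 activities anchored on the scrambled controls (the
#' empirical null), (ii) the 80th percentile band of library-CRE residuals
#' about that fit, (iii) the squared Pearson correlation of log2
#' activities, and (iv) activity-class transitions: lost enhancers,
#' amplified weak enhancers and silencer-to-enhancer conversions.
#'
#' @name genotype-comparison
NULL

#' Robust trimmed-mean regression on scrambled controls
#'
#' Least-trimmed iteratively reweighted least squares: at each iteration
#' the `trim_fraction` of points with the largest absolute residuals about
#' the current line get weight 0 and the rest weight 1, and the line is
#' refit on the retained points; iterated until the slope changes by less
#' than `tol` (or `max_iter`). Ties on |residual| are broken by retaining
#' the smaller index. `trim_fraction = 0` reduces to ordinary least
#' squares. A Huber M-estimator alternative is available via
#' `method = "huber"` ([MASS::rlm()]).
#'
#' @param x,y Log2 activities of the scrambled controls in the reference
#'   and test genotype.
#' @param trim_fraction Fraction trimmed per iteration, in `[0, 0.5)`.
#' @param method `"trim"` (default) or `"huber"`.
#' @param tol Convergence tolerance on the slope.
#' @param max_iter Iteration cap.
#' @return List with `slope`, `intercept`, `iterations`, `retained`
#'   (logical vector, trim method only).
#' @export
robust_fit_scrambled <- function(x, y, trim_fraction = 0.2,
                                 method = c("trim", "huber"),
                                 tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), trim_fraction >= 0, trim_fraction < 0.5)
  keep_fin <- is.finite(x) & is.finite(y)
  x <- x[keep_fin]; y <- y[keep_fin]
  n <- length(x)
  if (n < 3L) stop("need at least 3 point pairs", call. = FALSE)
  if (n < 10L) {
    warning("robust fit on fewer than 10 scrambled pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate x: zero variance in reference activities",
         call. = FALSE)
  }
  if (method == "huber") {
    fit <- MASS::rlm(y ~ x, maxit = max_iter)
    return(list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                iterations = NA_integer_, retained = rep(TRUE, n)))
  }
  n_trim <- floor(trim_fraction * n)
  cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
  retained <- rep(TRUE, n)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    res <- abs(y - (cf[1L] + cf[2L] * x))
    # retain the n - n_trim smallest |residuals|; ties keep smaller index
    keep_idx <- order(res, seq_along(res))[seq_len(n - n_trim)]
    retained <- seq_len(n) %in% keep_idx
    if (stats::var(x[retained]) == 0) {
      stop("degenerate x after trimming", call. = FALSE)
    }
    cf_new <- stats::coef(stats::lm.fit(cbind(1, x[retained]), y[retained]))
    if (abs(cf_new[2L] - cf[2L]) < tol) {
      cf <- cf_new
      break
    }
    cf <- cf_new
  }
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       iterations = iterations, retained = retained)
}

#' Compare a test genotype with a reference genotype
#'
#' @param activity An `activity_table` covering both genotypes.
#' @param classes Classification tibble from [classify_elements()].
#' @param design The `library_design`.
#' @param reference,test Genotype names.
#' @param trim_fraction Passed to [robust_fit_scrambled()].
#' @param band_percentile Percentile of |residuals| defining the library
#'   dispersion band (default 80).
#' @param method Robust-fit method.
#' @return Object of class `comparison_result`: robust fit on the
#'   scrambled controls (slope/intercept), per-element residuals about it,
#'   `residual_band` (the `band_percentile` of |residual| over library
#'   CREs), `r_squared` of log2 activities over shared library CREs, a
#'   5 x 5 `transition_matrix` (reference -> test, co-classified library
#'   CREs), `lost_enhancer_ids`, `amplified_weak_enhancer_ids`,
#'   `converted_silencer_ids` and the tally of excluded elements.
#' @export
compare_genotypes <- function(activity, classes, design, reference, test,
                              trim_fraction = 0.2, band_percentile = 80,
                              method = "trim") {
  el <- activity$elements
  for (g in c(reference, test)) {
    if (!g %in% el$genotype) stop("genotype not present: ", g, call. = FALSE)
  }
  ref <- el[el$genotype == reference & !el$missing, ]
  tst <- el[el$genotype == test & !el$missing, ]
  shared <- intersect(ref$element_id, tst$element_id)
  x <- ref$log2_activity[match(shared, ref$element_id)]
  y <- tst$log2_activity[match(shared, tst$element_id)]
  vclass <- design$elements$variant_class[
    match(shared, design$elements$element_id)]
  is_scram <- vclass == "scrambled"
  is_cre <- vclass %in% c("wild_type", "motif_mutant")

  fit <- robust_fit_scrambled(x[is_scram], y[is_scram],
                              trim_fraction = trim_fraction,
                              method = method)
  residuals <- y - (fit$intercept + fit$slope * x)
  residual_band <- stats::quantile(abs(residuals[is_cre]),
                                   band_percentile / 100, type = 7,
                                   names = FALSE)
  r_squared <- stats::cor(x[is_cre], y[is_cre])^2

  cls_ref <- classes[classes$genotype == reference, ]
  cls_tst <- classes[classes$genotype == test, ]
  cre_ids <- design$elements$element_id[
    design$elements$variant_class %in% c("wild_type", "motif_mutant")]
  pair <- tibble(
    element_id = cre_ids,
    ref_class = cls_ref$class[match(cre_ids, cls_ref$element_id)],
    test_class = cls_tst$class[match(cre_ids, cls_tst$element_id)]
  )
  excluded <- sum(is.na(pair$ref_class) | is.na(pair$test_class))
  pair <- pair[!is.na(pair$ref_class) & !is.na(pair$test_class), ]
  transition_matrix <- table(
    factor(pair$ref_class, levels = CLASS_LEVELS),
    factor(pair$test_class, levels = CLASS_LEVELS)
  )
  names(dimnames(transition_matrix)) <- c("reference", "test")
  rr <- class_rank(pair$ref_class)
  tr <- class_rank(pair$test_class)
  enh <- c("weak_enhancer", "strong_enhancer")
  sil <- c("weak_silencer", "strong_silencer")
  structure(
    list(reference = reference, test = test,
         slope = fit$slope, intercept = fit$intercept,
         trim_fraction = trim_fraction,
         residuals = tibble(element_id = shared, residual = residuals,
                            variant_class = vclass),
         residual_band = residual_band, r_squared = r_squared,
         transition_matrix = transition_matrix,
         lost_enhancer_ids =
           pair$element_id[pair$ref_class %in% enh & tr < rr],
         amplified_weak_enhancer_ids =
           pair$element_id[pair$ref_class == "weak_enhancer" &
                             pair$test_class == "strong_enhancer"],
         converted_silencer_ids =
           pair$element_id[pair$ref_class %in% sil &
                             pair$test_class %in% enh],
         n_excluded = excluded),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(paste0("<comparison_result> %s vs %s: slope %.3f, ",
                     "intercept %.3f, R^2 %.3f, band %.3f\n",
                     "  lost enhancers %d, amplified weak %d, ",
                     "converted silencers %d (excluded %d)\n"),
              x$test, x$reference, x$slope, x$intercept, x$r_squared,
              x$residual_band, length(x$lost_enhancer_ids),
              length(x$amplified_weak_enhancer_ids),
              length(x$converted_silencer_ids), x$n_excluded))
  invisible(x)
}

#' Silencers that convert to enhancers in test genotypes
#'
#' @param classes Classification tibble ([classify_elements()]).
#' @param reference Reference genotype (where elements must be weak or
#'   strong silencers).
#' @param test_genotypes Genotypes in which they must be weak or strong
#'   enhancers.
#' @param require_all If `TRUE` (default) the element must be an enhancer
#'   in all test genotypes; otherwise in any of them.
#' @return Character vector of element ids.
#' @export
find_converted_silencers <- function(classes, reference, test_genotypes,
                                     require_all = TRUE) {
  for (g in c(reference, test_genotypes)) {
    if (!g %in% classes$genotype) {
      stop("genotype not classified: ", g, call. = FALSE)
    }
  }
  sil <- c("weak_silencer", "strong_silencer")
  enh <- c("weak_enhancer", "strong_enhancer")
  ref <- classes[classes$genotype == reference, ]
  cand <- ref$element_id[!is.na(ref$class) & ref$class %in% sil]
  is_enh <- vapply(test_genotypes, function(g) {
    tg <- classes[classes$genotype == g, ]
    cl <- tg$class[match(cand, tg$element_id)]
    !is.na(cl) & cl %in% enh
  }, logical(length(cand)))
  is_enh <- matrix(is_enh, nrow = length(cand))
  hit <- if (require_all) apply(is_enh, 1L, all) else apply(is_enh, 1L, any)
  cand[hit]
}

#' Per-element fold changes and per-group class summaries
#'
#' Fold change is `log2(test activity + eps) - log2(reference activity +
#' eps)` per element and genotype (both taken from the activity table's
#' log2 field, which already applies the pseudocount). Group summaries
#' give per-label, per-genotype class proportions and mean log2 activity.
#'
#' @param activity An `activity_table`.
#' @param classes Classification tibble.
#' @param metadata Tibble with `element_id` and the label column (e.g. the
#'   design's element table with `proximity_label` or `chromatin_group`).
#' @param label_col Name of the metadata column to group by.
#' @param reference Reference genotype for fold changes.
#' @param sort_genotype Optional genotype whose fold change orders the
#'   output rows (descending).
#' @return List with `fold_changes` (element_id, label, genotype, lfc) and
#'   `group_summary` (label, genotype, n, mean_log2_activity, one
#'   proportion column per class). Empty groups are dropped with a
#'   warning.
#' @export
group_fold_changes <- function(activity, classes, metadata, label_col,
                               reference, sort_genotype = NULL) {
  if (!label_col %in% names(metadata)) {
    stop("metadata column not found: ", label_col, call. = FALSE)
  }
  el <- activity$elements[!activity$elements$missing, ]
  meta <- tibble(element_id = metadata$element_id,
                 label = metadata[[label_col]])
  meta <- meta[!is.na(meta$label), ]
  if (any(!table(meta$label) > 0L)) {
    warning("empty metadata groups omitted", call. = FALSE)
  }
  ref <- el[el$genotype == reference, ]
  fc <- el[el$element_id %in% meta$element_id, ]
  fc$lfc <- fc$log2_activity -
    ref$log2_activity[match(fc$element_id, ref$element_id)]
  fc$label <- meta$label[match(fc$element_id, meta$element_id)]
  fc <- fc[!is.na(fc$lfc), c("element_id", "label", "genotype", "lfc")]
  if (!is.null(sort_genotype)) {
    key <- fc[fc$genotype == sort_genotype, ]
    ord <- key$element_id[order(-key$lfc)]
    fc <- fc[order(match(fc$element_id, ord)), ]
  }
  cls <- dplyr::inner_join(classes, meta, by = "element_id")
  cls <- cls[!is.na(cls$class), ]
  summ <- cls |>
    dplyr::group_by(.data$label, .data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_log2_activity = mean(.data$log2_activity),
      .groups = "drop"
    )
  props <- cls |>
    dplyr::count(.data$label, .data$genotype, .data$class) |>
    dplyr::group_by(.data$label, .data$genotype) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "prop",
                       values_fill = 0)
  list(fold_changes = as_tibble(fc),
       group_summary = dplyr::left_join(summ, props,
                                        by = c("label", "genotype")))
}
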