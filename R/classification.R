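#' Five-class activity calls against basal and the scrambled null
#'
#' Elements are tested against the basal promoter with Welch's t-test on
#' log2 barcode-level values (log-normal expression), corrected with the
#' Benjamini-Hochberg FDR, and placed into five classes: elements not
#' significantly different from basal are inactive; significant increases
#' are strong enhancers above the 95th percentile of the scrambled
#' controls and weak enhancers otherwise; significant decreases are strong
#' silencers below the 5th percentile and weak silencers otherwise.
#'
#' @name classification
NULL

#' Ordered activity classes, weakest repression to strongest activation
#' @export
activity_class_levels <- function() CLASS_LEVELS

#' Welch's t-test of element values against the basal promoter
#'
#' Two-sided Welch (unequal-variance) t-test with Welch-Satterthwaite
#' degrees of freedom; intended for barcode-level log2 activity values
#' (typically 4 element barcodes vs the 16 basal barcodes).
#'
#' @param element_log_values,basal_log_values Numeric vectors (>= 2 values
#'   each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_test_vs_basal <- function(element_log_values, basal_log_values) {
  x <- element_log_values[is.finite(element_log_values)]
  y <- basal_log_values[is.finite(basal_log_values)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 finite observations on each side", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement,
#' order-preserving (wraps [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Classify elements into the five activity classes, per genotype
#'
#' @param activity An `activity_table` from [compute_activity()].
#' @param design The `library_design` (identifies basal and scrambled
#'   elements).
#' @param alpha FDR threshold separating inactive from active calls.
#' @param percentiles Scrambled-control percentiles bounding the weak
#'   classes (default 5th and 95th).
#' @return Tibble of class calls: element_id, genotype, activity,
#'   log2_activity, welch_t, welch_df, p_value, q_value, class,
#'   scrambled_q05, scrambled_q95, alpha. Elements without measurable
#'   activity get class `NA` and are flagged, not dropped.
#' @export
classify_elements <- function(activity, design, alpha = 0.05,
                              percentiles = c(5, 95)) {
  stopifnot(inherits(activity, "activity_table"),
            length(percentiles) == 2L, percentiles[1] < percentiles[2],
            alpha > 0, alpha < 1)
  basal_id <- design$basal_id
  scram_ids <- design$scrambled_ids
  if (length(scram_ids) < 20L) {
    warning("fewer than 20 scrambled controls; percentile thresholds ",
            "will be unstable", call. = FALSE)
  }
  bc <- activity$barcodes[activity$barcodes$used, ]
  el <- activity$elements
  out <- list()
  for (g in unique(el$genotype)) {
    bc_g <- bc[bc$genotype == g, ]
    el_g <- el[el$genotype == g, ]
    basal_vals <- bc_g$log2_ratio[bc_g$element_id == basal_id]
    scram_log2 <- el_g$log2_activity[el_g$element_id %in% scram_ids &
                                       !el_g$missing]
    qs <- stats::quantile(scram_log2, percentiles / 100, type = 7,
                          names = FALSE)
    vals_by_el <- split(bc_g$log2_ratio, bc_g$element_id)
    ids <- el_g$element_id[el_g$element_id != basal_id]
    res <- lapply(ids, function(id) {
      v <- vals_by_el[[id]]
      if (is.null(v) || length(v) < 2L) {
        return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                    delta = NA_real_))
      }
      w <- welch_test_vs_basal(v, basal_vals)
      c(w, list(delta = mean(v) - mean(basal_vals)))
    })
    tab <- tibble(
      element_id = ids, genotype = g,
      activity = el_g$activity[match(ids, el_g$element_id)],
      log2_activity = el_g$log2_activity[match(ids, el_g$element_id)],
      welch_t = vapply(res, function(r) r$t, numeric(1)),
      welch_df = vapply(res, function(r) r$df, numeric(1)),
      p_value = vapply(res, function(r) r$p, numeric(1)),
      delta = vapply(res, function(r) r$delta, numeric(1))
    )
    tab$q_value <- bh_adjust(tab$p_value)
    tab$class <- ifelse(
      is.na(tab$q_value), NA_character_,
      ifelse(tab$q_value > alpha, "inactive",
        ifelse(tab$delta > 0,
          ifelse(tab$log2_activity > qs[2], "strong_enhancer",
                 "weak_enhancer"),
          ifelse(tab$log2_activity < qs[1], "strong_silencer",
                 "weak_silencer"))))
    tab$delta <- NULL
    tab$scrambled_q05 <- qs[1]
    tab$scrambled_q95 <- qs[2]
    tab$alpha <- alpha
    out[[g]] <- tab
  }
  dplyr::bind_rows(out)
}
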