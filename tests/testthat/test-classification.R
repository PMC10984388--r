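test_that("Welch test handles identical, separated and degenerate inputs", {
  same <- c(1, 2, 3, 4)
  res <- welch_test_vs_basal(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # constant values on both sides with equal means
  res0 <- welch_test_vs_basal(rep(2, 4), rep(2, 16))
  expect_equal(res0$p, 1)
  # well-separated means with tiny jitter
  set.seed(1)
  res_sep <- welch_test_vs_basal(3 + rnorm(4, 0, 1e-6),
                                 1 + rnorm(16, 0, 1e-6))
  expect_lt(res_sep$p, 1e-6)
  expect_error(welch_test_vs_basal(1, c(1, 2)), "at least 2")
})

test_that("Welch statistics match the direct formula", {
  x <- c(1.1, 0.9, 1.2, 0.8)
  y <- seq(0.95, 1.05, length.out = 16)
  res <- welch_test_vs_basal(x, y)
  # independent oracle: the Welch-Satterthwaite formulas written out
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / (length(x) - 1) +
                              vy^2 / (length(y) - 1))
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
})

test_that("BH adjustment equals the textbook step-up procedure", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # textbook step-up oracle on random vectors
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- pmin(rev(cummin(rev(q))), 1)
    out <- numeric(n)
    out[o] <- q
    out
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(c(10, 100, 10000), 1)
    p <- runif(n)^sample(1:3, 1)
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("five-class calls follow the basal and scrambled-percentile rules", {
  # hand-built library: 30 scrambled controls spread around basal, plus
  # four probe elements at known positions relative to the null
  set.seed(9)
  n_scr <- 30
  ids <- c("NEUTRAL", "HIGH", "MID", "LOW", sprintf("SCR%02d", 1:n_scr))
  variant <- c(rep("wild_type", 4), rep("scrambled", n_scr))
  d <- micro_design(length(ids), ids = ids, variant = variant)
  n <- nrow(d$barcode_map)
  ratio <- rep(1, n)
  jitter <- function(k) 2^rnorm(k, 0, 0.02)
  set_el <- function(id, level) {
    i <- which(d$barcode_map$element_id == id)
    ratio[i] <<- level * jitter(length(i))
  }
  set_el("NEUTRAL", 1)       # indistinguishable from basal
  set_el("HIGH", 8)          # above any scrambled
  set_el("MID", 1.3)         # significant but inside the scrambled range
  set_el("LOW", 0.1)         # below the 5th percentile
  for (j in 1:n_scr) set_el(sprintf("SCR%02d", j), 2^rnorm(1, 0, 0.4))
  i_basal <- which(d$barcode_map$element_id == "BASAL")
  ratio[i_basal] <- jitter(length(i_basal))
  counts <- tibble::tibble(barcode = d$barcode_map$barcode, DNA = 1000,
                           RNA_wt_rep1 = 1000 * ratio)
  sheet <- tibble::tibble(sample = c("DNA", "RNA_wt_rep1"),
                          type = c("DNA", "RNA"),
                          genotype = c(NA, "wt"), replicate = c(NA, 1L))
  act <- compute_activity(counts, sheet, d)
  cls <- classify_elements(act, d)
  got <- stats::setNames(cls$class, cls$element_id)
  expect_equal(unname(got["NEUTRAL"]), "inactive")
  expect_equal(unname(got["HIGH"]), "strong_enhancer")
  expect_equal(unname(got["MID"]), "weak_enhancer")
  expect_equal(unname(got["LOW"]), "strong_silencer")
  # rule invariants on the full table
  expect_true(all(!is.na(got)))
  expect_true(all(got %in% activity_class_levels()))
  strong <- cls[cls$class %in% c("strong_enhancer", "strong_silencer"), ]
  expect_true(all(strong$log2_activity > strong$scrambled_q95 |
                    strong$log2_activity < strong$scrambled_q05))
  expect_true(all((cls$q_value > cls$alpha) == (cls$class == "inactive")))
})

test_that("classification recovers planted classes on synthetic data", {
  fix <- medium_run()
  lib <- fix$design$elements$element_id[
    fix$design$elements$variant_class %in% c("wild_type", "motif_mutant")]
  m <- dplyr::inner_join(
    fix$classes[fix$classes$element_id %in% lib,
                c("element_id", "genotype", "class")],
    fix$truth$activities[, c("element_id", "genotype", "true_class")],
    by = c("element_id", "genotype"))
  agreement <- mean(m$class == m$true_class, na.rm = TRUE)
  expect_gt(agreement, 0.85)
  # each element-genotype receives exactly one class
  expect_equal(nrow(m), length(lib) * length(unique(m$genotype)))
  # a small scrambled panel triggers the stability warning
  d_small <- build_synthetic_design(3, n_scrambled = 5, rng_seed = 4)
  tr <- simulate_true_activities(d_small, rng_seed = 4)
  cnt <- simulate_counts(tr, d_small, depth = 5e4, rng_seed = 4)
  a <- compute_activity(cnt$counts, cnt$sample_sheet, d_small)
  expect_warning(classify_elements(a, d_small), "scrambled")
})
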