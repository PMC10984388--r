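test_that("robust trimmed fit recovers clean and contaminated lines", {
  x <- seq(0, 5, length.out = 50)
  # exact identity
  f1 <- robust_fit_scrambled(x, x, trim_fraction = 0.2)
  expect_equal(f1$slope, 1, tolerance = 1e-10)
  expect_equal(f1$intercept, 0, tolerance = 1e-10)
  # exact affine line
  f2 <- robust_fit_scrambled(x, 0.5 * x - 1, trim_fraction = 0.2)
  expect_equal(f2$slope, 0.5, tolerance = 1e-10)
  expect_equal(f2$intercept, -1, tolerance = 1e-10)
  # 10% gross outliers: trimmed fit recovers the line, OLS does not
  y <- x
  y[1:5] <- y[1:5] + 10
  f3 <- robust_fit_scrambled(x, y, trim_fraction = 0.2)
  expect_equal(f3$slope, 1, tolerance = 1e-6)
  expect_equal(f3$intercept, 0, tolerance = 1e-6)
  ols <- stats::lm(y ~ x)
  expect_gt(abs(unname(coef(ols)[2]) - 1), 0.01)
  # Huber alternative is also resistant here
  f4 <- robust_fit_scrambled(x, y, method = "huber")
  expect_equal(f4$slope, 1, tolerance = 0.05)
})

test_that("trim 0 equals ordinary least squares; degenerate x errors", {
  set.seed(4)
  x <- rnorm(40)
  y <- 2 * x + 1 + rnorm(40, 0, 0.3)
  f <- robust_fit_scrambled(x, y, trim_fraction = 0)
  cf <- unname(coef(stats::lm(y ~ x)))
  expect_equal(f$intercept, cf[1], tolerance = 1e-10)
  expect_equal(f$slope, cf[2], tolerance = 1e-10)
  expect_error(robust_fit_scrambled(rep(1, 20), rnorm(20)), "zero variance")
})

test_that("comparing a genotype with itself is the identity comparison", {
  fix <- medium_run()
  cmp <- compare_genotypes(fix$activity, fix$classes, fix$design,
                           "wt", "wt")
  expect_equal(cmp$slope, 1, tolerance = 1e-10)
  expect_equal(cmp$r_squared, 1, tolerance = 1e-12)
  expect_equal(cmp$residual_band, 0, tolerance = 1e-12)
  tm <- cmp$transition_matrix
  expect_equal(sum(tm) - sum(diag(tm)), 0)
  expect_length(cmp$lost_enhancer_ids, 0)
  expect_length(cmp$converted_silencer_ids, 0)
})

test_that("transition matrix rows reconcile with reference class counts", {
  fix <- medium_run()
  cmp <- compare_genotypes(fix$activity, fix$classes, fix$design,
                           "wt", "E168d2_hom")
  lib <- fix$design$elements$element_id[
    fix$design$elements$variant_class %in% c("wild_type", "motif_mutant")]
  ref <- fix$classes[fix$classes$genotype == "wt" &
                       fix$classes$element_id %in% lib, ]
  tst <- fix$classes[fix$classes$genotype == "E168d2_hom" &
                       fix$classes$element_id %in% lib, ]
  co <- !is.na(ref$class) &
    !is.na(tst$class[match(ref$element_id, tst$element_id)])
  expect_equal(sum(cmp$transition_matrix), sum(co))
  counts_ref <- table(factor(ref$class[co],
                             levels = activity_class_levels()))
  expect_equal(as.integer(rowSums(cmp$transition_matrix)),
               as.integer(counts_ref))
  # converted ids are reference silencers by definition
  sil <- ref$element_id[ref$class %in% c("weak_silencer",
                                         "strong_silencer")]
  expect_true(all(cmp$converted_silencer_ids %in% sil))
})

test_that("residual band is invariant to a shared log-activity shift", {
  fix <- medium_run()
  cmp <- compare_genotypes(fix$activity, fix$classes, fix$design,
                           "wt", "R90W_hom")
  shifted <- fix$activity
  shifted$elements$log2_activity <- shifted$elements$log2_activity + 1.7
  cmp2 <- compare_genotypes(shifted, fix$classes, fix$design,
                            "wt", "R90W_hom")
  expect_equal(cmp2$residual_band, cmp$residual_band, tolerance = 1e-9)
  expect_equal(cmp2$slope, cmp$slope, tolerance = 1e-6)
})

test_that("dysregulation grows with severity in measured comparisons", {
  fix <- medium_run()
  r2 <- vapply(setdiff(GENOTYPES, "wt"), function(g) {
    compare_genotypes(fix$activity, fix$classes, fix$design, "wt",
                      g)$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) <= 0))
})

test_that("converted silencers are found under all/any semantics", {
  classes <- tibble::tibble(
    element_id = rep(c("a", "b", "c", "d"), 3),
    genotype = rep(c("wt", "g1", "g2"), each = 4),
    class = c("weak_silencer", "strong_silencer", "weak_silencer",
              "weak_enhancer",                         # wt
              "weak_enhancer", "strong_enhancer", "inactive",
              "strong_enhancer",                       # g1
              "strong_enhancer", "inactive", "inactive",
              "strong_enhancer")                       # g2
  )
  expect_equal(find_converted_silencers(classes, "wt", c("g1", "g2")),
               "a")
  expect_equal(sort(find_converted_silencers(classes, "wt", c("g1", "g2"),
                                             require_all = FALSE)),
               c("a", "b"))
  # silencer -> inactive is never a conversion; enhancers are not candidates
  expect_false("c" %in% find_converted_silencers(classes, "wt", "g1",
                                                 require_all = FALSE))
  expect_false("d" %in% find_converted_silencers(classes, "wt", c("g1")))
  expect_error(find_converted_silencers(classes, "wt", "nope"),
               "not classified")
})

test_that("group summaries capture cone-proximal derepression", {
  fix <- medium_run()
  meta <- fix$design$elements[, c("element_id", "proximity_label")]
  gf <- group_fold_changes(fix$activity, fix$classes, meta,
                           "proximity_label", reference = "wt")
  # identical reference: zero fold change
  wt_fc <- gf$fold_changes[gf$fold_changes$genotype == "wt", ]
  expect_true(all(abs(wt_fc$lfc) < 1e-12))
  # planted cone-proximal silencers derepress in effector-null genotypes
  cone_null <- gf$fold_changes[gf$fold_changes$label == "cone" &
                                 gf$fold_changes$genotype == "null", ]
  rod_null <- gf$fold_changes[gf$fold_changes$label == "rod" &
                                gf$fold_changes$genotype == "null", ]
  expect_gt(mean(cone_null$lfc), mean(rod_null$lfc))
  # class proportions per group sum to one
  props <- gf$group_summary[, intersect(activity_class_levels(),
                                        names(gf$group_summary))]
  expect_equal(unname(rowSums(props)), rep(1, nrow(gf$group_summary)),
               tolerance = 1e-12)
  # a single-element group yields proportions in {0, 1}
  meta1 <- tibble::tibble(element_id = meta$element_id[1], label = "solo")
  gf1 <- group_fold_changes(fix$activity, fix$classes, meta1, "label",
                            reference = "wt")
  p1 <- gf1$group_summary[, intersect(activity_class_levels(),
                                      names(gf1$group_summary))]
  expect_true(all(unlist(p1) %in% c(0, 1)))
})
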