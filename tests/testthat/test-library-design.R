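test_that("CRX motif mutation edits TAAT to TACT in motif orientation", {
  toy <- toy_taatcc()
  # plus-strand occurrence
  res <- mutate_crx_motifs("GGGTAATCCGGG", toy, p_threshold = 2.5e-3)
  expect_equal(res$sequence, "GGGTACTCCGGG")
  expect_equal(nrow(res$edits), 1L)
  expect_equal(res$edits$strand, "+")
  expect_equal(res$edits$original_window, "TAATCC")
  expect_equal(res$edits$edited_window, "TACTCC")
  # minus-strand occurrence: plus text changes ATTA -> AGTA
  res_m <- mutate_crx_motifs("CCGGATTACCC", toy, p_threshold = 2.5e-3)
  expect_equal(res_m$sequence, "CCGGAGTACCC")
  expect_equal(res_m$edits$strand, "-")
  # no occurrence at the threshold: identical sequence, no edits
  res_0 <- mutate_crx_motifs("GGGGGGGGGGGG", toy, p_threshold = 2.5e-3)
  expect_equal(res_0$sequence, "GGGGGGGGGGGG")
  expect_equal(nrow(res_0$edits), 0L)
  # sequence length never changes
  expect_equal(nchar(res$sequence), 12L)
})

test_that("mutation errors on motifs without a TAAT core", {
  bad <- motif_model("noCore", sharp_prob("GGGCCC"))
  expect_error(mutate_crx_motifs("AAAGGGCCCAAA", bad), "TAAT core")
})

test_that("scrambled controls are composition-matched and motif-free", {
  crx <- crx_motif()
  s <- make_scrambled_control(rep(0.25, 4), crx, p_threshold = 0.0025,
                              rng_seed = 1)
  expect_equal(nchar(s), 164L)
  expect_equal(nrow(scan_motif(s, crx, 0.0025)), 0L)
  # reproducible given the seed
  expect_identical(
    s, make_scrambled_control(rep(0.25, 4), crx, 0.0025, rng_seed = 1))
  # degenerate threshold: every window matches, so generation fails
  expect_error(
    make_scrambled_control(rep(0.25, 4), crx, p_threshold = 1 - 1e-12,
                           rng_seed = 1, max_tries = 5),
    "5 attempts")
  # poly-A composition cannot contain a TAAT core: accepted immediately
  polyA <- make_scrambled_control(c(1, 0, 0, 0), crx, 0.0025, rng_seed = 3,
                                  max_tries = 1)
  expect_equal(polyA, strrep("A", 164))
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(5)
  template <- paste(sample(c("A", "C", "G", "T"), 164, replace = TRUE),
                    collapse = "")
  crx <- crx_motif()
  s <- make_scrambled_control(template, crx, 0.0025, rng_seed = 2,
                              method = "dinuc")
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_equal(dinucs(s)[sort(names(dinucs(template)))],
               dinucs(template)[sort(names(dinucs(template)))])
})

test_that("synthetic designs have the expected composition and are reproducible", {
  d <- build_synthetic_design(10, n_scrambled = 5, rng_seed = 7)
  tab <- table(d$elements$variant_class)
  expect_equal(as.integer(tab[c("wild_type", "motif_mutant", "scrambled",
                                "basal")]),
               c(10L, 10L, 5L, 1L))
  expect_equal(nrow(d$barcode_map), 10 * 4 + 10 * 4 + 5 * 4 + 16)
  d2 <- build_synthetic_design(10, n_scrambled = 5, rng_seed = 7)
  expect_identical(d$elements, d2$elements)
  expect_identical(d$barcode_map, d2$barcode_map)
  # two-site cooperativity elements come as wild-type + two singles + double
  dc <- build_synthetic_design(6, n_scrambled = 5, n_coop = 2, rng_seed = 8)
  roles <- dc$elements$coop_role[!is.na(dc$elements$coop_role)]
  expect_equal(as.integer(table(roles)[c("wt", "m1", "m2", "m12")]),
               rep(2L, 4))
  crx <- dc$motif_models$CRX
  coop_wt <- dc$elements[!is.na(dc$elements$coop_role) &
                           dc$elements$coop_role == "wt", ]
  for (s in coop_wt$sequence) {
    expect_equal(nrow(scan_motif(s, crx, 2.5e-3)), 2L)
  }
})

test_that("motif-mutant partners carry no callable CRX occurrence", {
  fix <- medium_run()
  crx <- fix$design$motif_models$CRX
  mut <- fix$design$elements[fix$design$elements$variant_class ==
                               "motif_mutant", ]
  full_mut <- mut[is.na(mut$coop_role) | mut$coop_role == "m12", ]
  hits <- vapply(full_mut$sequence[1:25], function(s) {
    nrow(scan_motif(s, crx, 2.5e-3))
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("barcodes are unique with pairwise Hamming distance >= 2", {
  set.seed(42)
  bc <- make_barcodes(200)
  expect_equal(length(unique(bc)), 200L)
  expect_true(all(nchar(bc) == 12L))
  mat <- do.call(rbind, strsplit(bc, ""))
  dmin <- 12L
  for (i in 1:199) {
    d <- rowSums(mat[(i + 1):200, , drop = FALSE] !=
                   matrix(mat[i, ], 200 - i, 12, byrow = TRUE))
    dmin <- min(dmin, d)
  }
  expect_gte(dmin, 2L)
})

test_that("designs round-trip through the interchange files", {
  d <- build_synthetic_design(8, n_scrambled = 5, n_coop = 2, rng_seed = 9)
  dir <- withr::local_tempdir()
  write_design(d, dir)
  expect_true(all(file.exists(file.path(dir, c("design.tsv", "sequences.fa",
                                               "motifs.meme")))))
  d2 <- read_design(dir)
  expect_equal(as.data.frame(d2$elements), as.data.frame(d$elements))
  expect_equal(as.data.frame(d2$barcode_map), as.data.frame(d$barcode_map))
  expect_identical(d2$basal_id, d$basal_id)
  expect_identical(sort(d2$scrambled_ids), sort(d$scrambled_ids))
  expect_equal(names(d2$motif_models), names(d$motif_models))
  expect_equal(d2$motif_models$CRX$prob, d$motif_models$CRX$prob,
               tolerance = 1e-4)
  expect_equal(d2$motif_models$CRX$mu, d$motif_models$CRX$mu)
})

test_that("design invariants are enforced", {
  d <- build_synthetic_design(4, n_scrambled = 3, rng_seed = 1)
  # duplicated barcode
  bad <- d
  bad$barcode_map$barcode[2] <- bad$barcode_map$barcode[1]
  expect_error(validate_design(bad), "not unique")
  # mutant pointing at a missing parent
  bad2 <- d
  bad2$elements$parent_id[bad2$elements$variant_class == "motif_mutant"][1] <-
    "NOPE"
  expect_error(validate_design(bad2), "parent")
})
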