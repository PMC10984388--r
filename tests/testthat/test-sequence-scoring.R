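test_that("a planted consensus site is reported with the maximal score", {
  crx <- crx_motif()
  seq <- paste0(strrep("G", 10), "CTAATCCC", strrep("A", 10))
  hits <- scan_motif(seq, crx, p_threshold = 2.5e-3)
  expect_equal(hits$position, 11L)
  expect_equal(hits$strand, "+")
  max_score <- sum(log2(apply(crx$prob, 1, max) / 0.25))
  expect_equal(hits$score, max_score, tolerance = 1e-3)
  # threshold 0 returns nothing
  expect_equal(nrow(scan_motif(seq, crx, p_threshold = 0)), 0L)
  # the reverse complement is found on the minus strand at the same spot
  rc <- reverse_complement(seq)
  hits_rc <- scan_motif(rc, crx, p_threshold = 2.5e-3)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
})

test_that("scan p-values match exhaustive enumeration for toy motifs", {
  bin <- 1e-4
  for (case in list(list(seed = 1, bg = rep(0.25, 4)),
                    list(seed = 2, bg = c(0.4, 0.1, 0.2, 0.3)))) {
    set.seed(case$seed)
    K <- 4L
    prob <- matrix(stats::runif(K * 4, 0.05, 1), K, 4)
    prob <- prob / rowSums(prob)
    motif <- motif_model("toy", prob, background = case$bg)
    # exhaustive null: all 4^K words under the background model
    words <- as.matrix(expand.grid(rep(list(1:4), K)))
    lo_int <- round(log2(prob / matrix(case$bg, K, 4, byrow = TRUE)) / bin)
    w_scores <- vapply(seq_len(nrow(words)), function(i) {
      sum(lo_int[cbind(seq_len(K), words[i, ])])
    }, numeric(1))
    w_probs <- apply(words, 1, function(w) prod(case$bg[w]))
    brute_p <- function(s) sum(w_probs[w_scores >= s])
    seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                        prob = case$bg), collapse = "")
    hits <- scan_motif(seq, motif, p_threshold = 1, bin = bin)
    expect_gt(nrow(hits), 0)
    for (i in seq_len(nrow(hits))) {
      expect_equal(hits$p_value[i], brute_p(round(hits$score[i] / bin)),
                   tolerance = 1e-6)
    }
  }
})

test_that("non-ACGT symbols are an error naming the position", {
  crx <- crx_motif()
  expect_error(scan_motif(paste0(strrep("A", 10), "N", strrep("A", 10)),
                          crx),
               "position 11")
  expect_error(predicted_occupancy("ACGTNACGTTTTT", crx), "position 5")
})

test_that("predicted occupancy equals a hand-summed logistic oracle and is strand-symmetric", {
  crx <- crx_motif()
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
  res <- predicted_occupancy(seq, crx)
  expect_equal(nrow(res$per_position), 2 * (20 - 8 + 1))
  # independent oracle: plain loop over windows of both strands
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (s in c(seq, reverse_complement(seq))) {
    for (i in seq_len(nchar(s) - 7)) {
      win <- substr(s, i, i + 7)
      E <- 0
      for (k in 1:8) {
        E <- E + crx$ewm[k, match(substr(win, k, k), bases)]
      }
      total <- total + 1 / (1 + exp(E - crx$mu))
    }
  }
  expect_equal(res$total_occupancy, unname(total), tolerance = 1e-12)
  rc <- predicted_occupancy(reverse_complement(seq), crx)
  expect_identical(res$total_occupancy, rc$total_occupancy)
  expect_true(all(res$per_position$probability >= 0 &
                    res$per_position$probability <= 1))
  expect_equal(res$total_occupancy, sum(res$per_position$probability))
})

test_that("occupancy is monotone in mu and 0.5 at the logistic midpoint", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  prob <- sharp_prob("CTAATCCC")
  totals <- vapply(c(-2, 0, 2, 4, 6), function(mu) {
    predicted_occupancy(seq, motif_model("CRX", prob, mu = mu))$total_occupancy
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  # flat EWM at mu = 0: every window bound with probability exactly 1/2
  flat <- motif_model("flat", matrix(0.25, 4, 4),
                      ewm = matrix(0, 4, 4), mu = 0)
  res <- predicted_occupancy("ACGTACGTAC", flat)
  expect_true(all(res$per_position$probability == 0.5))
  expect_equal(res$total_occupancy, nrow(res$per_position) / 2)
})

test_that("Boltzmann information content reproduces multiset counts", {
  expect_equal(as.numeric(boltzmann_ic(c(2, rep(0, 7)))), 0)
  expect_equal(as.numeric(boltzmann_ic(c(1, 1, rep(0, 6)))), 1)
  expect_equal(as.numeric(boltzmann_ic(c(2, 1, 1, rep(0, 5)))), log2(12))
  # label permutation invariance
  expect_equal(boltzmann_ic(c(1, 2, 0, 1)), boltzmann_ic(c(0, 1, 1, 2)))
  # integer mode rounds first
  expect_equal(as.numeric(boltzmann_ic(c(1.9, 1.2, 0.8), mode = "integer")),
               log2(factorial(4) / (factorial(2) * factorial(1) *
                                      factorial(1))))
  # continuous form agrees with the factorial form at integers
  n <- c(3, 2, 1, 0)
  expect_equal(as.numeric(boltzmann_ic(n)),
               log2(factorial(6) / prod(factorial(n))))
  # all-zero occupancy flags rather than errors
  expect_warning(ic0 <- boltzmann_ic(rep(0, 8)), "zero")
  expect_equal(as.numeric(ic0), 0)
  expect_true(attr(ic0, "zero_occupancy"))
})

test_that("information content is insensitive to motif-free padding", {
  # sharp motif models so a poly-A pad carries >= 5 strong mismatches in
  # every window of every motif on either strand
  motifs <- list(CRX = motif_model("CRX", sharp_prob("CTAATCCC")),
                 NRL = motif_model("NRL", sharp_prob("TGCTGACT")),
                 NEUROD1 = motif_model("NEUROD1", sharp_prob("CCAGCTGG")))
  seq <- paste0(strrep("G", 12), "CTAATCCC", strrep("G", 10), "TGCTGACT",
                strrep("G", 12))
  base <- information_content(seq, motifs)
  padded <- information_content(paste0(seq, strrep("A", 30)), motifs)
  pad_occ <- sum(vapply(motifs, function(m) {
    predicted_occupancy(strrep("A", 30), m)$total_occupancy
  }, numeric(1)))
  expect_lt(pad_occ, 1e-8)
  expect_equal(padded$ic_bits, base$ic_bits, tolerance = 1e-6)
  expect_named(base$per_tf_occupancy, names(motifs))
})

test_that("score_sequences separates planted silencers from enhancers", {
  fix <- medium_run()
  scores <- score_sequences(fix$design)
  el <- fix$design$elements
  wt <- el[el$variant_class == "wild_type", ]
  sc <- scores[match(wt$element_id, scores$element_id), ]
  sil <- wt$planted_class %in% c("weak_silencer", "strong_silencer")
  enh <- wt$planted_class %in% c("weak_enhancer", "strong_enhancer")
  expect_gt(median(sc$crx_occupancy[sil]), median(sc$crx_occupancy[enh]))
  expect_gt(median(sc$ic_bits[enh]), median(sc$ic_bits[sil]))
})
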