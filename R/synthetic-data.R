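#' Synthetic MPRA data with known ground truth
#'
#' The generator emulates the statistical structure the analysis assumes:
#' approximately log-normal activities, a scrambled-control null centred on
#' the basal promoter, genotype-graded enhancer loss, amplification of weak
#' enhancers against a declining basal promoter, silencer derepression and
#' silencer-to-enhancer conversion restricted to genotypes lacking the CRX
#' transcriptional effector domain, and homotypic two-site cooperativity
#' quads.
#'
#' @name synthetic-data
NULL

#' Severity-ordered genotype names
#' @export
GENOTYPES <- c("wt", "R90W_het", "E168d2_het", "R90W_hom", "E168d2_hom",
               "null")

CLASS_LEVELS <- c("strong_silencer", "weak_silencer", "inactive",
                  "weak_enhancer", "strong_enhancer")

#' Genotype effect model for the synthetic generator
#'
#' Defaults encode the study conditions: six severity-ordered genotypes,
#' basal promoter activity declining with severity, per-genotype fractions
#' of enhancers losing a class, weak enhancers amplified relative to basal,
#' silencers derepressed, and conversion of flagged silencers restricted to
#' the two effector-domain-null genotypes (`E168d2_hom`, `null`).
#' Fractions for the intermediate genotypes interpolate the reported
#' severity gradient (lost enhancers 13/16/21%, amplified 13/18/23%).
#'
#' @param genotypes Ordered genotype names (wild type first).
#' @param basal_activity Positive basal promoter activity per genotype
#'   (RNA/DNA scale), non-increasing with severity.
#' @param enhancer_loss_fraction Per-genotype probability that an
#'   enhancer drops to a lower activity class.
#' @param amplified_fraction Per-genotype probability that a surviving
#'   weak enhancer becomes a strong enhancer relative to basal.
#' @param silencer_derepression Per-genotype probability that a
#'   non-converting silencer moves up a class (toward basal).
#' @param effector_null Logical per genotype: lacks the CRX effector
#'   domain (conversion-permissive).
#' @param noise_sd Log2-scale barcode noise SD in the count model.
#' @param scrambled_sd Log2 SD of scrambled-control true activities about
#'   basal (the empirical-null spread).
#' @param class_effects Canonical log2 activity relative to basal for each
#'   class.
#' @param strong_jitter,weak_jitter Half-widths of the per-element uniform
#'   jitter applied to strong/weak canonical effects.
#' @param conversion_gain,amplified_gain Log2 effect (relative to basal)
#'   of converted silencers / amplified weak enhancers in affected
#'   genotypes when they land in the strong-enhancer class.
#' @param coop_wt_effect,coop_delta_single Log2 effect of a two-site
#'   cooperativity element and of losing a single site.
#' @param sig_min Smallest |log2 effect| regarded as a true departure from
#'   basal when assigning ground-truth classes to derived effects.
#' @return Object of class `genotype_effect_model`.
#' @export
genotype_effect_model <- function(
    genotypes = GENOTYPES,
    basal_activity = c(1.00, 0.95, 0.85, 0.70, 0.55, 0.50),
    enhancer_loss_fraction = c(0, 0.13, 0.15, 0.16, 0.21, 0.27),
    amplified_fraction = c(0, 0.13, 0.15, 0.18, 0.23, 0.25),
    silencer_derepression = c(0, 0.05, 0.08, 0.30, 0.90, 0.97),
    effector_null = genotypes %in% c("E168d2_hom", "null"),
    noise_sd = 0.1,
    scrambled_sd = 0.4,
    class_effects = c(strong_silencer = -2.2, weak_silencer = -0.4,
                      inactive = 0, weak_enhancer = 0.4,
                      strong_enhancer = 2.2),
    strong_jitter = 0.25, weak_jitter = 0.05,
    conversion_gain = 1.2, amplified_gain = 1.2,
    coop_wt_effect = 2.0, coop_delta_single = 0.9,
    sig_min = 0.15) {
  n <- length(genotypes)
  stopifnot(
    n >= 1L, length(basal_activity) == n, all(basal_activity > 0),
    all(diff(basal_activity) <= 0),
    length(enhancer_loss_fraction) == n,
    all(enhancer_loss_fraction >= 0 & enhancer_loss_fraction <= 1),
    length(amplified_fraction) == n,
    all(amplified_fraction >= 0 & amplified_fraction <= 1),
    length(silencer_derepression) == n,
    all(silencer_derepression >= 0 & silencer_derepression <= 1),
    length(effector_null) == n, noise_sd >= 0, scrambled_sd > 0
  )
  structure(
    list(genotypes = genotypes, basal_activity = basal_activity,
         enhancer_loss_fraction = enhancer_loss_fraction,
         amplified_fraction = amplified_fraction,
         silencer_derepression = silencer_derepression,
         effector_null = effector_null, noise_sd = noise_sd,
         scrambled_sd = scrambled_sd, class_effects = class_effects,
         strong_jitter = strong_jitter, weak_jitter = weak_jitter,
         conversion_gain = conversion_gain, amplified_gain = amplified_gain,
         coop_wt_effect = coop_wt_effect,
         coop_delta_single = coop_delta_single, sig_min = sig_min),
    class = "genotype_effect_model"
  )
}

# Map a numeric log2 effect (relative to basal) to a ground-truth class,
# using the true scrambled quantiles and the sig_min surrogate for
# statistical distinguishability from basal.
effect_to_class <- function(effect, effects) {
  q95 <- stats::qnorm(0.95) * effects$scrambled_sd
  ifelse(abs(effect) < effects$sig_min, "inactive",
    ifelse(effect > 0,
      ifelse(effect > q95, "strong_enhancer", "weak_enhancer"),
      ifelse(effect < -q95, "strong_silencer", "weak_silencer")))
}

# Class index helpers on the ordered scale
class_rank <- function(class) match(class, CLASS_LEVELS)

#' Simulate ground-truth activities for every element and genotype
#'
#' Wild-type-genotype activities follow the planted classes (canonical
#' log2 effects relative to basal with persistent per-element jitter;
#' scrambled controls are log-normal about basal). Mutant-genotype
#' activities are derived deterministically from class, severity and the
#' element's persistent sensitivity draws: enhancers drop classes with the
#' genotype's loss fraction (homozygous genotypes can drop two), surviving
#' weak enhancers amplify relative to the declining basal, non-converting
#' silencers derepress toward basal, and conversion-flagged silencers gain
#' enhancer activity in effector-domain-null genotypes. Motif-mutant
#' partners are CRX-independent: their class (derived from the parent's)
#' is constant across genotypes. Two-site cooperativity quads receive
#' single/double-mutant effects consistent with the planted ratio.
#'
#' @param design A `library_design` from [build_synthetic_design()] (must
#'   carry the planted metadata columns).
#' @param effects A [genotype_effect_model()].
#' @param rng_seed Integer seed.
#' @return Object of class `ground_truth`: list with `activities` (tibble:
#'   element_id, genotype, true_activity, true_log2_rel_basal, true_class,
#'   conversion_flag), `coop` (tibble: element_id, planted_rho, delta_m1,
#'   delta_m2, delta_m12) and the `effects` model.
#' @export
simulate_true_activities <- function(design, effects = genotype_effect_model(),
                                     rng_seed = 1L) {
  el <- design$elements
  if (!all(c("planted_class", "planted_conversion", "coop_role",
             "planted_rho") %in% names(el))) {
    stop("design lacks planted ground-truth metadata; ",
         "use build_synthetic_design()", call. = FALSE)
  }
  G <- effects$genotypes
  n_g <- length(G)
  ranks <- seq_len(n_g)
  lev <- effects$class_effects

  with_seed(rng_seed, {
    n <- nrow(el)
    u_loss <- stats::runif(n)
    u_amp <- stats::runif(n)
    u_derep <- stats::runif(n)
    u_target <- stats::runif(n)   # conversion target class draw
    j_strong <- stats::runif(n, -effects$strong_jitter, effects$strong_jitter)
    j_weak <- stats::runif(n, -effects$weak_jitter, effects$weak_jitter)
    j_gain <- stats::runif(n, -0.1, 0.1)
    z_scram <- stats::rnorm(n, 0, effects$scrambled_sd)

    # canonical effect of a class for element i (persistent jitter)
    class_effect <- function(cl, i) {
      base <- lev[[cl]]
      jit <- if (cl %in% c("strong_enhancer", "strong_silencer"))
        j_strong[i] else if (cl == "inactive") 0 else j_weak[i]
      base + jit
    }
    mutant_class_of <- function(parent_class) {
      switch(parent_class,
             strong_enhancer = "weak_enhancer",
             weak_enhancer = "inactive",
             "inactive")
    }

    wt_class <- el$planted_class
    parent_idx <- match(el$parent_id, el$element_id)

    rows <- vector("list", n * n_g)
    k <- 0L
    for (i in seq_len(n)) {
      vclass <- el$variant_class[i]
      role <- el$coop_role[i]
      for (g in seq_len(n_g)) {
        eff <- NA_real_
        cls <- NA_character_
        conv <- FALSE
        if (vclass == "basal") {
          eff <- 0; cls <- "inactive"
        } else if (vclass == "scrambled") {
          eff <- z_scram[i]
          cls <- effect_to_class(eff, effects)
        } else if (!is.na(role)) {
          # cooperativity quad member; effects relative to basal are
          # genotype-independent by construction
          pi <- if (role == "wt") i else parent_idx[i]
          rho <- el$planted_rho[pi]
          wt_eff <- effects$coop_wt_effect + j_strong[pi]
          d1 <- effects$coop_delta_single
          eff <- switch(role,
                        wt = wt_eff,
                        m1 = wt_eff - d1,
                        m2 = wt_eff - d1,
                        m12 = wt_eff - (2 * d1) / rho)
          cls <- effect_to_class(eff, effects)
        } else if (vclass == "motif_mutant") {
          pcls <- wt_class[parent_idx[i]]
          cls <- mutant_class_of(pcls)
          eff <- class_effect(cls, i)
        } else { # wild-type CRE
          cls <- wt_class[i]
          i_enh <- cls %in% c("weak_enhancer", "strong_enhancer")
          i_sil <- cls %in% c("weak_silencer", "strong_silencer")
          if (i_enh) {
            loss <- effects$enhancer_loss_fraction[g]
            if (u_loss[i] < loss) {
              drop <- 1L + as.integer(u_loss[i] < 0.5 * loss &&
                                        ranks[g] >= 4L)
              cls <- CLASS_LEVELS[max(class_rank(cls) - drop, 3L)]
              eff <- class_effect(cls, i)
            } else if (cls == "weak_enhancer" &&
                       u_amp[i] < effects$amplified_fraction[g]) {
              eff <- effects$amplified_gain + j_gain[i]
              cls <- "strong_enhancer"
            } else {
              eff <- class_effect(cls, i)
            }
          } else if (i_sil) {
            conv <- isTRUE(el$planted_conversion[i])
            if (conv && effects$effector_null[g]) {
              if (u_target[i] < 0.6) {
                eff <- effects$conversion_gain + j_gain[i]
                cls <- "strong_enhancer"
              } else {
                eff <- class_effect("weak_enhancer", i)
                cls <- "weak_enhancer"
              }
            } else {
              derep <- effects$silencer_derepression[g]
              if (u_derep[i] < derep) {
                up <- 1L + as.integer(u_derep[i] < 0.5 * derep)
                cls <- CLASS_LEVELS[min(class_rank(cls) + up, 3L)]
                eff <- class_effect(cls, i)
              } else {
                eff <- class_effect(cls, i)
              }
            }
          } else { # inactive
            eff <- 0
          }
        }
        k <- k + 1L
        rows[[k]] <- list(element_id = el$element_id[i], genotype = G[g],
                          true_log2_rel_basal = eff, true_class = cls,
                          conversion_flag = conv)
      }
    }
    act <- dplyr::bind_rows(rows)
    act$genotype <- factor(act$genotype, levels = G)
    act$true_activity <- effects$basal_activity[as.integer(act$genotype)] *
      2^act$true_log2_rel_basal
    act$genotype <- as.character(act$genotype)
    act <- act[, c("element_id", "genotype", "true_activity",
                   "true_log2_rel_basal", "true_class", "conversion_flag")]

    coop_wt <- which(!is.na(el$coop_role) & el$coop_role == "wt")
    coop <- tibble(
      element_id = el$element_id[coop_wt],
      planted_rho = el$planted_rho[coop_wt],
      delta_m1 = effects$coop_delta_single,
      delta_m2 = effects$coop_delta_single,
      delta_m12 = (2 * effects$coop_delta_single) / el$planted_rho[coop_wt]
    )
    structure(list(activities = as_tibble(act), coop = coop,
                   effects = effects),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d element-genotype activities, %d coop quads\n",
              nrow(x$activities), nrow(x$coop)))
  invisible(x)
}

#' Simulate barcode count tables from ground truth
#'
#' DNA barcode representation follows a log-normal model (`dna_dispersion`
#' is the log SD of barcode weights); DNA counts are Poisson at the
#' sequencing depth. RNA counts per genotype and replicate are Poisson
#' with mean proportional to DNA proportion x true activity x depth x
#' exp(log-normal barcode noise). Every design barcode appears in the DNA
#' table.
#'
#' @param truth A `ground_truth` from [simulate_true_activities()].
#' @param design The matching `library_design`.
#' @param depth Expected reads per RNA sample (>= 1).
#' @param replicates Biological replicates per genotype (default 3).
#' @param dna_depth Expected reads for the single input plasmid DNA
#'   sample. The input library serves as denominator for every RNA
#'   sample and is sequenced deeply (default 1e7, over 1000x per barcode
#'   at the default library size, matching standard practice).
#' @param dna_dispersion Log SD of DNA barcode representation weights.
#' @param noise_sd Log2 SD of per-barcode-per-replicate RNA noise;
#'   defaults to the effect model's `noise_sd`.
#' @param rng_seed Integer seed.
#' @return List with `counts` (tibble: barcode + one column per sample)
#'   and `sample_sheet` (tibble: sample, type, genotype, replicate).
#' @export
simulate_counts <- function(truth, design, depth = 1e6, replicates = 3L,
                            dna_depth = 1e7, dna_dispersion = 0.5,
                            noise_sd = truth$effects$noise_sd,
                            rng_seed = 1L) {
  if (depth < 1 || dna_depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  bm <- design$barcode_map
  genotypes <- truth$effects$genotypes
  act <- truth$activities
  with_seed(rng_seed, {
    nb <- nrow(bm)
    w <- exp(stats::rnorm(nb, 0, dna_dispersion))
    prop <- w / sum(w)
    counts <- tibble(barcode = bm$barcode,
                     DNA = stats::rpois(nb, dna_depth * prop))
    sheet <- list(tibble(sample = "DNA", type = "DNA",
                         genotype = NA_character_, replicate = NA_integer_))
    for (g in genotypes) {
      a_g <- act[act$genotype == g, ]
      a_bc <- a_g$true_activity[match(bm$element_id, a_g$element_id)]
      if (anyNA(a_bc)) stop("ground truth missing elements for genotype ", g)
      for (r in seq_len(replicates)) {
        lam <- depth * prop * a_bc *
          2^stats::rnorm(nb, 0, noise_sd)
        nm <- sprintf("RNA_%s_rep%d", g, r)
        counts[[nm]] <- stats::rpois(nb, lam)
        sheet[[length(sheet) + 1L]] <-
          tibble(sample = nm, type = "RNA", genotype = g,
                 replicate = as.integer(r))
      }
    }
    list(counts = counts, sample_sheet = dplyr::bind_rows(sheet))
  })
}
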