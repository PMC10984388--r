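---
title: "Models and methods behind crxmpra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crxmpra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crxmpra)
```

## The experimental design the package models

crxmpra analyses massively parallel reporter assays (MPRAs) of
cis-regulatory elements (CREs) bound by the photoreceptor transcription
factor CRX. In the assay a library of 164-bp CREs sits upstream of a
minimal *Rhodopsin* promoter driving a reporter; each CRE is tagged by
four unique 3'-UTR barcodes (sixteen for the basal promoter alone, so the
reference point is measured precisely), and the library is delivered into
retinal explants of six *Crx* genotypes — wild type, heterozygous and
homozygous p.R90W (DNA-binding domain) and p.E168d2 (effector-domain
truncation), and the full knockout — each in three biological replicates.
Transcriptional activity of an element is its RNA barcode abundance
normalised to its abundance in the input plasmid DNA library.

The package covers the full analysis path: quantification, five-class
activity calls against an empirical null, cross-genotype dysregulation,
sequence scoring, and homotypic cooperativity, plus a synthetic-data
generator that produces count tables with known ground truth for every
downstream call.

## Quantification

Barcode counts are normalised to reads per million (RPM) per sample. For
each barcode the RNA/DNA RPM ratio is computed per replicate; ratios are
averaged across replicates and then across the element's barcodes
(`compute_activity()`), following the ratio → replicates → barcodes
order. The alternative pooled orderings differ only at second order for
balanced designs; the implemented order matches the way the measurement
is usually described. Log2 activity uses a pseudocount of 1e-3.

Two numerical guards are configurable:

* `min_dna_rpm` (default 5 RPM) excludes barcodes that are nearly absent
  from the input library, whose ratios are dominated by denominator
  noise. Setting it to 0 reproduces the unfiltered calculation; barcodes
  with exactly zero DNA are always excluded because their ratio is
  undefined. Elements losing all barcodes are flagged missing rather
  than dropped.
* RPM ratios are *relative* measurements: each RNA sample's ratios are
  scaled by the library-weighted mean activity of that sample. Every
  downstream quantity is basal- or scrambled-relative, so this global
  scale cancels; absolute activities are only meaningful up to it.

## Five-class activity calls

Expression is approximately log-normal, so element-vs-basal testing is
done on log2 values with Welch's *t*-test (`welch_test_vs_basal()`),
using the barcode-level replicate-averaged values as the unit of
replication — typically n = 4 element barcodes against the 16 basal
barcodes. Degenerate inputs (zero variance on both sides) are resolved
explicitly: equal means give p = 1. P-values are corrected per genotype
with Benjamini–Hochberg (`bh_adjust()`); the FDR cutoff `alpha` defaults
to 0.05 (conventional; the choice is exposed).

Classes (`classify_elements()`): elements not significantly different
from basal are **inactive**; significant increases are **strong
enhancers** if the element's log2 activity exceeds the 95th percentile of
the scrambled controls and **weak enhancers** otherwise; significant
decreases are **strong silencers** below the 5th percentile and **weak
silencers** otherwise. Percentiles are linear-interpolation empirical
quantiles (type 7) of the scrambled mean log2 activities, computed per
genotype; with fewer than 20 scrambled controls a stability warning is
emitted. Direction is taken from the difference of mean log values,
consistent with the log-normal framing.

## The scrambled empirical null and robust comparison

Scrambled controls are composition-matched sequences with no callable
CRX motif (`make_scrambled_control()`): i.i.d. draws from the target
mononucleotide composition, rejected while any motif occurrence scores
p ≤ 0.0025; a dinucleotide-preserving shuffle is available as an option.
Their activity distribution defines both the strong/weak thresholds and
the anchor for cross-genotype regression.

`robust_fit_scrambled()` implements a trimmed-mean M-estimator as
least-trimmed iteratively reweighted least squares: at each iteration the
fraction `trim_fraction` (default 0.2) of points with the largest
absolute residuals get weight zero and the line is refit, to slope
convergence at 1e-8 (ties on |residual| retain the smaller index, making
the fit deterministic). With `trim_fraction = 0` it is ordinary least
squares; a Huber M-estimator (`MASS::rlm`) sits behind `method =
"huber"`. "Trimmed mean M-estimator" admits both readings; the trimmed
form is the default as the more literal one.

`compare_genotypes()` then reports: the robust slope/intercept on the
scrambled controls (tracking basal promoter decline), per-element
residuals about that line with the 80th-percentile band over library
CREs, R² of log2 activities over library CREs shared by both genotypes
(computed on the log2 scale; scrambled controls and basal are excluded
from R² and the band so they measure CRE dysregulation, not the null),
the 5×5 class-transition matrix, and the derived id lists: lost
enhancers (any move to a strictly lower class on the ordered scale
strong_silencer < weak_silencer < inactive < weak_enhancer <
strong_enhancer), amplified weak enhancers (weak → strong), and
converted silencers (silencer → enhancer).
`find_converted_silencers()` defaults to requiring conversion in *all*
named effector-null genotypes (the stricter reading); `require_all =
FALSE` gives the any-genotype variant, and the pipeline reports both
counts.

## Sequence scoring

`scan_motif()` is a log2-odds scan with exact p-values: scores are
discretised into 1e-4 bins and the null distribution of the window score
under the background model is built by dynamic programming, so
`p = Pr(score ≥ observed)` is exact up to discretisation (verified
against exhaustive enumeration for toy motifs to 1e-6). Both strands are
scanned; minus-strand windows are scored as the reverse complement under
the same null. Non-ACGT symbols are an error naming the position — no
silent N handling. The standard threshold for calling CRX sites is
p ≤ 2.5e-3.

`mutate_crx_motifs()` abolishes called CRX occurrences by editing the
core TAAT to TACT in the motif's own orientation (minus-strand
occurrences edit ATTA → AGTA on the plus text). Because removing one of
two overlapping occurrences can leave the other callable, scan-and-edit
iterates (bounded at 10 rounds); a `site_subset` builds single- and
double-site mutants for cooperativity quads. An occurrence without a
TAAT core at the consensus offset is an error — it signals a
motif/consensus mismatch rather than something to silently skip.

`predicted_occupancy()` is the threshold-free statistic: every K-mer
window on both strands gets a binding energy from an energy weight
matrix (EWM; per-position penalties with the optimal base at zero) and a
logistic occupancy `1 / (1 + exp(E − μ))`, summed over windows. The EWM
and chemical potential μ are not uniquely determined by published
probability matrices; the package derives `ewm = −ln(p / max p)` per
position and sets μ so the consensus site is bound with probability
0.99 (μ = ln 99 ≈ 4.6). Both are overridable from file (`read_ewm_tsv()`,
`motif_model()`), and results that depend on the exact energy units
should use the historically calibrated matrices, which are not
redistributable here. The bundled eight-TF motif set
(`default_motif_set()`: CRX/OTX2, NRL, NEUROD1, RORB, MAZ/SP4, MEF2D,
RAX, GFI1) is a synthetic stand-in built from consensus sequences, with
qualitatively realistic occupancy behaviour but not the published
energies — absolute occupancy and information-content values therefore
differ from published ones even where orderings agree.

`information_content()` summarises motif diversity as Boltzmann entropy:
with per-TF occupancies `n_j` and `N = Σ n_j`, the score is
`log2(Γ(N+1) / Π Γ(n_j+1))` — the log2 multinomial microstate count at
integer occupancies, extended continuously via the Gamma function. An
integer mode (round first) is provided since the original calculation's
rounding convention is not restated in the sources this design follows;
the continuous form is the default because occupancies are inherently
fractional. All-zero occupancy returns 0 with a flag, not an error.

## Cooperativity

For a CRE with exactly two CRX sites, effects are losses of mean log2
activity in the wild type, each single mutant, and the double mutant;
`ρ = (δ₁ + δ₂) / δ₁₂`. Effects are taken on the log2 scale (they are
fold-changes); a linear-scale variant only changes ρ when effects are
large. ρ is reported only when |δ₁₂| > `min_effect` (0.1 log2 units) to
avoid ratio blow-up with an inert double mutant. A percentile bootstrap
over barcode-level values gives the CI; calls are `cooperative` (CI >
1), `sub_additive` (CI < 1), `additive` (CI inside 1 ± 0.25), and
`undetermined` otherwise — the CI-based call is this package's
operationalisation of "evidence of cooperativity", which is otherwise a
qualitative judgement. `cooperativity_sweep()` summarises medians and
cooperative fractions per genotype with a descriptive paired sign test.

## The synthetic-data generator

`build_synthetic_design()` + `simulate_true_activities()` +
`simulate_counts()` emulate the study's structure with known truth. The
defaults define the study conditions used throughout the tests and the
acceptance script:

* 1000 wild-type CREs (the real library has 1723), one CRX-motif-mutant
  partner each, 100 scrambled controls, 100 two-site cooperativity quads
  (wild type + two singles + double), one basal element; 4 barcodes per
  element and 16 for basal; 164 bp; 12-nt barcodes with pairwise Hamming
  distance ≥ 2 via a checksum base.
* Planted wild-type class mix: 22/28/20/16/14% strong enhancer / weak
  enhancer / inactive / weak silencer / strong silencer — a majority of
  enhancers with silencers at ~30%, the qualitative mix of CRX-bound
  accessible chromatin. 48% of silencers carry a conversion flag
  (mirroring 234 of 485 wild-type silencers converting).
* Motif planting follows class: silencers get 3–4 CRX sites and few
  other-TF sites, enhancers 1–2 CRX plus 2–3 other-TF sites, and
  conversion-flagged silencers get both — reproducing the
  high-occupancy/high-information profile of bifunctional elements.
  Chromatin-group and rod/cone proximity labels are sampled with mild
  class conditioning (silencers enriched near cone genes and in
  late-accessible distal groups).
* True activities: log2 effects relative to basal of ±0.4 (weak), ±2.2
  (strong) with small persistent per-element jitter; scrambled controls
  are log-normal about basal with SD 0.4 log2. These levels deliberately
  sit away from the decision boundaries (the significance floor and the
  scrambled 5th/95th percentiles at ±0.66), so recovery failures
  indicate pipeline defects rather than boundary coin-flips.
* Genotype effects are graded by severity (wt < R90W/+ < E168d2/+ <
  R90W/W < E168d2/d2 < −/−): basal activity declines
  1.00/0.95/0.85/0.70/0.55/0.50; enhancer-loss fractions
  0/0.13/0.15/0.16/0.21/0.27 and weak-enhancer amplification
  0/0.13/0.15/0.18/0.23/0.25 interpolate the reported percentages;
  silencer derepression 0/0.05/0.08/0.30/0.90/0.97; conversion applies
  only in the two effector-null genotypes. Per-element uniform
  sensitivity draws make affected sets nested across genotypes, as
  observed for the real variants. Motif-mutant partners respond to
  genotype only through basal (their CRX sites are gone).
* Counts: DNA barcode representation is log-normal (sdlog 0.5) and the
  input plasmid library is a single deeply sequenced sample
  (`dna_depth = 1e7`, ≈1085× per barcode at the default library size,
  matching the deep coverage such input libraries receive); RNA samples
  are Poisson at `depth = 1e6` with log-normal per-barcode noise (SD 0.1
  log2).

One normalisation consequence worth knowing: the generator encodes the
basal-promoter decline as a genotype-global multiplicative factor, and
RPM ratios cancel any genotype-global factor. In simulated *measured*
data the scrambled-anchored fits therefore stay near the identity line,
and basal decline expresses itself through the class structure instead —
weak enhancers amplified *relative to basal* — rather than through the
fit intercept as it does when absolute activities are observable.

What the generator does *not* emulate: sequencing errors and barcode
hopping, PCR jackpots, replicate batch effects, transfection-efficiency
drift, and any genomic-context effects — so passing recovery tests shows
the pipeline correctly inverts its own generative assumptions, not that
those assumptions exhaust real MPRA noise. One realistic artifact it
*does* reproduce: because every element is compared against the same
measured basal barcodes, the basal element's finite sampling error is
shared across all tests in a genotype, slightly correlating calls near
the significance boundary; the sixteen basal barcodes and deep DNA
coverage keep this small.

The end-to-end expectations at the default conditions (verified in the
test suite with a fixed seed): ≥ 90% five-class agreement with ground
truth over library CREs across all six genotypes, ≥ 80% sensitivity and
≤ 10% false-positive rate for conversion calls, monotonically
non-increasing R² along the severity order, and ≥ 90% of cooperativity
ratios within ±0.15 of their planted values. A full run takes on the
order of a minute; the routine test fixtures use a 150-CRE library at
depth 3e5, which keeps the suite fast while preserving the structure.

## Known limitations

* Welch's test on four barcode values is a small-sample test; its
  calibration leans on the log-normal assumption and the 16 basal
  barcodes. A count-based GLM would model the noise more directly but is
  a different method from the one implemented here by design.
* The conversion call compounds three classification events (silencer in
  reference, enhancer in each test genotype), so its sensitivity is the
  product of per-genotype powers; the `require_all = FALSE` mode trades
  specificity for sensitivity.
* Occupancy and information content depend on the motif energies; with
  the bundled synthetic motif set only orderings and within-run
  contrasts are meaningful.
* Desk-scale reproduction of the published transition counts (e.g. the
  234 converted silencers) requires the deposited per-genotype
  classification tables, which are not redistributable with the package;
  the counting machinery itself is exercised on synthetic data.
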