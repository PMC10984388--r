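#' Bundled reference tables from the source study
#'
#' Two small plain-text tables ship with the package: the counts of
#' differentially expressed (DE) genes in homozygous Crx-mutant retinas
#' from the companion RNA-seq analysis (up-regulated vs total, per
#' genotype), and the chromatin-environment annotation of the MPRA library
#' CREs (groups A/C/D by H3K4me3/H3K27ac marks, CRX-dependent vs
#' -independent accessibility, and the number of library CREs per group).
#' They support desk-scale consistency checks: the fraction of
#' up-regulated DE genes per genotype, Fisher's exact test comparing the
#' two genotypes, and the total library CRE count.
#'
#' @return Tibbles: `de_gene_counts()` has columns genotype,
#'   up_regulated, total_de; `chromatin_group_table()` has group,
#'   h3k4me3, h3k27ac, tss_distance, accessibility, timing, n_cres.
#' @export
de_gene_counts <- function() {
  path <- system.file("extdata", "de_gene_counts.tsv", package = "crxmpra",
                      mustWork = TRUE)
  as_tibble(utils::read.delim(path))
}

#' @rdname de_gene_counts
#' @export
chromatin_group_table <- function() {
  path <- system.file("extdata", "chromatin_groups.tsv",
                      package = "crxmpra", mustWork = TRUE)
  as_tibble(utils::read.delim(path))
}

#' Derepression contrast between homozygous mutant genotypes
#'
#' Computes, from [de_gene_counts()], the percentage of up-regulated DE
#' genes per genotype and a two-sided Fisher's exact test of the 2 x 2
#' up/down table across the two genotypes — the transcriptome-level
#' counterpart of MPRA silencer derepression.
#'
#' @return List with `percent_up` (named numeric, percent) and `fisher_p`.
#' @export
derepression_contrast <- function() {
  de <- de_gene_counts()
  pct <- 100 * de$up_regulated / de$total_de
  names(pct) <- de$genotype
  tab <- rbind(de$up_regulated, de$total_de - de$up_regulated)
  list(percent_up = pct,
       fisher_p = stats::fisher.test(tab)$p.value)
}
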