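#' Packaged reference tables
#'
#' Small plain-text data sets shipped with the package: the published
#' replicate-clustering matrices and their printed discrimination
#' metrics for eight primer pairs, the eight-population haplotype
#' frequency/coordinate table used throughout the phylogeography
#' examples, the list of nucleotide contrasts that melt analysis failed
#' to separate, and a *synthetic* stand-in for the wild haplotype
#' alignment (the published sequences live in GenBank; the stand-in
#' reproduces the described variation structure - five haplotypes,
#' 561 bp over two loci, five SNPs plus one 7 bp indel in a star
#' around the ancestral haplotype - but not the real nucleotides).
#'
#' @name hrm_fixtures
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "hrmhap", mustWork = TRUE)
}

#' @describeIn hrm_fixtures replicate matrices, a named list of
#'   [replicate_matrix()] objects keyed by primer pair.
#' @export
hrm_table3 <- function() {
  x <- readr::read_tsv(fixture_path("table3_replicates.tsv"),
                       show_col_types = FALSE)
  lapply(split(x, factor(x$primer_pair, levels = unique(x$primer_pair))),
         function(part) {
           n <- part$n[!duplicated(part$haplotype)]
           names(n) <- part$haplotype[!duplicated(part$haplotype)]
           replicate_matrix(part[c("haplotype", "cluster", "count")], n = n)
         })
}

#' @describeIn hrm_fixtures printed discrimination metrics per
#'   haplotype, with internally inconsistent cells flagged.
#' @export
hrm_table3_metrics <- function() {
  readr::read_tsv(fixture_path("table3_metrics.tsv"), show_col_types = FALSE)
}

#' @describeIn hrm_fixtures population haplotype counts, coordinates
#'   and mountain-range groups.
#' @export
hrm_table5 <- function() {
  readr::read_tsv(fixture_path("table5_populations.tsv"),
                  show_col_types = FALSE)
}

#' @describeIn hrm_fixtures nucleotide contrasts not separated by melt
#'   clustering, with the specificity each produced.
#' @export
hrm_table6 <- function() {
  readr::read_tsv(fixture_path("table6_contrasts.tsv"), show_col_types = FALSE)
}

#' @describeIn hrm_fixtures synthetic wild polymorphic-site table
#'   (positions, SNP classes, per-haplotype alleles).
#' @export
hrm_wild_sites <- function() {
  readr::read_tsv(fixture_path("wild_sites_synthetic.tsv"),
                  show_col_types = FALSE, na = "NA")
}

# locus boundaries of the concatenated synthetic alignment
wild_loci <- c("atpI-atpH" = 217L, "ndhA" = 344L)

#' @describeIn hrm_fixtures synthetic wild haplotype alignment, whole
#'   (`"concatenated"`, 561 bp) or sliced per locus.
#' @param locus which alignment to return.
#' @export
hrm_wild_haplotypes <- function(locus = c("concatenated", "atpI-atpH",
                                          "ndhA")) {
  locus <- match.arg(locus)
  set <- read_haplotype_fasta(fixture_path("wild_haplotypes_synthetic.fasta"),
                              locus = "concatenated")
  if (locus == "concatenated") return(set)
  start <- if (locus == "atpI-atpH") 1L else wild_loci[["atpI-atpH"]] + 1L
  end <- start + wild_loci[[locus]] - 1L
  haplotype_set(set$label, substr(set$sequence, start, end), locus = locus)
}
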