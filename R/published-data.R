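## Published characterization tables for the two deposited mitogenomes:
## Ampelophaga rubiginosa (GenBank KT153024, 15,282 bp) and Rondotia
## menciana (GenBank KT258908, 15,636 bp). Shipped as plain TSV under
## inst/extdata and used as desk-scale inputs for reproduction tests.

.speciesKey <- function(species) {
  key <- match.arg(species, c("A_rubiginosa", "R_menciana"))
  c(A_rubiginosa = "arubiginosa", R_menciana = "rmenciana")[[key]]
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "mitochar")
  if (!nzchar(path)) stop("missing extdata file ", file)
  path
}

#' Published annotation summary of a deposited mitogenome
#'
#' The full 38-row annotation table (coordinates, strands, anticodons,
#' start/stop codons, sizes and intergenic spacers as printed) for one of
#' the two deposited genomes. The published table's intergenic value for
#' the final A+T-rich-region row is blank and stored as \code{NA}; the
#' circular-closure value is computable with
#' \code{\link{buildSummaryTable}}.
#'
#' @param species \code{"A_rubiginosa"} or \code{"R_menciana"}.
#' @return \code{data.frame} with columns \code{gene}, \code{klass},
#'   \code{strand}, \code{start}, \code{end}, \code{anticodon},
#'   \code{start_codon}, \code{stop_codon}, \code{size},
#'   \code{intergenic}.
#' @export
publishedFeatureTable <- function(species = c("A_rubiginosa", "R_menciana")) {
  read.delim(.extdata(paste0(.speciesKey(species), "_summary_published.tsv")),
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Published per-class composition counts of a deposited mitogenome
#'
#' Region sizes, A/T/G/C counts and the printed percentages and skews for
#' the whole genome and each region class.
#'
#' @param species \code{"A_rubiginosa"} or \code{"R_menciana"}.
#' @return \code{data.frame} with columns \code{region}, \code{size},
#'   \code{A}, \code{T}, \code{G}, \code{C}, \code{pctA}, \code{pctT},
#'   \code{pctG}, \code{pctC}, \code{pctAT}, \code{at_skew},
#'   \code{gc_skew}.
#' @export
publishedComposition <- function(species = c("A_rubiginosa", "R_menciana")) {
  read.delim(.extdata(paste0(.speciesKey(species), "_composition_published.tsv")),
             stringsAsFactors = FALSE)
}

#' Published codon counts and RSCU of a deposited mitogenome
#'
#' The 64-row codon-usage table (RNA-alphabet codons, amino acid under
#' transl_table 5, pooled PCG counts and printed 2-decimal RSCU).
#'
#' @param species \code{"A_rubiginosa"} or \code{"R_menciana"}.
#' @return \code{data.frame} with columns \code{codon},
#'   \code{amino_acid}, \code{count}, \code{rscu_published}.
#' @export
publishedCodonCounts <- function(species = c("A_rubiginosa", "R_menciana")) {
  read.delim(.extdata(paste0(.speciesKey(species), "_codon_counts_published.tsv")),
             stringsAsFactors = FALSE)
}

#' Published feature coordinates as a MitoGenome over a placeholder sequence
#'
#' Coordinate-level statistics (sizes, spacers, gene order, region
#' location) need no real sequence; this helper wraps the published
#' feature coordinates around a synthetic all-A sequence of the deposited
#' genome's length, clearly not the deposited sequence itself.
#'
#' @param species \code{"A_rubiginosa"} or \code{"R_menciana"}.
#' @param drop_control drop the A+T-rich-region row (e.g. to exercise
#'   \code{\link{locateATRichRegion}}'s gap search).
#' @return a \linkS4class{MitoGenome}.
#' @export
publishedCoordinateGenome <- function(species = c("A_rubiginosa",
                                                  "R_menciana"),
                                      drop_control = FALSE) {
  tab <- publishedFeatureTable(species)
  len <- tab$end[nrow(tab)]   # final feature ends at the genome length
  ft <- tab[, c("gene", "klass", "strand", "start", "end", "anticodon")]
  names(ft)[1L] <- "name"
  if (drop_control) ft <- ft[ft$klass != "control", , drop = FALSE]
  MitoGenome(.speciesKey(species), strrep("A", len), ft)
}
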