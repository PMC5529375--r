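## Codon usage and RSCU under the invertebrate mitochondrial genetic code
## (transl_table 5: AGA/AGG -> Ser, ATA -> Met, TGA -> Trp; stops TAA/TAG).
## Computation uses DNA codons; reports transliterate to RNA (T -> U).

.DNA_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"), paste0),
                               c("T", "C", "A", "G"), paste0))

#' Convert codons between DNA and RNA alphabets
#' @param codons character vector of codons.
#' @return transliterated codons.
#' @export
codonToRNA <- function(codons) chartr("Tt", "Uu", codons)

#' @rdname codonToRNA
#' @export
codonToDNA <- function(codons) chartr("Uu", "Tt", codons)

#' The invertebrate mitochondrial genetic code (transl_table 5)
#'
#' Total mapping of the 64 DNA codons to amino-acid one-letter symbols
#' (stop = \code{"*"}) plus the partition into synonymous families. Under
#' this code AGA/AGG encode Ser (8-codon Ser family), ATA encodes Met and
#' TGA encodes Trp; the only stops are TAA and TAG, which form a 2-codon
#' family of their own for RSCU purposes.
#'
#' @return list with \code{table_id = 5}, \code{codon_to_aa} (named
#'   character, DNA codons), and \code{families} (list of codon vectors
#'   keyed by amino-acid symbol).
#' @examples
#' code <- mitoGeneticCode()
#' code$codon_to_aa[c("AGA", "ATA", "TGA")]  # S, M, W
#' lengths(code$families)[c("L", "S")]       # 6, 8
#' @export
mitoGeneticCode <- function() {
  aa <- Biostrings::getGeneticCode("5")[.DNA_CODONS]
  list(table_id = 5L,
       codon_to_aa = aa,
       families = split(names(aa), unname(aa)))
}

#' Count codons across protein-coding sequences
#'
#' Reads each CDS as non-overlapping triplets from position 1, discarding
#' a trailing 1-2 nt (incomplete stop codons); complete stop codons are
#' counted. Counts are pooled across all input sequences.
#'
#' @param cds_list character vector (or list) of sense-strand CDS strings.
#' @return named integer vector over the 64 DNA codons.
#' @examples
#' countCodons("ATGAAAT")[c("ATG", "AAA")]  # 1, 1; trailing T dropped
#' @export
countCodons <- function(cds_list) {
  counts <- setNames(integer(64), .DNA_CODONS)
  for (cds in as.character(unlist(cds_list))) {
    cds <- toupper(cds)
    n3 <- nchar(cds) %/% 3L
    if (n3 == 0L) next
    codons <- substring(cds, 3L * seq_len(n3) - 2L, 3L * seq_len(n3))
    tab <- table(codons)
    known <- intersect(names(tab), .DNA_CODONS)
    counts[known] <- counts[known] + as.integer(tab[known])
  }
  counts
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{i} in a synonymous family of size \eqn{k} with family
#' total \eqn{n}: \eqn{RSCU_i = count_i \times k / n} — the observed count
#' divided by the count expected under uniform usage within the family.
#' Every codon of a family with zero total gets RSCU 0. Within a nonzero
#' family the RSCU values sum to the family size.
#'
#' @param counts named integer vector over the 64 DNA codons
#'   (\code{\link{countCodons}}).
#' @param code genetic code from \code{\link{mitoGeneticCode}}.
#' @return named numeric vector of RSCU values over the 64 DNA codons.
#' @examples
#' counts <- countCodons(character(0))
#' counts[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")] <-
#'   c(482L, 14L, 26L, 2L, 20L, 0L)
#' round(rscu(counts)[["TTA"]], 2)  # 5.32
#' @export
rscu <- function(counts, code = mitoGeneticCode()) {
  stopifnot(all(.DNA_CODONS %in% names(counts)))
  out <- setNames(numeric(64), .DNA_CODONS)
  for (fam in code$families) {
    n <- sum(counts[fam])
    out[fam] <- if (n > 0) counts[fam] * length(fam) / n else 0
  }
  out
}

#' Amino-acid composition from codon counts
#'
#' Sums codon counts per amino acid, excluding stop codons. With
#' \code{split_families = TRUE} the six-codon Leu and eight-codon Ser
#' families are reported as the conventional two-box categories Leu(UUR) /
#' Leu(CUN) and Ser(AGN) / Ser(UCN).
#'
#' @param counts named integer vector over the 64 DNA codons.
#' @param code genetic code from \code{\link{mitoGeneticCode}}.
#' @param split_families split Leu and Ser by codon box.
#' @return named integer vector of amino-acid counts.
#' @examples
#' counts <- countCodons(character(0))
#' counts[c("ATA", "ATG")] <- c(276L, 21L)
#' aaComposition(counts)[["M"]]  # 297
#' @export
aaComposition <- function(counts, code = mitoGeneticCode(),
                          split_families = FALSE) {
  stopifnot(all(.DNA_CODONS %in% names(counts)))
  fams <- code$families[names(code$families) != "*"]
  if (split_families) {
    fams <- fams[!names(fams) %in% c("L", "S")]
    fams <- c(fams,
              list("L(UUR)" = c("TTA", "TTG"),
                   "L(CUN)" = c("CTT", "CTC", "CTA", "CTG"),
                   "S(AGN)" = c("AGT", "AGC", "AGA", "AGG"),
                   "S(UCN)" = c("TCT", "TCC", "TCA", "TCG")))
  }
  vapply(fams, function(f) as.integer(sum(counts[f])), integer(1))
}

#' Codon usage table for a genome
#'
#' Pools the sense-strand CDSs of all protein-coding genes, counts codons
#' and computes RSCU and amino-acid assignments under transl_table 5.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param code genetic code from \code{\link{mitoGeneticCode}}.
#' @return \code{data.frame} with columns \code{codon} (RNA alphabet),
#'   \code{amino_acid}, \code{count}, \code{rscu}.
#' @export
codonUsageTable <- function(genome, code = mitoGeneticCode()) {
  stopifnot(is(genome, "MitoGenome"))
  ft <- features(genome)
  cds <- lapply(which(ft$klass == "PCG"),
                function(i) extractFeatureSequence(genome, ft[i, ]))
  counts <- countCodons(cds)
  data.frame(codon = codonToRNA(.DNA_CODONS),
             amino_acid = unname(code$codon_to_aa[.DNA_CODONS]),
             count = unname(counts[.DNA_CODONS]),
             rscu = unname(rscu(counts, code)[.DNA_CODONS]),
             stringsAsFactors = FALSE)
}

#' Write codon usage and amino-acid composition reports as TSV
#'
#' RSCU is rounded to 2 decimals unless \code{raw = TRUE}.
#'
#' @param usage output of \code{\link{codonUsageTable}}.
#' @param path output file; \code{NULL} returns the TSV text.
#' @param genome_id optional id column value.
#' @param raw keep full precision.
#' @return path (invisibly) or TSV text.
#' @export
writeCodonUsageTSV <- function(usage, path = NULL, genome_id = NULL,
                               raw = FALSE) {
  out <- usage
  if (!raw) out$rscu <- round(out$rscu, 2)
  if (!is.null(genome_id)) out <- cbind(genome = genome_id, out)
  if (is.null(path)) {
    con <- textConnection("txt", "w", local = TRUE)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(paste0(paste(txt, collapse = "\n"), "\n"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
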