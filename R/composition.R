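## Nucleotide composition and strand-asymmetry (skew) statistics per
## region class. AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C).
## N is counted as neither AT nor GC.

#' Base counts of a DNA string
#'
#' @param seq a character string over A/C/G/T/N (empty allowed).
#' @return named integer vector with components A, T, G, C, N.
#' @examples
#' baseCounts("AATG")  # A=2 T=1 G=1 C=0 N=0
#' @export
baseCounts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq))
    return(c(A = 0L, T = 0L, G = 0L, C = 0L, N = 0L))
  f <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(seq)),
                                   c("A", "T", "G", "C", "N"))
  setNames(as.integer(f), c("A", "T", "G", "C", "N"))
}

#' AT skew
#'
#' Strand asymmetry between adenine and thymine:
#' \eqn{(A - T) / (A + T)}. \code{NA} when \code{A + T = 0}.
#'
#' @param countA,countT non-negative counts.
#' @return numeric in \eqn{[-1, 1]} or \code{NA}.
#' @examples
#' atSkew(6334, 6126)  # 0.0167 -> prints as 0.017
#' @export
atSkew <- function(countA, countT) {
  if (countA + countT == 0) return(NA_real_)
  (countA - countT) / (countA + countT)
}

#' GC skew
#'
#' Strand asymmetry between guanine and cytosine:
#' \eqn{(G - C) / (G + C)}. \code{NA} when \code{G + C = 0}.
#'
#' @param countG,countC non-negative counts.
#' @return numeric in \eqn{[-1, 1]} or \code{NA}.
#' @examples
#' gcSkew(1144, 1678)  # -0.189
#' @export
gcSkew <- function(countG, countC) {
  if (countG + countC == 0) return(NA_real_)
  (countG - countC) / (countG + countC)
}

.statsRow <- function(region, seqs) {
  counts <- Reduce(`+`, lapply(seqs, baseCounts),
                   c(A = 0L, T = 0L, G = 0L, C = 0L, N = 0L))
  size <- sum(nchar(seqs))
  pct <- function(x) if (size > 0) 100 * x / size else NA_real_
  data.frame(region = region, size_nt = as.integer(size),
             A = counts[["A"]], T = counts[["T"]],
             G = counts[["G"]], C = counts[["C"]], N = counts[["N"]],
             pctA = pct(counts[["A"]]), pctT = pct(counts[["T"]]),
             pctG = pct(counts[["G"]]), pctC = pct(counts[["C"]]),
             pctAT = pct(counts[["A"]] + counts[["T"]]),
             at_skew = atSkew(counts[["A"]], counts[["T"]]),
             gc_skew = gcSkew(counts[["G"]], counts[["C"]]),
             stringsAsFactors = FALSE)
}

#' Composition and skew statistics per region class
#'
#' Computes one row of composition statistics for the whole genome
#' (counted once, on the majority strand) and for each gene class (PCGs,
#' tRNAs, rRNAs, A+T-rich region). A class is counted as the
#' concatenation of its members' sense-strand (reading-direction)
#' sequences; overlapping features are counted per feature, not
#' deduplicated. Percentages and skews are kept at full precision; see
#' \code{\link{writeCompositionTSV}} for report rounding.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return \code{data.frame} with one row per region class: counts,
#'   percentages, \code{at_skew}, \code{gc_skew}. Empty classes get size 0
#'   and \code{NA} skews.
#' @export
compositionByClass <- function(genome) {
  stopifnot(is(genome, "MitoGenome"))
  ft <- features(genome)
  classSeqs <- function(klass) {
    idx <- which(ft$klass == klass)
    if (!length(idx)) return(character(0))
    vapply(idx, function(i) extractFeatureSequence(genome, ft[i, ]),
           character(1))
  }
  rows <- rbind(
    .statsRow("whole_genome", as.character(genomeSeq(genome))),
    .statsRow("PCGs", classSeqs("PCG")),
    .statsRow("tRNAs", classSeqs("tRNA")),
    .statsRow("rRNAs", classSeqs("rRNA")),
    .statsRow("AT_rich_region", classSeqs("control")))
  rownames(rows) <- NULL
  rows
}

#' Write a composition report as TSV
#'
#' Percentages are rounded to 1 decimal and skews to 3 decimals (the
#' conventional print format) unless \code{raw = TRUE}.
#'
#' @param stats output of \code{\link{compositionByClass}}.
#' @param path output file; \code{NULL} returns the TSV text.
#' @param genome_id optional id column value.
#' @param raw keep full precision.
#' @return path (invisibly) or TSV text.
#' @export
writeCompositionTSV <- function(stats, path = NULL, genome_id = NULL,
                                raw = FALSE) {
  out <- stats
  if (!raw) {
    for (col in c("pctA", "pctT", "pctG", "pctC", "pctAT"))
      out[[col]] <- round(out[[col]], 1)
    for (col in c("at_skew", "gc_skew"))
      out[[col]] <- round(out[[col]], 3)
  }
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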