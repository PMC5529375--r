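## Annotation summary: gene sizes, intergenic spacers, start/stop codon
## classification (complete and incomplete mitochondrial stops).

.CANONICAL_STARTS <- c("ATA", "ATT", "ATC", "ATG", "CGA")

#' Length of a feature on a circular genome
#'
#' \code{end - start + 1} for ordinary features; features with
#' \code{end < start} wrap across the origin and have length
#' \code{genome_length - start + 1 + end}.
#'
#' @param feature one-row data.frame/list with \code{start} and \code{end},
#'   or a numeric \code{c(start, end)} pair.
#' @param genome_length total genome length, needed for wrapping features.
#' @return integer length in bp.
#' @examples
#' featureLength(c(1463, 2990))           # 1528
#' featureLength(c(15280, 5), 15282)      # 8, wraps the origin
#' @export
featureLength <- function(feature, genome_length = NA_integer_) {
  if (is.numeric(feature)) feature <- list(start = feature[1], end = feature[2])
  start <- as.integer(feature$start); end <- as.integer(feature$end)
  if (start < 1L || end < 1L) stop("coordinates must be >= 1")
  if (end >= start) return(end - start + 1L)
  if (is.na(genome_length))
    stop("wrapping feature needs genome_length")
  as.integer(genome_length) - start + 1L + end
}

#' Intergenic spacer between two consecutive features
#'
#' Number of nucleotides strictly between \code{prev} and \code{next_};
#' negative values denote overlap. When \code{prev} is the genome's last
#' feature and \code{next_} its first, the spacer closes the circle
#' (wrapped distance).
#'
#' @param prev,next_ one-row data.frames/lists with \code{start},
#'   \code{end} (and \code{name} for error messages).
#' @param genome_length total genome length.
#' @param circular_closure set \code{TRUE} when \code{next_} precedes
#'   \code{prev} in coordinates because the pair closes the circle.
#' @return integer spacer (negative = overlap).
#' @examples
#' intergenicSpacer(list(end = 198), list(start = 255))    # 56
#' intergenicSpacer(list(end = 4043), list(start = 4037))  # -7
#' @export
intergenicSpacer <- function(prev, next_, genome_length = NA_integer_,
                             circular_closure = FALSE) {
  pe <- as.integer(prev$end); ns <- as.integer(next_$start)
  if (!is.null(prev$start) && !is.null(next_$start) &&
      identical(as.integer(prev$start), ns) && identical(pe, as.integer(next_$end)))
    stop("intergenic spacer of a feature with itself is undefined")
  if (circular_closure) {
    if (is.na(genome_length)) stop("circular closure needs genome_length")
    return(as.integer(genome_length) - pe + ns - 1L)
  }
  ns - pe - 1L
}

#' Classify the start codon of a protein-coding sequence
#'
#' Returns the first codon and whether it belongs to the canonical
#' mitochondrial start set \{ATA, ATT, ATC, ATG, CGA\} (CGA is the
#' conserved lepidopteran cox1 initiator).
#'
#' @param cds sense-strand CDS string, length >= 3.
#' @return list with \code{codon} and \code{canonical} (logical).
#' @examples
#' classifyStartCodon("CGAGCT")  # CGA, canonical
#' classifyStartCodon("GTGAAA")  # GTG, noncanonical
#' @export
classifyStartCodon <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than 3 nt")
  codon <- substr(cds, 1L, 3L)
  list(codon = codon, canonical = codon %in% .CANONICAL_STARTS)
}

#' Classify the stop codon of a protein-coding sequence
#'
#' Mitochondrial CDSs may end in a complete stop (TAA/TAG) or an
#' incomplete one (T, TA, or A) completed to UAA by polyadenylation of the
#' transcript. Classification is driven by the CDS length modulo 3:
#' \itemize{
#'   \item remainder 0 and last codon TAA/TAG: that codon;
#'   \item remainder 1 and last base T or A: that single base;
#'   \item remainder 2 and last two bases TA: \code{"TA"};
#'   \item anything else: \code{"OTHER"}, flagged inconsistent.
#' }
#'
#' @param cds sense-strand CDS string, length >= 4.
#' @return list with \code{stop} (one of TAA, TAG, T, TA, A, OTHER) and
#'   \code{consistent} (logical).
#' @examples
#' classifyStopCodon("ATGAAATAA")$stop   # "TAA"
#' classifyStopCodon("ATGAAAT")$stop     # "T" (incomplete)
#' @export
classifyStopCodon <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 4L) stop("CDS shorter than 4 nt")
  r <- n %% 3L
  if (r == 0L) {
    last3 <- substr(cds, n - 2L, n)
    if (last3 %in% c("TAA", "TAG"))
      return(list(stop = last3, consistent = TRUE))
  } else if (r == 1L) {
    last1 <- substr(cds, n, n)
    if (last1 %in% c("T", "A"))
      return(list(stop = last1, consistent = TRUE))
  } else {
    last2 <- substr(cds, n - 1L, n)
    if (last2 == "TA")
      return(list(stop = "TA", consistent = TRUE))
  }
  list(stop = "OTHER", consistent = FALSE)
}

#' Build the annotation summary table
#'
#' One row per feature, in genome order: coordinates, size, anticodon,
#' start/stop codon for protein-coding genes (computed from the extracted
#' sense-strand sequence), and the intergenic spacer to the next feature.
#' The last feature's spacer closes the circle back to the first.
#' \code{start_ok}/\code{stop_ok} flag codons outside the canonical sets.
#'
#' @param genome a \linkS4class{MitoGenome} with at least one feature.
#' @return \code{data.frame} with columns \code{gene}, \code{klass},
#'   \code{direction}, \code{start}, \code{end}, \code{size_nt},
#'   \code{anticodon}, \code{start_codon}, \code{stop_codon},
#'   \code{start_ok}, \code{stop_ok}, \code{intergenic_nt}.
#' @export
buildSummaryTable <- function(genome) {
  stopifnot(is(genome, "MitoGenome"))
  ft <- features(genome)
  if (!nrow(ft)) stop("genome has no features")
  len <- genomeLength(genome)
  n <- nrow(ft)
  size <- vapply(seq_len(n), function(i) featureLength(ft[i, ], len),
                 integer(1))
  start_codon <- stop_codon <- rep(NA_character_, n)
  start_ok <- stop_ok <- rep(NA, n)
  for (i in which(ft$klass == "PCG")) {
    cds <- extractFeatureSequence(genome, ft[i, ])
    st <- classifyStartCodon(cds); sp <- classifyStopCodon(cds)
    start_codon[i] <- st$codon; start_ok[i] <- st$canonical
    stop_codon[i] <- sp$stop; stop_ok[i] <- sp$consistent
  }
  intergenic <- integer(n)
  for (i in seq_len(n)) {
    if (n == 1L) {
      ## a lone feature closes the circle onto itself
      intergenic[i] <- len - ft$end[i] + ft$start[i] - 1L
    } else {
      j <- if (i == n) 1L else i + 1L
      intergenic[i] <- intergenicSpacer(ft[i, ], ft[j, ], len,
                                        circular_closure = (i == n))
    }
  }
  data.frame(gene = ft$name, klass = ft$klass, direction = ft$strand,
             start = ft$start, end = ft$end, size_nt = size,
             anticodon = ft$anticodon, start_codon = start_codon,
             stop_codon = stop_codon, start_ok = start_ok,
             stop_ok = stop_ok, intergenic_nt = intergenic,
             stringsAsFactors = FALSE)
}

#' Write an annotation summary table as TSV
#'
#' Columns mirror the conventional mitogenome summary layout: gene,
#' direction, location, size, anticodon, start codon, stop codon,
#' intergenic nucleotides.
#'
#' @param summary output of \code{\link{buildSummaryTable}}.
#' @param path output file; \code{NULL} returns the TSV text.
#' @param genome_id optional id column value.
#' @return path (invisibly) or TSV text.
#' @export
writeSummaryTSV <- function(summary, path = NULL, genome_id = NULL) {
  out <- data.frame(
    gene = summary$gene, direction = summary$direction,
    location = paste0(summary$start, "..", summary$end),
    size = summary$size_nt,
    anticodon = ifelse(is.na(summary$anticodon), "-", summary$anticodon),
    start_codon = ifelse(is.na(summary$start_codon), "-", summary$start_codon),
    stop_codon = ifelse(is.na(summary$stop_codon), "-", summary$stop_codon),
    intergenic_nt = summary$intergenic_nt, stringsAsFactors = FALSE)
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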