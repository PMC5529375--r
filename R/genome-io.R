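## Reading and writing annotated mitogenomes (GenBank flat file,
## FASTA + feature TSV) and strand-correct feature sequence extraction.

.TSV_HEADER <- c("name", "klass", "strand", "start", "end", "anticodon")

## Synonym table: common GenBank spellings -> canonical label. Keys are
## matched after uppercasing and stripping spaces/hyphens/underscores.
.makeSynonyms <- function() {
  syn <- list(
    cox1 = c("COX1", "COI", "CO1", "COXI"),
    cox2 = c("COX2", "COII", "CO2", "COXII"),
    cox3 = c("COX3", "COIII", "CO3", "COXIII"),
    cob  = c("COB", "CYTB", "CYB"),
    nad1 = c("NAD1", "ND1", "NADH1"), nad2 = c("NAD2", "ND2", "NADH2"),
    nad3 = c("NAD3", "ND3", "NADH3"), nad4 = c("NAD4", "ND4", "NADH4"),
    nad4L = c("NAD4L", "ND4L"),
    nad5 = c("NAD5", "ND5", "NADH5"), nad6 = c("NAD6", "ND6", "NADH6"),
    atp6 = c("ATP6", "ATPASE6", "ATPASESUBUNIT6"),
    atp8 = c("ATP8", "ATPASE8", "ATPASESUBUNIT8"),
    rrnL = c("RRNL", "16S", "16SRRNA", "LRRNA", "LSU", "16SRIBOSOMALRNA",
             "RRN16"),
    rrnS = c("RRNS", "12S", "12SRRNA", "SRRNA", "SSU", "12SRIBOSOMALRNA",
             "RRN12"),
    AT_rich_region = c("ATRICHREGION", "A+TRICHREGION", "DLOOP",
                       "CONTROLREGION", "CR")
  )
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", K = "LYS", M = "MET",
           F = "PHE", P = "PRO", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  for (a in names(aa3))
    syn[[paste0("trn", a)]] <- c(paste0("TRN", a), paste0("TRNA", aa3[[a]]),
                                 aa3[[a]])
  ## disambiguated Leu/Ser tRNAs
  syn$trnL1 <- c("TRNL1", "TRNL1(CUN)", "TRNL(CUN)", "TRNALEU(CUN)",
                 "TRNALEU1", "LEU1", "TRNL(TAG)")
  syn$trnL2 <- c("TRNL2", "TRNL2(UUR)", "TRNL(UUR)", "TRNALEU(UUR)",
                 "TRNALEU2", "LEU2", "TRNL(TAA)")
  syn$trnS1 <- c("TRNS1", "TRNS1(AGN)", "TRNS(AGN)", "TRNASER(AGN)",
                 "TRNASER1", "SER1", "TRNS(GCT)")
  syn$trnS2 <- c("TRNS2", "TRNS2(UCN)", "TRNS(UCN)", "TRNASER(UCN)",
                 "TRNASER2", "SER2", "TRNS(TGA)")
  out <- character(0)
  for (canon in names(syn))
    out[c(toupper(canon), syn[[canon]])] <- canon
  out
}
.SYNONYMS <- .makeSynonyms()

#' Canonical mitochondrial gene label
#'
#' Maps common GenBank spellings (COI, ND5, 16S, tRNA-Met, D-loop, ...) to
#' the canonical labels used throughout the package (cox1, nad5, rrnL,
#' trnM, AT_rich_region, ...). Unrecognized names are returned unchanged.
#'
#' @param name character vector of raw feature names.
#' @return character vector of canonical (or original) labels.
#' @examples
#' canonicalGeneName(c("COI", "ND4L", "tRNA-Leu(UUR)", "D-loop", "orfX"))
#' @export
canonicalGeneName <- function(name) {
  key <- gsub("[ _-]", "", toupper(name))
  hit <- .SYNONYMS[key]
  ifelse(is.na(hit), name, unname(hit))
}

.klassForLabel <- function(label) {
  ifelse(label %in% .PCG_LABELS, "PCG",
  ifelse(label %in% .TRNA_LABELS, "tRNA",
  ifelse(label %in% .RRNA_LABELS, "rRNA",
  ifelse(label == .CONTROL_LABEL, "control", "other"))))
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement over the alphabet A/C/G/T/N (N maps to
#' N). Thin character-level wrapper around
#' \code{\link[Biostrings]{reverseComplement}}.
#'
#' @param seq a single character string.
#' @return the reverse-complemented string.
#' @examples
#' revComp("AAC")   # "GTT"
#' revComp("ACGT")  # its own reverse complement
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  bad <- setdiff(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(bad), collapse = ", "))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

## Positions covered by a feature, honouring circular wrap (end < start).
.featurePositions <- function(start, end, genome_length) {
  if (end >= start) start:end
  else c(start:genome_length, 1:end)
}

#' Extract the reading-direction sequence of a feature
#'
#' Returns the sense-strand sequence of one feature: the span
#' \code{start..end} for majority-strand (F) features, its reverse
#' complement for minority-strand (R) features. A feature with
#' \code{end < start} wraps across the origin; the suffix and prefix are
#' concatenated before orientation.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param feature a feature name present in \code{features(genome)}, or a
#'   one-row data.frame/list with \code{start}, \code{end}, \code{strand}.
#' @return a character string.
#' @examples
#' g <- MitoGenome("toy", "AACGTT",
#'                 data.frame(name = "x", klass = "other", strand = "R",
#'                            start = 2, end = 4))
#' extractFeatureSequence(g, "x")  # "CGT"
#' @export
extractFeatureSequence <- function(genome, feature) {
  stopifnot(is(genome, "MitoGenome"))
  if (is.character(feature)) {
    ft <- features(genome)
    i <- match(feature, ft$name)
    if (is.na(i)) stop("no feature named '", feature, "'")
    feature <- ft[i, ]
  }
  len <- genomeLength(genome)
  if (feature$start < 1L || feature$start > len ||
      feature$end < 1L || feature$end > len)
    stop("coordinates of feature outside [1, ", len, "]")
  pos <- .featurePositions(feature$start, feature$end, len)
  s <- paste(strsplit(as.character(genomeSeq(genome)), "")[[1L]][pos],
             collapse = "")
  if (identical(feature$strand, "R")) revComp(s) else s
}

## ---------------------------------------------------------------------------
## Feature TSV

#' Read a genome from a feature TSV plus its sequence
#'
#' The TSV must carry the header
#' \code{name<TAB>klass<TAB>strand<TAB>start<TAB>end<TAB>anticodon}.
#' \code{end < start} encodes an origin-spanning feature on the circle.
#'
#' @param text TSV content as a single string, or a file path.
#' @param sequence the genome DNA sequence (string or DNAString).
#' @param id genome identifier.
#' @return a \linkS4class{MitoGenome}.
#' @seealso \code{\link{writeFeatureTSV}} for the inverse.
#' @export
parseFeatureTSV <- function(text, sequence, id = "genome") {
  ## colClasses keeps all-"F" strand or all-"T" anticodon columns textual
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    ft <- read.delim(text, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""), colClasses = "character")
  else
    ft <- read.delim(text = text, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""), colClasses = "character")
  missing_cols <- setdiff(.TSV_HEADER[1:5], names(ft))
  if (length(missing_cols))
    stop("feature TSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(ft$klass %in% .KLASSES))
    stop("unknown klass value(s): ",
         paste(setdiff(ft$klass, .KLASSES), collapse = ", "))
  ft$name <- canonicalGeneName(ft$name)
  MitoGenome(id, sequence, ft)
}

#' Write the feature table of a genome as TSV
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param path output file path; when \code{NULL} the TSV is returned as a
#'   string.
#' @return the path (invisibly), or the TSV text when \code{path = NULL}.
#' @export
writeFeatureTSV <- function(genome, path = NULL) {
  ft <- features(genome)[, .TSV_HEADER, drop = FALSE]
  lines <- c(paste(.TSV_HEADER, collapse = "\t"),
             vapply(seq_len(nrow(ft)), function(i)
               paste(c(ft$name[i], ft$klass[i], ft$strand[i],
                       ft$start[i], ft$end[i],
                       ifelse(is.na(ft$anticodon[i]), "NA", ft$anticodon[i])),
                     collapse = "\t"), character(1)))
  if (is.null(path)) return(paste0(paste(lines, collapse = "\n"), "\n"))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GenBank flat file (minimal LOCUS/FEATURES/ORIGIN subset)

.parseGBLocation <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- "F"
  if (grepl("^complement\\(", loc)) {
    strand <- "R"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1L]]
    nums <- lapply(parts, function(p)
      as.integer(strsplit(p, "\\.\\.")[[1L]]))
    ## origin-spanning join(a..L,1..b) -> start a, end b (wrap convention)
    start <- nums[[1L]][1L]
    end <- nums[[length(nums)]][length(nums[[length(nums)]])]
  } else if (grepl("\\.\\.", loc)) {
    nums <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
    start <- nums[1L]; end <- nums[2L]
  } else {
    start <- end <- as.integer(loc)
  }
  list(strand = strand, start = start, end = end)
}

.gbQualifier <- function(block, qual) {
  m <- regmatches(block,
                  regexec(paste0('/', qual, '="?([^"\n]*)"?'), block))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Parse a GenBank flat file into a MitoGenome
#'
#' Understands the LOCUS / FEATURES / ORIGIN subset used for mitogenome
#' records: \code{gene}, \code{CDS}, \code{tRNA}, \code{rRNA},
#' \code{misc_feature} and \code{D-loop} features with plain,
#' \code{complement()} and origin-spanning \code{join()} locations.
#' Feature names are mapped to canonical labels via the built-in synonym
#' table; \code{complement()} becomes strand R. \code{gene} features are
#' used only when no CDS/tRNA/rRNA feature covers the same name.
#'
#' @param text GenBank record as a single string, or a file path.
#' @return a \linkS4class{MitoGenome}.
#' @export
parseGenBank <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]

  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1L])),
                                    "\\s+")[[1L]][1L] else "genome"

  io <- grep("^ORIGIN", lines)
  if (!length(io)) stop("GenBank record has no ORIGIN block")
  seq_lines <- lines[(io[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("ORIGIN block contains no sequence")

  ifeat <- grep("^FEATURES", lines)
  if (!length(ifeat)) stop("GenBank record has no FEATURES block")
  feat_lines <- lines[(ifeat[1L] + 1L):(io[1L] - 1L)]
  ## split into feature blocks: a new block starts at indent 5 with a key
  starts <- grep("^ {5}\\S", feat_lines)
  if (!length(starts)) stop("FEATURES block contains no features")
  ends <- c(starts[-1L] - 1L, length(feat_lines))

  rows <- list()
  for (b in seq_along(starts)) {
    block_lines <- feat_lines[starts[b]:ends[b]]
    key <- strsplit(trimws(block_lines[1L]), "\\s+")[[1L]][1L]
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "misc_feature", "D-loop"))
      next
    loc_txt <- trimws(sub("^\\s*\\S+\\s+", "", block_lines[1L]))
    ## location may continue on following lines until a qualifier starts
    k <- 2L
    while (k <= length(block_lines) && !grepl("^\\s*/", block_lines[k])) {
      loc_txt <- paste0(loc_txt, trimws(block_lines[k])); k <- k + 1L
    }
    block <- paste(block_lines, collapse = "\n")
    loc <- .parseGBLocation(loc_txt)
    nm <- .gbQualifier(block, "gene")
    if (is.na(nm)) nm <- .gbQualifier(block, "product")
    if (is.na(nm)) nm <- if (key == "D-loop") "D-loop" else
      .gbQualifier(block, "note")
    if (is.na(nm)) next
    label <- canonicalGeneName(nm)
    klass <- .klassForLabel(label)
    if (klass == "other")
      klass <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                      "D-loop" = "control", "other")
    if (klass == "control" && label != .CONTROL_LABEL) label <- .CONTROL_LABEL
    anticodon <- NA_character_
    if (klass == "tRNA") {
      ac <- .gbQualifier(block, "anticodon_seq")
      anticodon <- if (is.na(ac)) "NNN" else toupper(ac)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(name = label, klass = klass, strand = loc$strand,
                 start = loc$start, end = loc$end, anticodon = anticodon,
                 key = key, stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, rows)
  if (is.null(ft)) stop("no usable features found")
  ## prefer typed features (CDS/tRNA/rRNA/...) over bare 'gene' duplicates
  typed <- ft[ft$key != "gene", , drop = FALSE]
  genes <- ft[ft$key == "gene" & !(ft$name %in% typed$name), , drop = FALSE]
  ft <- rbind(typed, genes)
  ft$key <- NULL
  len <- nchar(sequence)
  bad <- ft$start > len | ft$end > len | ft$start < 1L | ft$end < 1L
  if (any(bad))
    stop("feature(s) with coordinates outside the ", len, "-bp sequence: ",
         paste(ft$name[bad], collapse = ", "))
  MitoGenome(id, sequence, ft)
}

#' Write a MitoGenome as a GenBank flat file
#'
#' Emits a minimal LOCUS / FEATURES / ORIGIN record that
#' \code{\link{parseGenBank}} reads back to an equal object.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param path output file path; when \code{NULL} the record is returned
#'   as a string.
#' @return the path (invisibly), or the record text.
#' @export
writeGenBank <- function(genome, path = NULL) {
  ft <- features(genome)
  len <- genomeLength(genome)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular     %s",
                   genomeID(genome), len, format(Sys.Date(), "%d-%b-%Y")),
           sprintf("DEFINITION  %s mitochondrion, complete genome.",
                   genomeID(genome)),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", len))
  for (i in seq_len(nrow(ft))) {
    key <- switch(ft$klass[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "misc_feature", "misc_feature")
    span <- if (ft$end[i] >= ft$start[i])
      sprintf("%d..%d", ft$start[i], ft$end[i])
    else
      sprintf("join(%d..%d,1..%d)", ft$start[i], len, ft$end[i])
    loc <- if (ft$strand[i] == "R") sprintf("complement(%s)", span) else span
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", ft$name[i]))
    if (ft$klass[i] == "tRNA" && !is.na(ft$anticodon[i]))
      out <- c(out, sprintf("                     /anticodon_seq=\"%s\"",
                            ft$anticodon[i]))
  }
  out <- c(out, "ORIGIN")
  s <- as.character(genomeSeq(genome))
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  if (is.null(path)) return(paste0(paste(out, collapse = "\n"), "\n"))
  writeLines(out, path)
  invisible(path)
}

#' Read a genome from FASTA plus a feature TSV
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param tsv_path path to the feature TSV (see
#'   \code{\link{parseFeatureTSV}}).
#' @param id genome identifier; defaults to the FASTA record name.
#' @return a \linkS4class{MitoGenome}.
#' @export
readGenomeFASTA <- function(fasta_path, tsv_path, id = NULL) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1L)
    stop("expected exactly one FASTA record in ", fasta_path)
  if (is.null(id)) id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  parseFeatureTSV(tsv_path, set[[1L]], id = id)
}
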