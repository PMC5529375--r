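#' @import methods
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

## The 37 mitochondrial genes in canonical spelling, plus the control region.
## The two leucine and two serine tRNAs carry disambiguated labels
## (trnL1 = CUN, trnL2 = UUR, trnS1 = AGN, trnS2 = UCN).
.PCG_LABELS  <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                  "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")
.TRNA_LABELS <- c("trnM", "trnI", "trnQ", "trnW", "trnC", "trnY", "trnL2",
                  "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                  "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                  "trnV")
.RRNA_LABELS <- c("rrnL", "rrnS")
.CONTROL_LABEL <- "AT_rich_region"
.ALL_LABELS <- c(.PCG_LABELS, .TRNA_LABELS, .RRNA_LABELS, .CONTROL_LABEL)
.KLASSES <- c("PCG", "tRNA", "rRNA", "control", "other")

.FEATURE_COLS <- c("name", "klass", "strand", "start", "end", "anticodon")

#' Annotated circular mitochondrial genome
#'
#' Holds a circular DNA sequence together with an ordered, strand-aware
#' feature table. Coordinates are 1-based inclusive; a feature with
#' \code{end < start} spans the origin of the circle. Strand \code{"F"}
#' marks the majority strand, \code{"R"} the minority strand.
#'
#' @slot id single genome identifier.
#' @slot seq a \code{\link[Biostrings]{DNAString}} over A/C/G/T/N.
#' @slot features \code{data.frame} with columns \code{name}, \code{klass}
#'   (one of PCG, tRNA, rRNA, control, other), \code{strand} (F/R),
#'   \code{start}, \code{end} (1-based inclusive) and \code{anticodon}
#'   (3-letter DNA triplet for tRNAs, otherwise \code{NA}), sorted by
#'   \code{start}.
#'
#' @seealso \code{\link{MitoGenome}} for the constructor,
#'   \code{\link{parseGenBank}} and \code{\link{parseFeatureTSV}} to read
#'   genomes from files.
#' @exportClass MitoGenome
setClass("MitoGenome",
         slots = c(id = "character",
                   seq = "ANY",
                   features = "data.frame"))

setValidity("MitoGenome", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "'id' must be a single non-empty string")
  if (!is(object@seq, "DNAString"))
    msgs <- c(msgs, "'seq' must be a DNAString")
  else {
    if (length(object@seq) < 1L)
      msgs <- c(msgs, "sequence must have length >= 1")
    bad <- setdiff(strsplit(as.character(object@seq), "")[[1L]],
                   c("A", "C", "G", "T", "N"))
    if (length(bad))
      msgs <- c(msgs, paste0("sequence contains characters outside {A,C,G,T,N}: ",
                             paste(unique(bad), collapse = ", ")))
  }
  ft <- object@features
  if (!all(.FEATURE_COLS %in% names(ft)))
    return(paste0("features must have columns ",
                  paste(.FEATURE_COLS, collapse = ", ")))
  if (nrow(ft)) {
    if (anyDuplicated(ft$name))
      msgs <- c(msgs, paste0("duplicate feature names: ",
                             paste(unique(ft$name[duplicated(ft$name)]),
                                   collapse = ", ")))
    if (!all(ft$klass %in% .KLASSES))
      msgs <- c(msgs, paste0("unknown klass value(s): ",
                             paste(setdiff(ft$klass, .KLASSES), collapse = ", ")))
    if (!all(ft$strand %in% c("F", "R")))
      msgs <- c(msgs, "strand must be 'F' or 'R'")
    len <- if (is(object@seq, "DNAString")) length(object@seq) else NA_integer_
    if (!is.na(len)) {
      bad <- ft$start < 1L | ft$start > len | ft$end < 1L | ft$end > len
      if (any(bad))
        msgs <- c(msgs, paste0("feature(s) outside [1, ", len, "]: ",
                               paste(ft$name[bad], collapse = ", ")))
    }
    is_trna <- ft$klass == "tRNA"
    has_ac <- !is.na(ft$anticodon) & nzchar(ft$anticodon)
    if (any(is_trna & !has_ac))
      msgs <- c(msgs, paste0("tRNA feature(s) missing anticodon: ",
                             paste(ft$name[is_trna & !has_ac], collapse = ", ")))
    if (any(!is_trna & has_ac))
      msgs <- c(msgs, paste0("non-tRNA feature(s) carry an anticodon: ",
                             paste(ft$name[!is_trna & has_ac], collapse = ", ")))
    ctrl_name <- ft$name == .CONTROL_LABEL
    ctrl_klass <- ft$klass == "control"
    if (any(xor(ctrl_name, ctrl_klass)))
      msgs <- c(msgs, "klass 'control' must pair exactly with name 'AT_rich_region'")
    if (is.unsorted(ft$start))
      msgs <- c(msgs, "features must be sorted by start coordinate")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MitoGenome
#'
#' @param id genome identifier.
#' @param seq DNA sequence: a character string or a
#'   \code{\link[Biostrings]{DNAString}}.
#' @param features feature \code{data.frame} (see
#'   \linkS4class{MitoGenome}); missing \code{anticodon} column is added
#'   as all-\code{NA}. Rows are sorted by \code{start}.
#' @return a \linkS4class{MitoGenome}.
#' @examples
#' g <- MitoGenome("toy", "AACGTT",
#'                 data.frame(name = "trnM", klass = "tRNA", strand = "F",
#'                            start = 1, end = 6, anticodon = "CAT"))
#' genomeLength(g)
#' @export
MitoGenome <- function(id, seq, features = emptyFeatureTable()) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  features <- normalizeFeatureTable(features)
  new("MitoGenome", id = as.character(id), seq = seq, features = features)
}

#' An empty feature table with the canonical columns
#' @return zero-row \code{data.frame} with the feature columns.
#' @export
emptyFeatureTable <- function() {
  data.frame(name = character(0), klass = character(0), strand = character(0),
             start = integer(0), end = integer(0), anticodon = character(0),
             stringsAsFactors = FALSE)
}

## Coerce column types, fill anticodon, sort by start.
normalizeFeatureTable <- function(ft) {
  if (!"anticodon" %in% names(ft)) ft$anticodon <- NA_character_
  ft <- ft[, .FEATURE_COLS, drop = FALSE]
  for (col in c("name", "klass", "strand", "anticodon"))
    ft[[col]] <- as.character(ft[[col]])
  ft$anticodon[!is.na(ft$anticodon) & ft$anticodon %in% c("", "-", "--")] <-
    NA_character_
  for (col in c("start", "end")) {
    v <- ft[[col]]
    iv <- suppressWarnings(as.integer(v))
    if (any(is.na(iv) != is.na(v)) ||
        any(!is.na(v) & iv != suppressWarnings(as.numeric(v))))
      stop("feature column '", col, "' must be integer-valued")
    ft[[col]] <- iv
  }
  ft <- ft[order(ft$start), , drop = FALSE]
  rownames(ft) <- NULL
  ft
}

#' @describeIn MitoGenome-class display a short summary.
#' @param object a \code{MitoGenome}.
#' @export
setMethod("show", "MitoGenome", function(object) {
  ft <- object@features
  cat("MitoGenome '", object@id, "': ", length(object@seq),
      " bp circular, ", nrow(ft), " features\n", sep = "")
  if (nrow(ft)) {
    tab <- table(factor(ft$klass, levels = .KLASSES))
    cat("  ", paste(paste0(tab, " ", names(tab)), collapse = ", "), "\n",
        sep = "")
  }
})

#' Circular signed gene order
#'
#' A circular sequence of signed gene labels: a leading \code{"-"} marks a
#' minority-strand (R) gene. The anchor label fixes the rotation used for
#' display; rotation never changes the adjacency structure.
#'
#' @slot labels character vector of signed labels, e.g.
#'   \code{c("AT_rich_region", "trnM", "trnI", "-trnQ", "nad2")}.
#' @slot anchor unsigned label placed first when normalizing rotation.
#' @exportClass GeneOrder
setClass("GeneOrder",
         slots = c(labels = "character", anchor = "character"))

setValidity("GeneOrder", function(object) {
  base <- sub("^-", "", object@labels)
  if (anyDuplicated(base))
    return(paste0("duplicate gene labels: ",
                  paste(unique(base[duplicated(base)]), collapse = ", ")))
  if (length(object@anchor) != 1L)
    return("'anchor' must be a single label")
  if (nzchar(object@anchor) && !(object@anchor %in% base))
    return(paste0("anchor '", object@anchor, "' not among the labels"))
  TRUE
})

#' Construct a GeneOrder
#'
#' @param labels signed labels in circular order (\code{"-"} prefix =
#'   minority strand).
#' @param anchor unsigned label used to normalize rotation; defaults to
#'   \code{"AT_rich_region"} when present, otherwise the first label.
#' @return a \linkS4class{GeneOrder}, rotated so the anchor comes first.
#' @examples
#' GeneOrder(c("+a", "-b", "c"), anchor = "a")
#' @export
GeneOrder <- function(labels, anchor = NULL) {
  labels <- sub("^\\+", "", as.character(labels))
  base <- sub("^-", "", labels)
  if (is.null(anchor))
    anchor <- if (.CONTROL_LABEL %in% base) .CONTROL_LABEL else base[1L]
  obj <- new("GeneOrder", labels = labels, anchor = anchor)
  rotateToAnchor(obj)
}

rotateToAnchor <- function(order) {
  base <- sub("^-", "", order@labels)
  i <- match(order@anchor, base)
  if (!is.na(i) && i > 1L)
    order@labels <- c(order@labels[i:length(order@labels)],
                      order@labels[seq_len(i - 1L)])
  order
}

#' @describeIn GeneOrder-class display the circular order.
#' @param object a \code{GeneOrder}.
#' @export
setMethod("show", "GeneOrder", function(object) {
  cat("GeneOrder (circular, ", length(object@labels), " labels): ",
      paste(object@labels, collapse = " "), "\n", sep = "")
})
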