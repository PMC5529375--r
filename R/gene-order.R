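## Circular signed gene orders: extraction from annotations, adjacency
## sets, breakpoint distance, and single-gene translocation detection.

## Shared pancrustacean block downstream of nad2 (identical in the
## ancestral-insect and derived lepidopteran arrangements).
.SHARED_TAIL <- c("trnW", "-trnC", "-trnY", "cox1", "trnL2", "cox2", "trnK",
                  "trnD", "atp8", "atp6", "cox3", "trnG", "nad3", "trnA",
                  "trnR", "trnN", "trnS1", "trnE", "-trnF", "-nad5", "-trnH",
                  "-nad4", "-nad4L", "trnT", "-trnP", "nad6", "cob", "trnS2",
                  "-nad1", "-trnL1", "-rrnL", "-trnV", "-rrnS")

#' Built-in reference gene orders
#'
#' \code{ancestralInsectOrder()} carries the ancestral arrangement of the
#' trnM cluster (control region, trnI, -trnQ, trnM, nad2, ...);
#' \code{lepidopteranOrder()} carries the derived arrangement shared by
#' ditrysian Lepidoptera (control region, trnM, trnI, -trnQ, nad2, ...).
#' The remaining 33 genes follow the shared pancrustacean arrangement.
#'
#' @return a \linkS4class{GeneOrder} over all 37 genes plus the A+T-rich
#'   region, anchored at the A+T-rich region.
#' @examples
#' detectTranslocatedGenes(lepidopteranOrder(), ancestralInsectOrder())
#' @export
ancestralInsectOrder <- function() {
  GeneOrder(c(.CONTROL_LABEL, "trnI", "-trnQ", "trnM", "nad2", .SHARED_TAIL))
}

#' @rdname ancestralInsectOrder
#' @export
lepidopteranOrder <- function() {
  GeneOrder(c(.CONTROL_LABEL, "trnM", "trnI", "-trnQ", "nad2", .SHARED_TAIL))
}

#' Extract the signed gene order of an annotated genome
#'
#' Features are taken in genomic (start-coordinate) order; minority-strand
#' (R) features get a \code{"-"} sign. The order is anchored at the
#' A+T-rich region when present.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return a \linkS4class{GeneOrder}.
#' @export
extractGeneOrder <- function(genome) {
  stopifnot(is(genome, "MitoGenome"))
  ft <- features(genome)
  if (anyDuplicated(ft$name))
    stop("duplicate gene labels: ",
         paste(unique(ft$name[duplicated(ft$name)]), collapse = ", "))
  GeneOrder(paste0(ifelse(ft$strand == "R", "-", ""), ft$name))
}

#' Adjacency set of a circular signed gene order
#'
#' The set of consecutive ordered pairs, including the circular closure
#' pair from the last label back to the first. Signs participate in pair
#' identity, so inversions register as changed adjacencies. Rotating an
#' order leaves its adjacency set unchanged.
#'
#' @param order a \linkS4class{GeneOrder} with at least 2 labels.
#' @return character vector of pairs \code{"x|y"}.
#' @examples
#' adjacencySet(GeneOrder(c("a", "b", "c"), anchor = "a"))
#' @export
adjacencySet <- function(order) {
  stopifnot(is(order, "GeneOrder"))
  lab <- orderLabels(order)
  if (length(lab) < 2L) stop("adjacency set needs at least 2 labels")
  paste(lab, c(lab[-1L], lab[1L]), sep = "|")
}

.checkSameLabels <- function(a, b) {
  ba <- sub("^-", "", orderLabels(a)); bb <- sub("^-", "", orderLabels(b))
  if (!setequal(ba, bb)) {
    d1 <- setdiff(ba, bb); d2 <- setdiff(bb, ba)
    stop("gene-order label sets differ",
         if (length(d1)) paste0("; only in first: ", paste(d1, collapse = ", ")),
         if (length(d2)) paste0("; only in second: ", paste(d2, collapse = ", ")))
  }
}

#' Breakpoint distance between two circular signed gene orders
#'
#' Number of adjacencies (consecutive signed pairs, circular closure
#' included) present in \code{a} but absent from \code{b}. Both orders
#' must cover the same (unsigned) label set; for equal-size orders the
#' measure is symmetric. Distance 0 means the orders are identical up to
#' rotation.
#'
#' @param a,b \linkS4class{GeneOrder}s over the same label set.
#' @return non-negative integer.
#' @examples
#' breakpointDistance(lepidopteranOrder(), ancestralInsectOrder())  # 3
#' @export
breakpointDistance <- function(a, b) {
  .checkSameLabels(a, b)
  length(setdiff(adjacencySet(a), adjacencySet(b)))
}

.dropLabels <- function(order, drop) {
  keep <- !(sub("^-", "", orderLabels(order)) %in% drop)
  lab <- orderLabels(order)[keep]
  new("GeneOrder", labels = lab, anchor = sub("^-", "", lab[1L]))
}

#' Detect translocated genes between two gene orders
#'
#' Finds the smallest set of genes whose removal from both orders makes
#' the remaining circular adjacency sets identical — the minimal
#' explanation of the difference by single-gene translocations. Returns
#' an empty vector when the orders already match. Candidate genes are
#' those participating in differing adjacencies; subsets are searched in
#' order of increasing size.
#'
#' @param observed,reference \linkS4class{GeneOrder}s over the same label
#'   set.
#' @param max_moves largest subset size searched.
#' @return character vector of unsigned gene labels (possibly empty).
#' @examples
#' detectTranslocatedGenes(lepidopteranOrder(), ancestralInsectOrder())
#' # "trnM"
#' @export
detectTranslocatedGenes <- function(observed, reference, max_moves = 4L) {
  .checkSameLabels(observed, reference)
  if (setequal(adjacencySet(observed), adjacencySet(reference)))
    return(character(0))
  diffs <- c(setdiff(adjacencySet(observed), adjacencySet(reference)),
             setdiff(adjacencySet(reference), adjacencySet(observed)))
  candidates <- unique(sub("^-", "", unlist(strsplit(diffs, "|", fixed = TRUE))))
  n_lab <- length(orderLabels(observed))
  for (k in seq_len(min(max_moves, length(candidates), n_lab - 3L))) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    hits <- Filter(function(set)
      setequal(adjacencySet(.dropLabels(observed, set)),
               adjacencySet(.dropLabels(reference, set))), combos)
    if (length(hits)) {
      if (length(hits) > 1L)
        warning("multiple minimal translocation sets; returning the first")
      return(sort(hits[[1L]]))
    }
  }
  stop("no translocation set of size <= ", max_moves,
       " explains the rearrangement")
}

#' Write a gene-order comparison report as TSV
#'
#' One row per genome: the signed order string, breakpoint distances
#' against the ancestral-insect and lepidopteran references, and the
#' genes translocated relative to each.
#'
#' @param orders named list of \linkS4class{GeneOrder}s (names = genome
#'   ids).
#' @param path output file; \code{NULL} returns the TSV text.
#' @return path (invisibly) or TSV text.
#' @export
writeGeneOrderTSV <- function(orders, path = NULL) {
  anc <- ancestralInsectOrder(); lep <- lepidopteranOrder()
  safe <- function(expr) tryCatch(expr, error = function(e) NA)
  rows <- lapply(names(orders), function(id) {
    ord <- orders[[id]]
    trl_anc <- safe(paste(detectTranslocatedGenes(ord, anc), collapse = ","))
    trl_lep <- safe(paste(detectTranslocatedGenes(ord, lep), collapse = ","))
    data.frame(genome = id,
               order = paste(orderLabels(ord), collapse = " "),
               breakpoints_vs_ancestral = safe(breakpointDistance(ord, anc)),
               breakpoints_vs_lepidopteran = safe(breakpointDistance(ord, lep)),
               translocated_vs_ancestral = trl_anc,
               translocated_vs_lepidopteran = trl_lep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
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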