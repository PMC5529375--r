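## A+T-rich (control) region: location, the "ATAGA + poly-T" motif
## associated with the origin of minority-strand replication, and exact
## tandem-repeat detection by self-alignment.

#' Locate the A+T-rich region of an annotated genome
#'
#' Returns the annotated control feature when present. Otherwise the
#' longest unannotated span of the circle is taken; in lepidopteran
#' mitogenomes it must abut rrnS (the region lies between rrnS and trnM),
#' and a warning is raised when it does not.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param min_gap smallest unannotated span accepted (nt).
#' @return one-row \code{data.frame} with \code{name}, \code{klass},
#'   \code{strand}, \code{start}, \code{end}, \code{anticodon},
#'   \code{length}.
#' @export
locateATRichRegion <- function(genome, min_gap = 50L) {
  stopifnot(is(genome, "MitoGenome"))
  ft <- features(genome)
  len <- genomeLength(genome)
  ctrl <- which(ft$klass == "control")
  if (length(ctrl)) {
    row <- ft[ctrl[1L], , drop = FALSE]
    row$length <- featureLength(row, len)
    rownames(row) <- NULL
    return(row)
  }
  if (!nrow(ft)) stop("genome has no features")
  covered <- logical(len)
  for (i in seq_len(nrow(ft)))
    covered[.featurePositions(ft$start[i], ft$end[i], len)] <- TRUE
  if (all(covered))
    stop("no unannotated span found; genome is fully annotated")
  ## maximal uncovered runs on the circle
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  gaps <- data.frame(start = starts[!r$values], end = stops[!r$values])
  ## merge a gap touching position len with one starting at 1 (circular)
  if (nrow(gaps) > 1L && gaps$start[1L] == 1L && gaps$end[nrow(gaps)] == len) {
    gaps$end[nrow(gaps)] <- gaps$end[1L]
    gaps <- gaps[-1L, , drop = FALSE]
  }
  glen <- mapply(function(s, e) featureLength(list(start = s, end = e), len),
                 gaps$start, gaps$end)
  best <- which.max(glen)
  if (glen[best] < min_gap)
    stop("largest unannotated span is ", glen[best], " nt < min_gap = ",
         min_gap)
  gs <- gaps$start[best]; ge <- gaps$end[best]
  rs <- ft[ft$name == "rrnS", , drop = FALSE]
  if (nrow(rs)) {
    abuts <- (rs$end %% len) + 1L == gs || (ge %% len) + 1L == rs$start
    if (!abuts)
      warning("longest unannotated span does not abut rrnS")
  }
  data.frame(name = .CONTROL_LABEL, klass = "control", strand = "F",
             start = gs, end = ge, anticodon = NA_character_,
             length = glen[best], stringsAsFactors = FALSE)
}

#' Find "ATAGA + poly-T" motifs
#'
#' Scans a region (majority-strand orientation) for occurrences of the
#' conserved ATAGA motif followed, starting within \code{window} nt
#' downstream of its last base, by a run of at least \code{min_polyT}
#' consecutive T. The run length of the first qualifying run after each
#' motif is reported in full, even when the run extends past the window.
#'
#' @param region DNA string (e.g. the extracted A+T-rich region).
#' @param min_polyT minimum poly-T run length (nt).
#' @param window how far downstream of the motif the run may start (nt).
#' @return \code{data.frame} with \code{position} (1-based offset of the
#'   ATAGA within the region), \code{motif}, \code{polyT_start},
#'   \code{polyT_length}; zero rows when nothing qualifies.
#' @examples
#' findAtagaPolyT("ATAGATTTTTT")  # hit at position 1, poly-T length 6
#' @export
findAtagaPolyT <- function(region, min_polyT = 5L, window = 20L) {
  stopifnot(nzchar(region), min_polyT >= 1L)
  region <- toupper(region)
  n <- nchar(region)
  hits <- gregexpr("(?=ATAGA)", region, perl = TRUE)[[1L]]
  if (hits[1L] == -1L)
    return(data.frame(position = integer(0), motif = character(0),
                      polyT_start = integer(0), polyT_length = integer(0)))
  chars <- strsplit(region, "")[[1L]]
  rows <- lapply(as.integer(hits), function(pos) {
    lo <- pos + 5L
    hi <- min(pos + 4L + window, n)
    if (lo > n) return(NULL)
    for (s in lo:hi) {
      if (chars[s] != "T") next
      e <- s
      while (e < n && chars[e + 1L] == "T") e <- e + 1L
      if (e - s + 1L >= min_polyT)
        return(data.frame(position = pos, motif = "ATAGA",
                          polyT_start = s, polyT_length = e - s + 1L))
      ## skip to the end of this too-short run
      s_new <- e
      if (s_new >= hi) break
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), motif = character(0),
                      polyT_start = integer(0), polyT_length = integer(0))
  out
}

## Smallest q in 1..(p-1) that is a full period of chars[start..end],
## i.e. chars[i] == chars[i - q] for all interior i. Returns NA when none.
.smallerPeriod <- function(chars, start, end, p) {
  for (q in seq_len(p - 1L)) {
    idx <- (start + q):end
    if (all(chars[idx] == chars[idx - q])) return(q)
  }
  NA_integer_
}

#' Find exact tandem repeats by self-alignment
#'
#' For every period \eqn{p} the region is compared against itself shifted
#' by \eqn{p}; maximal runs of agreement of length \eqn{L} give tandem
#' arrays spanning \eqn{L + p} nt with \eqn{(L + p)/p} copies (a
#' fractional final copy is allowed). Arrays must reach
#' \code{min_copies} copies and \code{min_span} nt. An array whose span
#' also has a period smaller than \eqn{p} is reported only at its
#' smallest period (and dropped entirely when that period is below
#' \code{min_period}); arrays contained inside a longer reported array
#' are suppressed.
#'
#' @param region DNA string.
#' @param min_period,max_period period bounds (nt).
#' @param min_copies minimum copy number (may be fractional).
#' @param min_span minimum array span (nt).
#' @return \code{data.frame} with \code{start}, \code{end}, \code{period},
#'   \code{copies}, \code{unit}; zero rows when nothing qualifies.
#' @examples
#' findTandemRepeats("ACGACGACG", min_period = 2, min_span = 6)
#' @export
findTandemRepeats <- function(region, min_period = 2L, max_period = 200L,
                              min_copies = 2.0, min_span = 10L) {
  region <- toupper(region)
  n <- nchar(region)
  stopifnot(min_period >= 1L, min_period <= max_period)
  max_period <- min(max_period, n %/% 2L)
  chars <- strsplit(region, "")[[1L]]
  rows <- list()
  for (p in seq.int(min_period, length.out = max(0L, max_period - min_period + 1L))) {
    eq <- chars[(p + 1L):n] == chars[seq_len(n - p)]
    r <- rle(eq)
    stops <- cumsum(r$lengths)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (k in which(r$values)) {
      L <- r$lengths[k]
      span <- L + p
      if (span < min_span || span / p < min_copies) next
      s <- starts[k]            # first matching offset -> array starts at s
      e <- s + span - 1L
      if (!is.na(.smallerPeriod(chars, s, e, p))) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = s, end = e, period = p, copies = span / p,
                   unit = substr(region, s, s + p - 1L),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0),
                      unit = character(0)))
  ## drop arrays strictly contained in another reported array
  keep <- vapply(seq_len(nrow(out)), function(i) {
    inside <- out$start <= out$start[i] & out$end >= out$end[i] &
      (out$start < out$start[i] | out$end > out$end[i])
    !any(inside)
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a control-region report as TSV
#'
#' Sections: the region's coordinates, length and A+T percentage; motif
#' hits; tandem repeats.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param path output file; \code{NULL} returns the TSV text.
#' @param min_polyT,window motif-scan thresholds
#'   (\code{\link{findAtagaPolyT}}).
#' @param min_period,max_period,min_copies,min_span repeat-scan thresholds
#'   (\code{\link{findTandemRepeats}}).
#' @return path (invisibly) or TSV text; also returned invisibly is a
#'   list with the region, motif and repeat tables.
#' @export
controlRegionReport <- function(genome, path = NULL, min_polyT = 5L,
                                window = 20L, min_period = 2L,
                                max_period = 200L, min_copies = 2.0,
                                min_span = 10L) {
  region <- locateATRichRegion(genome)
  seq <- extractFeatureSequence(genome, region)
  bc <- baseCounts(seq)
  motifs <- findAtagaPolyT(seq, min_polyT, window)
  repeats <- findTandemRepeats(seq, min_period, max_period, min_copies,
                               min_span)
  lines <- c(
    "section\tfield1\tfield2\tfield3\tfield4\tfield5",
    sprintf("region\t%d\t%d\t%d\t%.1f\t%s", region$start, region$end,
            region$length, 100 * (bc[["A"]] + bc[["T"]]) / region$length,
            genomeID(genome)),
    if (nrow(motifs)) sprintf("motif\t%d\tATAGA\t%d\t%d\t-",
                              motifs$position, motifs$polyT_start,
                              motifs$polyT_length),
    if (nrow(repeats)) sprintf("repeat\t%d\t%d\t%d\t%.3f\t%s",
                               repeats$start, repeats$end, repeats$period,
                               repeats$copies, repeats$unit))
  result <- list(region = region, motifs = motifs, repeats = repeats)
  if (is.null(path)) {
    attr(result, "text") <- paste0(paste(lines, collapse = "\n"), "\n")
    return(result)
  }
  writeLines(lines, path)
  invisible(result)
}
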