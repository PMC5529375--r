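## Shared fixtures and independent oracles used across the test files.

## Tiny hand-built genome: 3 features tiling a 30-bp circle.
toyGenome <- function() {
  MitoGenome("toy30",
             "ATGAAATAAACGTACGTACGTTTTTAAAGG",
             data.frame(name = c("a", "b", "c"),
                        klass = c("other", "other", "other"),
                        strand = c("F", "R", "F"),
                        start = c(1L, 11L, 21L), end = c(10L, 20L, 30L)))
}

## full 64-codon count vector from a named subset
codonVector <- function(...) {
  counts <- countCodons(character(0))
  upd <- c(...)
  counts[codonToDNA(names(upd))] <- as.integer(upd)
  counts
}

## published codon counts as a DNA-codon count vector
publishedCounts <- function(species) {
  tab <- publishedCodonCounts(species)
  codonVector(setNames(tab$count, tab$codon))
}

## Independent breakpoint oracle: walks every adjacency of `la` and scans
## `lb` position-by-position for the same ordered signed pair.
oracleBreakpoints <- function(la, lb) {
  n <- length(la); m <- length(lb)
  missing <- 0L
  for (i in seq_len(n)) {
    x <- la[i]; y <- la[if (i == n) 1L else i + 1L]
    found <- FALSE
    for (j in seq_len(m)) {
      if (lb[j] == x && lb[if (j == m) 1L else j + 1L] == y) {
        found <- TRUE
        break
      }
    }
    if (!found) missing <- missing + 1L
  }
  missing
}

## random circular signed order over n labels
randomSignedOrder <- function(n) {
  lab <- sample(paste0("g", seq_len(n)))
  signs <- sample(c("", "-"), n, replace = TRUE)
  paste0(signs, lab)
}

rotateLabels <- function(labels, k) {
  n <- length(labels)
  k <- ((k - 1L) %% n) + 1L
  c(labels[k:n], labels[seq_len(k - 1L)])
}

## Independent tandem-repeat oracle: direct per-start extension over a
## character vector, then the same smallest-period and containment rules
## applied by explicit re-checking.
oracleTandemRepeats <- function(region, min_period = 2L, max_period = 200L,
                                min_copies = 2.0, min_span = 10L) {
  chars <- strsplit(toupper(region), "")[[1L]]
  n <- length(chars)
  rows <- list()
  for (p in seq.int(min_period, length.out = max(0L, min(max_period, n %/% 2L) - min_period + 1L))) {
    s <- 1L
    while (s + p <= n) {
      ## only left-maximal starts
      if (s > 1L && chars[s - 1L] == chars[s - 1L + p]) {
        s <- s + 1L
        next
      }
      e <- s + p - 1L
      i <- s + p
      while (i <= n && chars[i] == chars[i - p]) {
        e <- i
        i <- i + 1L
      }
      span <- e - s + 1L
      if (span > p && span >= min_span && span / p >= min_copies) {
        smaller <- FALSE
        for (q in seq_len(p - 1L)) {
          per <- TRUE
          for (j in (s + q):e)
            if (chars[j] != chars[j - q]) { per <- FALSE; break }
          if (per) { smaller <- TRUE; break }
        }
        if (!smaller)
          rows[[length(rows) + 1L]] <-
            data.frame(start = s, end = e, period = p, copies = span / p,
                       unit = paste(chars[s:(s + p - 1L)], collapse = ""),
                       stringsAsFactors = FALSE)
      }
      s <- s + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0),
                      unit = character(0)))
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

randomDNA <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
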