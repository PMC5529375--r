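## Synthetic annotated mitogenomes with planted, recorded ground truth:
## every downstream statistic (base counts per class, codon counts, gene
## order, control-region elements, start/stop codons) is recoverable
## exactly, so the whole pipeline is testable with no external data.

.DEFAULT_GENE_LENGTHS <- c(
  trnM = 68L, trnI = 64L, trnQ = 69L, nad2 = 1012L, trnW = 68L, trnC = 65L,
  trnY = 65L, cox1 = 1528L, trnL2 = 68L, cox2 = 682L, trnK = 71L,
  trnD = 68L, atp8 = 162L, atp6 = 678L, cox3 = 792L, trnG = 66L,
  nad3 = 352L, trnA = 67L, trnR = 64L, trnN = 66L, trnS1 = 62L, trnE = 68L,
  trnF = 66L, nad5 = 1739L, trnH = 64L, nad4 = 1335L, nad4L = 291L,
  trnT = 66L, trnP = 66L, nad6 = 531L, cob = 1149L, trnS2 = 65L,
  nad1 = 936L, trnL1 = 67L, rrnL = 1344L, trnV = 68L, rrnS = 775L,
  AT_rich_region = 450L)

.DEFAULT_ANTICODONS <- c(
  trnM = "CAT", trnI = "GAT", trnQ = "TTG", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

.DEFAULT_STARTS <- c(nad2 = "ATT", cox1 = "CGA", cox2 = "ATG", atp8 = "ATT",
                     atp6 = "ATG", cox3 = "ATG", nad3 = "ATT", nad5 = "ATT",
                     nad4 = "ATG", nad4L = "ATG", nad6 = "ATG", cob = "ATG",
                     nad1 = "ATG")
## complete TAA stops for length %% 3 == 0; incomplete T / TA otherwise
.DEFAULT_STOPS <- c(nad2 = "T", cox1 = "T", cox2 = "T", atp8 = "TAA",
                    atp6 = "TAA", cox3 = "TAA", nad3 = "T", nad5 = "TA",
                    nad4 = "TAA", nad4L = "TAA", nad6 = "TAA", cob = "TAA",
                    nad1 = "TAA")

## class base frequencies (A, T, G, C) near published lepidopteran values
.DEFAULT_CLASS_FREQS <- list(
  tRNA = c(A = 0.412, T = 0.403, G = 0.079, C = 0.106),
  rRNA = c(A = 0.428, T = 0.419, G = 0.049, C = 0.104),
  control = c(A = 0.436, T = 0.486, G = 0.035, C = 0.043))

## default codon weights: published hawkmoth mitochondrial codon usage
## (strong A/T third-position bias); stops excluded at sampling time
.defaultCodonWeights <- function() {
  counts <- publishedCodonCounts("A_rubiginosa")
  w <- setNames(counts$count + 0.5, codonToDNA(counts$codon))
  w <- w[.DNA_CODONS]          # align with the sampling codon vector
  w[c("TAA", "TAG")] <- 0
  w / sum(w)
}

#' Specification for a synthetic mitogenome
#'
#' Collects every tunable of the generator with defaults that mirror a
#' typical ~15.3-kb lepidopteran mitogenome: 38 features, published-like
#' gene lengths, AT-rich class base frequencies, published-like codon
#' usage, and a control region carrying an ATAGA + poly-T motif and one
#' tandem repeat.
#'
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @param gene_order_template \code{"lepidopteran"},
#'   \code{"ancestral_insect"}, or \code{"custom"} (then supply
#'   \code{custom_order}).
#' @param custom_order signed label vector for
#'   \code{gene_order_template = "custom"}.
#' @param gene_lengths named integer vector of per-feature lengths;
#'   entries override the defaults.
#' @param pcg_codon_weights named non-negative weights over the 64 DNA
#'   codons used to sample PCG body codons (stop weights are zeroed).
#' @param class_base_frequencies list with elements \code{tRNA},
#'   \code{rRNA}, \code{control}, each a named (A,T,G,C) frequency
#'   vector.
#' @param start_codons,stop_codons named per-PCG overrides; stops must be
#'   \code{"TAA"}, \code{"TAG"}, \code{"T"}, \code{"TA"} or \code{"A"}.
#' @param control_motif_offset 1-based offset of the planted ATAGA within
#'   the control region (\code{NA} = no motif).
#' @param control_polyT_length length of the poly-T run planted right
#'   after the motif.
#' @param control_repeat_unit_length,control_repeat_copies,control_repeat_offset
#'   planted tandem repeat: unit length (nt), copy number (fractional
#'   final copy allowed), 1-based offset (\code{NA} unit length = no
#'   repeat).
#' @param target_overlaps named integer vector of overlaps: name
#'   \code{"geneA|geneB"} means downstream \code{geneB} overlaps upstream
#'   \code{geneA} by that many nt. Only non-coding downstream features
#'   may overlap (a PCG or the control region would lose its planted
#'   codon truth).
#' @return a list of class \code{"SyntheticSpec"}.
#' @seealso \code{\link{generateGenome}}
#' @export
syntheticSpec <- function(seed = 1L,
                          gene_order_template = c("lepidopteran",
                                                  "ancestral_insect",
                                                  "custom"),
                          custom_order = NULL,
                          gene_lengths = NULL,
                          pcg_codon_weights = NULL,
                          class_base_frequencies = NULL,
                          start_codons = NULL,
                          stop_codons = NULL,
                          control_motif_offset = 10L,
                          control_polyT_length = 12L,
                          control_repeat_unit_length = 23L,
                          control_repeat_copies = 3.5,
                          control_repeat_offset = 120L,
                          target_overlaps = NULL) {
  gene_order_template <- match.arg(gene_order_template)
  lens <- .DEFAULT_GENE_LENGTHS
  if (!is.null(gene_lengths)) lens[names(gene_lengths)] <- as.integer(gene_lengths)
  weights <- .defaultCodonWeights()
  if (!is.null(pcg_codon_weights)) {
    stopifnot(all(names(pcg_codon_weights) %in% .DNA_CODONS),
              all(pcg_codon_weights >= 0))
    weights[] <- 0
    weights[names(pcg_codon_weights)] <- pcg_codon_weights
    weights[c("TAA", "TAG")] <- 0
    if (sum(weights) <= 0) stop("codon weights are not normalizable")
    weights <- weights / sum(weights)
  }
  freqs <- .DEFAULT_CLASS_FREQS
  if (!is.null(class_base_frequencies))
    freqs[names(class_base_frequencies)] <- class_base_frequencies
  for (f in freqs)
    if (any(f < 0) || sum(f) <= 0) stop("class base frequencies invalid")
  starts <- .DEFAULT_STARTS
  if (!is.null(start_codons)) starts[names(start_codons)] <- start_codons
  stops <- .DEFAULT_STOPS
  if (!is.null(stop_codons)) stops[names(stop_codons)] <- stop_codons
  if (!all(stops %in% c("TAA", "TAG", "T", "TA", "A")))
    stop("stop codons must be TAA, TAG, T, TA or A")
  order <- switch(gene_order_template,
                  lepidopteran = orderLabels(lepidopteranOrder()),
                  ancestral_insect = orderLabels(ancestralInsectOrder()),
                  custom = {
                    if (is.null(custom_order))
                      stop("custom template needs 'custom_order'")
                    sub("^\\+", "", custom_order)
                  })
  pcgs <- intersect(sub("^-", "", order), .PCG_LABELS)
  for (g in pcgs) {
    r <- lens[[g]] %% 3L
    want <- nchar(stops[[g]]) %% 3L
    if (r != want)
      stop("gene ", g, ": length ", lens[[g]], " is incompatible with stop '",
           stops[[g]], "' (length mod 3 must be ", want, ")")
    if (lens[[g]] < 6L) stop("PCG ", g, " shorter than 6 nt")
  }
  if (!is.null(target_overlaps)) {
    for (nm in names(target_overlaps)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1L]]
      if (length(pair) != 2L)
        stop("overlap name must be 'upstream|downstream': ", nm)
      k <- as.integer(target_overlaps[[nm]])
      if (k < 1L) stop("overlap must be a positive number of nt: ", nm)
      down <- sub("^-", "", pair[2L])
      if (.klassForLabel(down) %in% c("PCG", "control"))
        stop("overlap infeasible: downstream feature ", down,
             " is a ", .klassForLabel(down),
             " and would lose its planted sequence")
      if (k >= min(lens[[sub("^-", "", pair[1L])]], lens[[down]]))
        stop("overlap ", k, " nt is larger than gene ", nm)
    }
  }
  structure(list(seed = as.integer(seed), order = order, gene_lengths = lens,
                 codon_weights = weights, class_freqs = freqs,
                 start_codons = starts, stop_codons = stops,
                 control_motif_offset = control_motif_offset,
                 control_polyT_length = as.integer(control_polyT_length),
                 control_repeat_unit_length = control_repeat_unit_length,
                 control_repeat_copies = control_repeat_copies,
                 control_repeat_offset = as.integer(control_repeat_offset),
                 target_overlaps = target_overlaps),
            class = "SyntheticSpec")
}

.sampleBases <- function(n, freqs) {
  if (n <= 0L) return("")
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

## a repeat unit must not itself be periodic, or the planted array would
## be reported at a smaller period
.sampleRepeatUnit <- function(p, freqs) {
  for (i in 1:200) {
    unit <- .sampleBases(p, freqs)
    chars <- strsplit(unit, "")[[1L]]
    if (is.na(.smallerPeriod(chars, 1L, p, p))) return(unit)
  }
  stop("could not sample an aperiodic repeat unit of length ", p)
}

.buildControlRegion <- function(spec) {
  len <- spec$gene_lengths[[.CONTROL_LABEL]]
  freqs <- spec$class_freqs$control
  chars <- strsplit(.sampleBases(len, freqs), "")[[1L]]
  truth <- list(motif = NULL, repeats = NULL)
  if (!is.na(spec$control_motif_offset)) {
    off <- spec$control_motif_offset
    pt <- spec$control_polyT_length
    if (off + 4L + pt > len)
      stop("control region too short for the planted motif")
    chars[off:(off + 4L)] <- c("A", "T", "A", "G", "A")
    chars[(off + 5L):(off + 4L + pt)] <- "T"
    ## break any accidental continuation of the poly-T run
    if (off > 1L && chars[off - 1L] == "T") chars[off - 1L] <- "A"
    if (off + 5L + pt <= len && chars[off + 5L + pt] == "T")
      chars[off + 5L + pt] <- "A"
    truth$motif <- data.frame(position = off, motif = "ATAGA",
                              polyT_start = off + 5L, polyT_length = pt)
  }
  if (!is.na(spec$control_repeat_unit_length)) {
    p <- as.integer(spec$control_repeat_unit_length)
    span <- as.integer(floor(p * spec$control_repeat_copies))
    off <- spec$control_repeat_offset
    if (spec$control_repeat_copies < 2) stop("planted repeat needs >= 2 copies")
    if (off + span - 1L > len)
      stop("control region too short for the planted tandem repeat")
    if (!is.null(truth$motif) &&
        off <= truth$motif$polyT_start + truth$motif$polyT_length &&
        off + span - 1L >= truth$motif$position)
      stop("planted tandem repeat overlaps the planted motif")
    unit <- .sampleRepeatUnit(p, freqs)
    uchr <- strsplit(unit, "")[[1L]]
    array <- rep(uchr, length.out = span)
    chars[off:(off + span - 1L)] <- array
    ## keep the planted array maximal: neither side may extend the run
    if (off > 1L) {
      ## left neighbour must differ from the base one period before start
      if (chars[off - 1L] == chars[off - 1L + p])
        chars[off - 1L] <- setdiff(c("A", "T"), chars[off - 1L + p])[1L]
    }
    right <- off + span
    if (right <= len && chars[right] == chars[right - p])
      chars[right] <- setdiff(c("A", "T"), chars[right - p])[1L]
    truth$repeats <- data.frame(start = off, end = off + span - 1L,
                                period = p, copies = span / p, unit = unit,
                                stringsAsFactors = FALSE)
  }
  list(seq = paste(chars, collapse = ""), truth = truth)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic given the spec (the spec's seed is applied on entry).
#' PCGs are assembled codon-wise: the planted start codon, body codons
#' sampled from the spec's codon weights, and a complete (TAA/TAG) or
#' planted-incomplete (T/TA/A) stop consistent with the gene length.
#' tRNA and rRNA bodies are drawn from their class base frequencies; the
#' control region is AT-biased filler with the configured motif and
#' tandem repeat planted at known offsets. Features are placed
#' back-to-back in template order (the configured overlaps shift a
#' downstream non-coding feature into its predecessor); minority-strand
#' features are reverse-complemented into the genome.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{genome} (a \linkS4class{MitoGenome}) and
#'   \code{truth}: \code{gene_order} (signed labels),
#'   \code{codon_counts} (realized, over 64 DNA codons),
#'   \code{class_base_counts} (per region class, from the assembled
#'   genome), \code{pcg_codons} (per-gene start/stop table),
#'   \code{control} (planted motif and repeat tables, offsets within the
#'   region).
#' @export
generateGenome <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  labels <- spec$order
  base <- sub("^-", "", labels)
  strands <- ifelse(grepl("^-", labels), "R", "F")
  lens <- spec$gene_lengths
  codon_counts <- setNames(integer(64), .DNA_CODONS)
  pcg_rows <- list()
  control_truth <- list(motif = NULL, repeats = NULL)

  sense <- character(length(labels))
  for (i in seq_along(labels)) {
    g <- base[i]
    klass <- .klassForLabel(g)
    len <- lens[[g]]
    if (is.null(len) || is.na(len)) stop("no length for feature ", g)
    if (klass == "PCG") {
      start <- spec$start_codons[[g]]
      stp <- spec$stop_codons[[g]]
      n_full <- (len - (nchar(stp) %% 3L)) %/% 3L
      n_body <- n_full - 1L - as.integer(nchar(stp) == 3L)
      body <- sample(.DNA_CODONS, n_body, replace = TRUE,
                     prob = spec$codon_weights)
      cds <- paste0(start, paste(body, collapse = ""), stp)
      tallied <- c(start, body, if (nchar(stp) == 3L) stp)
      tab <- table(tallied)
      codon_counts[names(tab)] <- codon_counts[names(tab)] + as.integer(tab)
      pcg_rows[[g]] <- data.frame(gene = g, start_codon = start,
                                  stop_codon = stp, stringsAsFactors = FALSE)
      sense[i] <- cds
    } else if (klass %in% c("tRNA", "rRNA")) {
      sense[i] <- .sampleBases(len, spec$class_freqs[[klass]])
    } else if (klass == "control") {
      cr <- .buildControlRegion(spec)
      sense[i] <- cr$seq
      control_truth <- cr$truth
    } else stop("unknown feature label ", g)
    if (nchar(sense[i]) != len)
      stop("internal error: generated length mismatch for ", g)
  }

  ## assemble the circle; overlaps pull a downstream feature back into
  ## its predecessor, reusing the bases already laid down
  overlaps <- spec$target_overlaps
  genome_chars <- character(0)
  start_pos <- end_pos <- integer(length(labels))
  for (i in seq_along(labels)) {
    frag <- if (strands[i] == "R") revComp(sense[i]) else sense[i]
    k <- 0L
    if (i > 1L && !is.null(overlaps)) {
      key <- paste0(base[i - 1L], "|", base[i])
      if (key %in% names(overlaps)) k <- as.integer(overlaps[[key]])
    }
    pos <- length(genome_chars) - k + 1L
    if (k > 0L) frag <- substr(frag, k + 1L, nchar(frag))
    genome_chars <- c(genome_chars, strsplit(frag, "")[[1L]])
    start_pos[i] <- pos
    end_pos[i] <- pos + lens[[base[i]]] - 1L
  }
  sequence <- paste(genome_chars, collapse = "")

  ft <- data.frame(name = base, klass = .klassForLabel(base),
                   strand = strands, start = start_pos, end = end_pos,
                   anticodon = ifelse(base %in% names(.DEFAULT_ANTICODONS),
                                      .DEFAULT_ANTICODONS[base],
                                      NA_character_),
                   stringsAsFactors = FALSE)
  genome <- MitoGenome(paste0("synthetic_seed", spec$seed), sequence, ft)

  ## realized per-class base counts, measured on the assembled genome so
  ## overlap-adjusted features are counted as they will be extracted
  fts <- features(genome)
  class_counts <- lapply(c(PCG = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                           control = "control"), function(kl) {
    idx <- which(fts$klass == kl)
    Reduce(`+`, lapply(idx, function(j)
      baseCounts(extractFeatureSequence(genome, fts[j, ]))),
      c(A = 0L, T = 0L, G = 0L, C = 0L, N = 0L))
  })
  class_counts$whole_genome <- baseCounts(sequence)

  list(genome = genome,
       truth = list(gene_order = labels,
                    codon_counts = codon_counts,
                    class_base_counts = class_counts,
                    pcg_codons = do.call(rbind, pcg_rows),
                    control = control_truth))
}

#' Write a synthetic fixture to disk
#'
#' Emits \code{<prefix>.gb} (GenBank flat file),
#' \code{<prefix>_features.tsv}, and plain-text ground-truth tables:
#' \code{<prefix>_truth_codons.tsv}, \code{<prefix>_truth_genes.tsv},
#' \code{<prefix>_truth_control.tsv}. All files round-trip through the
#' package's readers.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param truth the truth list from \code{\link{generateGenome}}.
#' @param prefix output path prefix (directories are created).
#' @return named character vector of the files written (invisibly).
#' @export
writeFixture <- function(genome, truth, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  paths <- c(genbank = paste0(prefix, ".gb"),
             features = paste0(prefix, "_features.tsv"),
             codons = paste0(prefix, "_truth_codons.tsv"),
             genes = paste0(prefix, "_truth_genes.tsv"),
             control = paste0(prefix, "_truth_control.tsv"))
  tryCatch({
    writeGenBank(genome, paths[["genbank"]])
    writeFeatureTSV(genome, paths[["features"]])
    write.table(data.frame(codon = names(truth$codon_counts),
                           count = unname(truth$codon_counts)),
                paths[["codons"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth$pcg_codons, paths[["genes"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    ctrl <- truth$control
    lines <- c("element\tposition\tlength\tperiod\tcopies\tunit")
    if (!is.null(ctrl$motif))
      lines <- c(lines, sprintf("motif\t%d\t%d\tNA\tNA\tATAGA",
                                ctrl$motif$position, ctrl$motif$polyT_length))
    if (!is.null(ctrl$repeats))
      lines <- c(lines, sprintf("repeat\t%d\t%d\t%d\t%.6f\t%s",
                                ctrl$repeats$start,
                                ctrl$repeats$end - ctrl$repeats$start + 1L,
                                ctrl$repeats$period, ctrl$repeats$copies,
                                ctrl$repeats$unit))
    writeLines(lines, paths[["control"]])
  }, error = function(e)
    stop("failed writing fixture at prefix '", prefix, "': ",
         conditionMessage(e)))
  invisible(paths)
}
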