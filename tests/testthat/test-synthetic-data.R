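test_that("generation is deterministic given the spec", {
  a <- generateGenome(syntheticSpec(seed = 5))
  b <- generateGenome(syntheticSpec(seed = 5))
  expect_identical(as.character(genomeSeq(a$genome)),
                   as.character(genomeSeq(b$genome)))
  expect_identical(features(a$genome), features(b$genome))
  expect_identical(a$truth, b$truth)
  c <- generateGenome(syntheticSpec(seed = 6))
  expect_false(identical(as.character(genomeSeq(a$genome)),
                         as.character(genomeSeq(c$genome))))
})

test_that("the default spec emits a realistic 38-feature mitogenome", {
  sim <- generateGenome(syntheticSpec(seed = 1))
  g <- sim$genome
  ft <- features(g)
  expect_equal(nrow(ft), 38L)
  expect_gt(genomeLength(g), 15000L)
  expect_lt(genomeLength(g), 16000L)
  expect_equal(sum(ft$klass == "PCG"), 13L)
  expect_equal(sum(ft$klass == "tRNA"), 22L)
  expect_equal(sum(ft$klass == "rRNA"), 2L)
  expect_equal(sum(ft$klass == "control"), 1L)
  expect_identical(orderLabels(extractGeneOrder(g)), sim$truth$gene_order)
  expect_identical(detectTranslocatedGenes(extractGeneOrder(g),
                                           ancestralInsectOrder()),
                   "trnM")
})

test_that("planted codon weights shape the sampled usage", {
  ## weights proportional to the published hawkmoth Leu counts: with
  ## thousands of sampled Leu codons the realized RSCU sits near 5.32
  sim <- generateGenome(syntheticSpec(seed = 4))
  counts <- sim$truth$codon_counts
  leu <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  expect_gt(sum(counts[leu]), 400)
  r <- rscu(counts)
  expect_lt(abs(r[["TTA"]] - 5.32), 0.35)
  ## and the genome-level table equals the recorded draw exactly
  tab <- codonUsageTable(sim$genome)
  expect_equal(setNames(tab$count, codonToDNA(tab$codon))[names(counts)],
               counts)
})

test_that("infeasible specs are rejected with named constraints", {
  expect_error(syntheticSpec(gene_lengths = c(nad2 = 1013L)),
               "nad2.*incompatible")
  expect_error(syntheticSpec(target_overlaps = c("atp8|atp6" = 7L)),
               "infeasible")
  expect_error(syntheticSpec(target_overlaps = c("trnW|trnC" = 200L)),
               "larger")
  expect_error(syntheticSpec(pcg_codon_weights = c(TAA = 1)),
               "normalizable")
})

test_that("requested overlaps are realized between non-coding neighbours", {
  spec <- syntheticSpec(seed = 9, target_overlaps = c("trnW|trnC" = 8L))
  sim <- generateGenome(spec)
  ft <- features(sim$genome)
  w <- ft[ft$name == "trnW", ]; c2 <- ft[ft$name == "trnC", ]
  expect_equal(c2$start - w$end - 1L, -8L)
  ## composition still matches recorded (post-assembly) truth
  comp <- compositionByClass(sim$genome)
  trna <- comp[comp$region == "tRNAs", ]
  expect_equal(unlist(trna[c("A", "T", "G", "C")], use.names = FALSE),
               unname(sim$truth$class_base_counts$tRNA[c("A", "T", "G", "C")]))
})

test_that("class base frequencies converge across seeds", {
  ## empirical tRNA-class frequencies across several seeds stay within 3
  ## multinomial standard errors of the spec frequencies
  freqs <- c(A = 0.412, T = 0.403, G = 0.079, C = 0.106)
  tot <- c(A = 0, T = 0, G = 0, C = 0); n <- 0
  for (seed in 1:5) {
    sim <- generateGenome(syntheticSpec(seed = seed))
    bc <- sim$truth$class_base_counts$tRNA
    tot <- tot + bc[c("A", "T", "G", "C")]
    n <- n + sum(bc)
  }
  for (b in names(freqs)) {
    se <- sqrt(freqs[[b]] * (1 - freqs[[b]]) / n)
    expect_lt(abs(tot[[b]] / n - freqs[[b]]), 3 * se + 1e-12)
  }
})

test_that("fixtures round-trip through the package readers", {
  tmp <- withr::local_tempdir()
  sim <- generateGenome(syntheticSpec(seed = 3))
  paths <- writeFixture(sim$genome, sim$truth, file.path(tmp, "fix"))
  expect_true(all(file.exists(paths)))

  gb <- parseGenBank(paths[["genbank"]])
  expect_identical(features(gb), features(sim$genome))
  expect_identical(as.character(genomeSeq(gb)),
                   as.character(genomeSeq(sim$genome)))

  tsv <- parseFeatureTSV(paths[["features"]],
                         as.character(genomeSeq(sim$genome)),
                         id = genomeID(sim$genome))
  expect_identical(features(tsv), features(sim$genome))

  ## the truth files list the planted elements
  codons <- read.delim(paths[["codons"]])
  expect_equal(setNames(codons$count, codons$codon)[names(sim$truth$codon_counts)],
               sim$truth$codon_counts)
  ctrl <- read.delim(paths[["control"]])
  expect_true("motif" %in% ctrl$element)
  expect_true("repeat" %in% ctrl$element)
})

test_that("a fixture without control elements reports empty sections", {
  spec <- syntheticSpec(seed = 2, control_motif_offset = NA,
                        control_repeat_unit_length = NA)
  sim <- generateGenome(spec)
  expect_null(sim$truth$control$motif)
  expect_null(sim$truth$control$repeats)
  tmp <- withr::local_tempdir()
  paths <- writeFixture(sim$genome, sim$truth, file.path(tmp, "empty"))
  ctrl <- read.delim(paths[["control"]])
  expect_equal(nrow(ctrl), 0L)
})
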