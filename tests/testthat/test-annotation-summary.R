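test_that("feature lengths follow the circular convention", {
  expect_equal(featureLength(c(1463, 2990)), 1528L)
  expect_equal(featureLength(c(6355, 8076)), 1722L)
  expect_equal(featureLength(c(1, 1)), 1L)
  expect_equal(featureLength(c(15280, 5), 15282L), 8L)  # wraps the origin
  expect_error(featureLength(c(10, 2)), "genome_length")
})

test_that("intergenic spacers handle gaps, overlaps and circular closure", {
  expect_equal(intergenicSpacer(list(end = 198), list(start = 255)), 56L)
  expect_equal(intergenicSpacer(list(end = 4043), list(start = 4037)), -7L)
  expect_equal(intergenicSpacer(list(end = 10), list(start = 11)), 0L)
  expect_equal(intergenicSpacer(list(end = 15282), list(start = 1),
                                genome_length = 15282L,
                                circular_closure = TRUE), 0L)
  f <- list(name = "x", start = 5, end = 9)
  expect_error(intergenicSpacer(f, f), "itself")
})

test_that("start codons are classified with the canonical mito set", {
  expect_identical(classifyStartCodon("CGAGCTAAA"),
                   list(codon = "CGA", canonical = TRUE))
  expect_true(classifyStartCodon("ATGAAA")$canonical)
  st <- classifyStartCodon("GTGAAA")
  expect_identical(st$codon, "GTG")
  expect_false(st$canonical)
  expect_error(classifyStartCodon("AT"), "shorter")
})

test_that("stop codons cover complete and incomplete forms", {
  expect_identical(classifyStopCodon("ATGAAATAA")$stop, "TAA")
  expect_identical(classifyStopCodon("ATGAAATAG")$stop, "TAG")
  ## length mod 3 == 1 with terminal T or A -> incomplete single base
  expect_identical(classifyStopCodon(paste0(strrep("ATG", 227), "T"))$stop, "T")
  expect_identical(classifyStopCodon("ATGAAAA")$stop, "A")
  ## length mod 3 == 2 ending TA
  expect_identical(classifyStopCodon(paste0(strrep("ATT", 579), "TA"))$stop, "TA")
  bad <- classifyStopCodon("ATGAAAAGG")
  expect_identical(bad$stop, "OTHER")
  expect_false(bad$consistent)
})

test_that("the published coordinate tables are reproduced row-for-row", {
  for (sp in c("A_rubiginosa", "R_menciana")) {
    g <- publishedCoordinateGenome(sp)
    s <- buildSummaryTable(g)
    pub <- publishedFeatureTable(sp)
    expect_equal(s$size_nt, pub$size)
    comparable <- which(!is.na(pub$intergenic))
    if (sp == "R_menciana") {
      ## the published trnG cell reads 0 but the printed coordinates give
      ## -3 (trnG 5512-5577 vs nad3 5575); the computed value is kept
      i <- which(pub$gene == "trnG")
      expect_equal(s$intergenic_nt[i], -3L)
      comparable <- setdiff(comparable, i)
    }
    expect_equal(s$intergenic_nt[comparable], pub$intergenic[comparable])
    ## the blank final cell closes the circle
    expect_equal(s$intergenic_nt[38], 0L)
    ## telescoping identity on the circle
    expect_equal(sum(s$size_nt + s$intergenic_nt), genomeLength(g))
  }
})

test_that("summary tables agree with generator ground truth", {
  sim <- generateGenome(syntheticSpec(seed = 42))
  s <- buildSummaryTable(sim$genome)
  expect_equal(sum(s$size_nt + s$intergenic_nt), genomeLength(sim$genome))
  expect_true(all(s$size_nt + s$start - 1L == s$end |
                  s$end < s$start))        # non-wrapping identity
  pc <- merge(s[s$klass == "PCG", ], sim$truth$pcg_codons, by.x = "gene",
              by.y = "gene")
  expect_identical(pc$start_codon.x, pc$start_codon.y)
  expect_identical(pc$stop_codon.x, pc$stop_codon.y)
  expect_true(all(pc$start_ok) && all(pc$stop_ok))
})

test_that("a single-feature genome closes the circle onto itself", {
  g <- MitoGenome("solo", strrep("ACGT", 5),
                  data.frame(name = "x", klass = "other", strand = "F",
                             start = 3L, end = 12L))
  s <- buildSummaryTable(g)
  expect_equal(nrow(s), 1L)
  expect_equal(s$intergenic_nt, 10L)   # 20-bp circle minus the feature
  expect_equal(s$size_nt + s$intergenic_nt, 20L)
})
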