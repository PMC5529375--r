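test_that("reverse complement is correct and involutive", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAC"), "GTT")
  expect_identical(revComp("N"), "N")
  expect_error(revComp("ACGU"), "outside")
  set.seed(11)
  for (i in 1:25) {
    s <- randomDNA(50)
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("feature sequences are extracted strand-correctly, wrap included", {
  g <- MitoGenome("toy", "AACGTT",
                  data.frame(name = c("f", "r"), klass = "other",
                             strand = c("F", "R"), start = 2L, end = 4L))
  expect_identical(extractFeatureSequence(g, "f"), "ACG")
  expect_identical(extractFeatureSequence(g, "r"), "CGT")

  wrap <- MitoGenome("circ", "AAAAACCCCC",
                     data.frame(name = "w", klass = "other", strand = "F",
                                start = 9L, end = 2L))
  expect_identical(extractFeatureSequence(wrap, "w"), "CCAA")
  wrapR <- MitoGenome("circ", "AAAAACCCCC",
                      data.frame(name = "w", klass = "other", strand = "R",
                                 start = 9L, end = 2L))
  expect_identical(extractFeatureSequence(wrapR, "w"), revComp("CCAA"))
})

test_that("feature TSV parses, validates and round-trips", {
  tsv <- "name\tklass\tstrand\tstart\tend\tanticodon\ntrnM\ttRNA\tF\t1\t68\tCAT\n"
  g <- parseFeatureTSV(tsv, strrep("A", 100), id = "mini")
  expect_s4_class(g, "MitoGenome")
  expect_equal(nrow(features(g)), 1L)
  expect_identical(features(g)$anticodon, "CAT")

  ## origin-spanning row (end < start) is accepted on the circle
  tsv2 <- paste0("name\tklass\tstrand\tstart\tend\tanticodon\n",
                 "x\tother\tF\t90\t10\tNA\n")
  g2 <- parseFeatureTSV(tsv2, strrep("A", 100))
  expect_equal(featureLength(features(g2)[1, ], 100L), 21L)

  expect_error(parseFeatureTSV("name\tklass\tstrand\tstart\tend\nx\tbogus\tF\t1\t5\n",
                               strrep("A", 10)), "klass")
  expect_error(parseFeatureTSV("name\tklass\tstrand\tstart\tend\nx\tother\tF\t1.5\t5\n",
                               strrep("A", 10)), "integer")

  ## round-trip on a realistic table
  full <- publishedCoordinateGenome("A_rubiginosa")
  back <- parseFeatureTSV(writeFeatureTSV(full),
                          as.character(genomeSeq(full)), id = genomeID(full))
  expect_identical(features(back), features(full))
})

test_that("the published coordinate sets load with the expected structure", {
  g <- publishedCoordinateGenome("A_rubiginosa")
  ft <- features(g)
  expect_equal(nrow(ft), 38L)
  expect_equal(sum(ft$strand == "R"), 14L)   # 4 PCGs + 8 tRNAs + 2 rRNAs
  expect_equal(sum(ft$strand == "F"), 24L)
  expect_equal(genomeLength(g), 15282L)

  r <- publishedCoordinateGenome("R_menciana")
  expect_equal(nrow(features(r)), 38L)
  expect_equal(genomeLength(r), 15636L)
  last <- features(r)[38, ]
  expect_identical(last$name, "AT_rich_region")
  expect_equal(c(last$start, last$end), c(15033L, 15636L))
})

test_that("GenBank parsing handles complement, join and synonym mapping", {
  gb <- paste(
    "LOCUS       demo 100 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     tRNA            complement(30..98)",
    "                     /gene=\"tRNA-Gln\"",
    "                     /anticodon_seq=\"TTG\"",
    "     CDS             join(90..100,1..20)",
    "                     /gene=\"COI\"",
    "     misc_feature    40..60",
    "                     /note=\"A+T-rich region\"",
    "ORIGIN",
    paste0("        1 ", tolower(strrep("acgtacgtag", 6))),
    paste0("       61 ", tolower(strrep("acgtacgtag", 4))),
    "//", sep = "\n")
  g <- parseGenBank(gb)
  ft <- features(g)
  expect_equal(genomeLength(g), 100L)
  q <- ft[ft$name == "trnQ", ]
  expect_identical(c(q$strand, q$anticodon), c("R", "TTG"))
  expect_equal(c(q$start, q$end), c(30L, 98L))
  cx <- ft[ft$name == "cox1", ]
  expect_identical(cx$klass, "PCG")
  expect_equal(c(cx$start, cx$end), c(90L, 20L))   # wraps the origin
  expect_identical(ft$name[ft$klass == "control"], "AT_rich_region")

  expect_error(parseGenBank(sub("ORIGIN", "NOTHING", gb)), "ORIGIN")
})

test_that("GenBank writing round-trips through the parser", {
  g <- publishedCoordinateGenome("R_menciana")
  back <- parseGenBank(writeGenBank(g))
  expect_identical(features(back), features(g))
  expect_identical(as.character(genomeSeq(back)), as.character(genomeSeq(g)))
})

test_that("MitoGenome validity rejects malformed annotations", {
  expect_error(MitoGenome("x", "ACGT",
                          data.frame(name = c("a", "a"), klass = "other",
                                     strand = "F", start = 1L, end = 2L)),
               "duplicate")
  expect_error(MitoGenome("x", "ACGT",
                          data.frame(name = "a", klass = "other",
                                     strand = "F", start = 1L, end = 9L)),
               "outside")
  expect_error(MitoGenome("x", "ACGT",
                          data.frame(name = "t", klass = "tRNA",
                                     strand = "F", start = 1L, end = 2L)),
               "anticodon")
})
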