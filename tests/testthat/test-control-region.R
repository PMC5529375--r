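test_that("the A+T-rich region is located from annotation or from the gap", {
  ## annotated control features are returned directly
  for (sp in c("A_rubiginosa", "R_menciana")) {
    r <- locateATRichRegion(publishedCoordinateGenome(sp))
    expect_identical(r$name, "AT_rich_region")
  }
  ## with the control row dropped, the gap search recovers the same span
  a <- locateATRichRegion(publishedCoordinateGenome("A_rubiginosa",
                                                    drop_control = TRUE))
  expect_equal(c(a$start, a$end, a$length), c(14884L, 15282L, 399L))
  m <- locateATRichRegion(publishedCoordinateGenome("R_menciana",
                                                    drop_control = TRUE))
  expect_equal(c(m$start, m$end, m$length), c(15033L, 15636L, 604L))

  ## a gap-free genome has nothing to find
  g <- MitoGenome("full", strrep("A", 40),
                  data.frame(name = c("a", "b"), klass = "other",
                             strand = "F", start = c(1L, 21L),
                             end = c(20L, 40L)))
  expect_error(locateATRichRegion(g), "min_gap|fully annotated")
})

test_that("ATAGA + poly-T motifs are found with run lengths", {
  hit <- findAtagaPolyT("ATAGATTTTTT", min_polyT = 5, window = 5)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$position, hit$polyT_length), c(1L, 6L))
  expect_equal(nrow(findAtagaPolyT("ATAGAGGGGG", min_polyT = 5)), 0L)
  ## run starting later within the window still qualifies
  hit <- findAtagaPolyT("GGATAGACGTTTTTTTAAA", min_polyT = 5, window = 10)
  expect_equal(c(hit$position, hit$polyT_start, hit$polyT_length),
               c(3L, 10L, 7L))
  ## run starting beyond the window does not
  expect_equal(nrow(findAtagaPolyT(paste0("ATAGA", strrep("G", 21), "TTTTT"),
                                   min_polyT = 5, window = 20)), 0L)
})

test_that("tandem repeats are found exactly with the smallest period", {
  r <- findTandemRepeats("ACGACGACG", min_period = 3, min_span = 6)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end, r$period), c(1L, 9L, 3L))
  expect_equal(r$copies, 3)
  expect_identical(r$unit, "ACG")
  ## period-2 canonical form wins over its multiples
  r <- findTandemRepeats("ATATATATAT", min_period = 2, min_span = 6)
  expect_equal(r$period, 2L)
  expect_equal(nrow(r), 1L)
  ## reported spans truly satisfy the periodicity they claim
  set.seed(6)
  for (i in 1:10) {
    s <- randomDNA(150, c(A = .4, C = .1, G = .1, T = .4))
    reps <- findTandemRepeats(s, min_period = 2, max_period = 30,
                              min_copies = 2, min_span = 8)
    chars <- strsplit(s, "")[[1]]
    for (j in seq_len(nrow(reps))) {
      idx <- (reps$start[j] + reps$period[j]):reps$end[j]
      expect_true(all(chars[idx] == chars[idx - reps$period[j]]))
    }
  }
})

test_that("detector and brute-force oracle agree on random regions", {
  set.seed(31)
  for (i in 1:40) {
    s <- randomDNA(sample(40:200, 1),
                   if (i %% 2) c(A = .25, C = .25, G = .25, T = .25)
                   else c(A = .4, C = .1, G = .1, T = .4))
    got <- findTandemRepeats(s, min_period = 2, max_period = 20,
                             min_copies = 2, min_span = 8)
    want <- oracleTandemRepeats(s, min_period = 2, max_period = 20,
                                min_copies = 2, min_span = 8)
    expect_equal(got, want, info = paste("string", i))
  }
})

test_that("planted control-region elements are recovered from fixtures", {
  sim <- generateGenome(syntheticSpec(seed = 12))
  region <- locateATRichRegion(sim$genome)
  seq <- extractFeatureSequence(sim$genome, region)
  truth <- sim$truth$control

  hits <- findAtagaPolyT(seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, truth$motif$position)
  expect_equal(hits$polyT_length, truth$motif$polyT_length)

  reps <- findTandemRepeats(seq, min_span = 30)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps[, c("start", "end", "period", "copies", "unit")],
               truth$repeats[, c("start", "end", "period", "copies", "unit")])
})
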