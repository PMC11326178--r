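test_that("computePsi implements the length-normalized inclusion formula", {
  expect_equal(computePsi(0, 15, 2, 1), 0)
  expect_equal(computePsi(20, 10, 2, 1), 0.5)  # (20/2)/(20/2 + 10/1)
  expect_true(is.na(computePsi(0, 0, 2, 1)))
  expect_equal(computePsi(c(20, 0), c(10, 0), 2, 1), c(0.5, NA))
  expect_error(computePsi(1, 1, 0, 1), "positive")
  expect_error(computePsi(-1, 1, 2, 1), "non-negative")
})

.writeRmatsFixture <- function(rows) {
  hdr <- paste("ID", "GeneID", "geneSymbol", "chr", "strand",
               "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
               "downstreamES", "downstreamEE", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
               "IncFormLen", "SkipFormLen", "IncLevel1", sep = "\t")
  f <- tempfile(fileext = ".txt")
  writeLines(c(hdr, rows), f)
  f
}

test_that("readRmatsTable parses, recomputes blank PSI, and reports errors", {
  f <- .writeRmatsFixture(
    "1\tG1\tGENE1\tchr1\t+\t100\t200\t0\t50\t300\t400\t20\t10\t2\t1\t")
  tb <- readRmatsTable(f, "SE", sampleId = "s1")
  expect_s4_class(tb, "SpliceEventTable")
  expect_equal(nEvents(tb), 1L)
  expect_equal(eventData(tb)$psi, 0.5)  # recomputed from counts
  expect_equal(eventData(tb)$exon_start, 100L)

  empty <- .writeRmatsFixture(character(0))
  expect_equal(nEvents(readRmatsTable(empty, "SE")), 0L)

  ## missing mandatory column is named in the error
  bad <- tempfile(fileext = ".txt")
  writeLines("ID\tGeneID\tgeneSymbol\tchr\tstrand", bad)
  expect_error(readRmatsTable(bad, "SE"), "exonStart_0base")

  ## non-numeric count carries the line number
  f2 <- .writeRmatsFixture(c(
    "1\tG1\tG1\tchr1\t+\t100\t200\t0\t50\t300\t400\t20\t10\t2\t1\t0.5",
    "2\tG2\tG2\tchr1\t+\t100\t200\t0\t50\t300\t400\tzz\t10\t2\t1\t0.5"))
  expect_error(readRmatsTable(f2, "SE"), "line 3")
})

test_that("multi-replicate IncLevel fields split into per-replicate tables", {
  f <- .writeRmatsFixture(
    "1\tG1\tG1\tchr1\t+\t100\t200\t0\t50\t300\t400\t20,30\t10,10\t2\t1\t0.5,0.6")
  tbs <- readRmatsTable(f, "SE", sampleId = "p")
  expect_length(tbs, 2L)
  expect_equal(sampleId(tbs[[2]]), "p_rep2")
  expect_equal(eventData(tbs[[1]])$psi, 0.5)
  expect_equal(eventData(tbs[[2]])$psi, 0.6)
  expect_equal(eventData(tbs[[2]])$ijc, 30)
})

test_that("writer and reader are inverse on generator output", {
  sim <- simulateCohort(cohortSpec(nSamples = 3, nEvents = c(SE = 40),
                                   nClusters = 1, missingRate = 0.1,
                                   seed = 5))
  tb <- sim$tables$SE[[2]]
  f <- tempfile(fileext = ".txt")
  writeRmatsTable(tb, f)
  tb2 <- readRmatsTable(f, "SE", sampleId = sampleId(tb))
  expect_identical(eventData(tb)[, c("gene_id", "chrom", "strand",
                                     "exon_start", "exon_end")],
                   eventData(tb2)[, c("gene_id", "chrom", "strand",
                                      "exon_start", "exon_end")])
  expect_equal(eventData(tb2)$psi, eventData(tb)$psi, tolerance = 1e-12)
  ## recomputed PSI matches the written IncLevel on every supported row
  ev <- eventData(tb2)
  ok <- !is.na(ev$psi)
  expect_equal(computePsi(ev$ijc[ok], ev$sjc[ok], ev$inc_form_len[ok],
                          ev$skip_form_len[ok]),
               ev$psi[ok], tolerance = 1e-6)
})

test_that("junction filter keeps >= minReads, is idempotent and monotone", {
  tb <- SpliceEventTable("s", "SE", makeEvents(3, ijc = c(4, 5, 6),
                                               sjc = c(5, 5, 5)))
  f10 <- applyJunctionFilter(tb, 10)
  expect_equal(nEvents(f10), 2L)  # supports 9, 10, 11
  expect_equal(eventData(f10)$ijc, c(5, 6))
  expect_equal(nEvents(applyJunctionFilter(tb, 0)), 3L)
  expect_equal(nEvents(applyJunctionFilter(tb, 100)), 0L)
  expect_identical(eventData(applyJunctionFilter(f10, 10)), eventData(f10))
  ## monotone: higher threshold keeps a subset
  for (m in c(0, 5, 10, 11, 12)) {
    lo <- eventData(applyJunctionFilter(tb, m))$gene_id
    hi <- eventData(applyJunctionFilter(tb, m + 1))$gene_id
    expect_true(all(hi %in% lo))
  }
})

test_that("buildPsiMatrix harmonizes events and applies the completeness floor", {
  ev <- makeEvents(1, ijc = 20, sjc = 10)
  tabs <- lapply(c("a", "b", "c"), function(s) SpliceEventTable(s, "SE", ev))
  pe <- buildPsiMatrix(tabs)
  expect_s4_class(pe, "PsiExperiment")
  expect_equal(dim(pe), c(1L, 3L))
  expect_false(anyNA(psiValues(pe)))
  expect_error(buildPsiMatrix(list(tabs[[1]], tabs[[1]])), "duplicate")

  ## an event present in 1 of 10 samples is dropped at the 0.8 floor
  evB <- makeEvents(2, ijc = c(20, 20), sjc = c(10, 10))
  tabs10 <- c(list(SpliceEventTable("x01", "SE", evB)),
              lapply(sprintf("x%02d", 2:10), function(s)
                SpliceEventTable(s, "SE", evB[1, ])))
  pe10 <- buildPsiMatrix(tabs10, 0.8)
  expect_equal(nrow(pe10), 1L)
  expect_equal(S4Vectors::metadata(pe10)$events_dropped_incomplete, 1L)

  ## synthetic cohort dimensions equal the generator truth
  sim <- simulateCohort(cohortSpec(nSamples = 20, nEvents = c(SE = 500),
                                   nClusters = 1, missingRate = 0.1,
                                   seed = 9))
  measured <- sapply(sim$tables$SE, function(tb) !is.na(eventData(tb)$psi))
  expected <- sum(rowMeans(measured) >= 0.8)
  peS <- buildPsiMatrix(sim$tables$SE, 0.8)
  expect_equal(dim(peS), c(expected, 20L))
})

test_that("buildPsiMatrix round-trips through write/read bit-stably", {
  sim <- simulateCohort(cohortSpec(nSamples = 4, nEvents = c(SE = 60),
                                   nClusters = 1, seed = 21))
  pe1 <- buildPsiMatrix(sim$tables$SE)
  d <- tempfile(); dir.create(d)
  tabs2 <- lapply(sim$tables$SE, function(tb) {
    f <- file.path(d, paste0(sampleId(tb), ".txt"))
    writeRmatsTable(tb, f)
    readRmatsTable(f, "SE", sampleId = sampleId(tb))
  })
  pe2 <- buildPsiMatrix(tabs2)
  expect_identical(dimnames(pe1), dimnames(pe2))
  expect_equal(psiValues(pe1), psiValues(pe2), tolerance = 1e-9)
})

test_that("readClinical types columns and validates invariants", {
  f <- tempfile()
  writeLines(c("sample_id\thistology\tos_days\tos_status\tefs_days\tefs_status",
               "s1\tHGG\t120\t1\t90\t1",
               "s2\tweird histology label\t400\t0\t400\t0"), f)
  cl <- readClinical(f)
  expect_equal(nrow(cl), 2L)
  expect_type(cl$os_days, "double")
  expect_equal(cl$histology[2], "weird histology label")
  expect_false(attr(cl, "has_tmb"))

  f2 <- tempfile()
  writeLines(c("sample_id\tos_days\tos_status", "s1\t-1\t0"), f2)
  expect_error(readClinical(f2), "negative survival time")
})

test_that("SpliceEventTable validity enforces the PSI/support invariant", {
  ev <- makeEvents(1, ijc = 0, sjc = 0)
  expect_true(is.na(ev$psi))
  expect_s4_class(SpliceEventTable("s", "SE", ev), "SpliceEventTable")
  ev$psi <- 0.5  # psi present with zero support violates the invariant
  expect_error(SpliceEventTable("s", "SE", ev), "missing exactly")
  ev2 <- makeEvents(1, ijc = 5, sjc = 5, psi = 1.5)
  expect_error(SpliceEventTable("s", "SE", ev2), "0, 1")
})
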