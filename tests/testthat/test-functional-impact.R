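## Hand-built two-exon transcript: + strand, exons (1-based GTF) 101-160 and
## 261-330, CDS covering 121-160 and 261-310 (90 nt = 30 residues).
.writeToyGtf <- function(strand = "+") {
  attr <- paste0('gene_id "GX"; transcript_id "TX"; gene_name "GX"; ',
                 'protein_id "PX";')
  lines <- c(
    paste("chrT", "toy", "exon", 101, 160, ".", strand, ".", attr, sep = "\t"),
    paste("chrT", "toy", "exon", 261, 330, ".", strand, ".", attr, sep = "\t"),
    paste("chrT", "toy", "CDS", 121, 160, ".", strand, ".", attr, sep = "\t"),
    paste("chrT", "toy", "CDS", 261, 310, ".", strand, ".", attr, sep = "\t"))
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

test_that("loadTranscriptModels converts GTF 1-based to 0-based half-open", {
  models <- loadTranscriptModels(.writeToyGtf("+"))
  tm <- models[["TX"]]
  expect_equal(tm$exons, cbind(start = c(100L, 260L), end = c(160L, 330L)),
               ignore_attr = TRUE)
  expect_equal(tm$cds, cbind(start = c(120L, 260L), end = c(160L, 310L)),
               ignore_attr = TRUE)
  expect_equal(tm$cds_len, 90L)
  expect_true(tm$valid); expect_true(tm$frame_ok)
  expect_equal(attr(models, "gene_index")$GX, "TX")
})

test_that("negative-strand models keep transcript orientation and frame flags", {
  models <- loadTranscriptModels(.writeToyGtf("-"))
  tm <- models[["TX"]]
  ## transcript order starts at the rightmost exon on the minus strand
  expect_equal(tm$exons_tx[1, ], c(start = 260L, end = 330L))

  ## CDS length not divisible by 3 is flagged
  attr <- 'gene_id "GY"; transcript_id "TY"; protein_id "PY";'
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "toy", "exon", 1, 100, ".", "+", ".", attr, sep = "\t"),
    paste("chrT", "toy", "CDS", 11, 30, ".", "+", ".", attr, sep = "\t")), f)
  expect_false(loadTranscriptModels(f)[["TY"]]$frame_ok)

  ## CDS outside the exon union is flagged invalid
  f2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "toy", "exon", 1, 100, ".", "+", ".", attr, sep = "\t"),
    paste("chrT", "toy", "CDS", 150, 200, ".", "+", ".", attr, sep = "\t")),
    f2)
  expect_false(loadTranscriptModels(f2)[["TY"]]$valid)
})

test_that("genomicToProtein maps CDS intervals to residues", {
  models <- loadTranscriptModels(.writeToyGtf("+"))
  tm <- models[["TX"]]
  ## first CDS exon part: CDS nucleotides 0..39 -> residues 1..14
  expect_equal(genomicToProtein(tm, 120, 160), c(first_res = 1L, last_res = 14L),
               ignore_attr = TRUE)
  ## whole CDS: 90 nt -> residues 1..30
  expect_equal(unname(genomicToProtein(tm, 0, 1000)), c(1L, 30L))
  ## pure 5'UTR interval
  expect_null(genomicToProtein(tm, 100, 120))
  ## junction-straddling interval agrees with the per-base oracle
  expect_equal(unname(genomicToProtein(tm, 150, 270)),
               unname(perBaseResidueSpan(tm, 150, 270)))
  expect_error(genomicToProtein(tm, 160, 150))
})

test_that("exon covering CDS nucleotides 0..29 on + strand gives residues 1-10", {
  attr <- 'gene_id "GZ"; transcript_id "TZ"; protein_id "PZ";'
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "toy", "exon", 1, 60, ".", "+", ".", attr, sep = "\t"),
    paste("chrT", "toy", "CDS", 11, 40, ".", "+", ".", attr, sep = "\t")), f)
  tm <- loadTranscriptModels(f)[["TZ"]]
  expect_equal(unname(genomicToProtein(tm, 10, 40)), c(1L, 10L))
})

test_that("interval mapping equals the per-base walk on random toy models", {
  ann <- simulateAnnotation(25, seed = 41)
  models <- loadTranscriptModels(ann$gtf)
  set.seed(5)
  for (tm in models) {
    lo <- min(tm$exons[, 1]); hi <- max(tm$exons[, 2])
    for (r in 1:8) {
      s <- sample(lo:(hi - 1), 1)
      e <- s + sample(1:200, 1)
      got <- genomicToProtein(tm, s, e)
      exp <- perBaseResidueSpan(tm, s, e)
      expect_equal(got, exp, ignore_attr = TRUE)
      if (!is.null(got)) {
        expect_lte(got[2], ceiling(tm$cds_len / 3))
        expect_gte(got[1], 1)
      }
    }
  }
})

test_that("annotateEvents classifies gain/loss/none with feature overlaps", {
  models <- loadTranscriptModels(.writeToyGtf("+"))
  features <- data.frame(
    protein_id = c("PX", "PX", "PX"),
    feature_type = c("DOMAIN", "DISULFID", "SIGNAL"),
    start_res = c(1L, 20L, 28L), end_res = c(14L, 20L, 30L),
    description = c("dom", "ss", "sig"), stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("evA", "evB"), gene_id = "GX", gene_symbol = "GX",
    chrom = "chrT", strand = "+",
    exon_start = c(100L, 100L), exon_end = c(160L, 120L),
    direction = c("skipping", "inclusion_gain"), stringsAsFactors = FALSE)
  ## evA covers residues 1..14 (domain hit); evB is pure UTR
  res <- annotateEvents(events, models, features)
  a <- res$byEvent[res$byEvent$event_id == "evA", ]
  expect_equal(a$impact, "loss")
  expect_equal(a$n_hits, 1L)
  expect_true(a$functional)
  b <- res$byEvent[res$byEvent$event_id == "evB", ]
  expect_equal(b$impact, "none")
  expect_equal(b$n_transcripts, 0L)
  ## single-residue disulfide feature inside a wider span overlaps 1 residue
  ev2 <- events[1, ]; ev2$direction <- "inclusion_gain"
  ev2$exon_start <- 120L; ev2$exon_end <- 330L  # full CDS, residues 1..30
  res2 <- annotateEvents(ev2, models, features)
  hit <- res2$hits[res2$hits$feature_type == "disulfide_bond", ]
  expect_equal(hit$overlap_residues, 1L)
  expect_equal(res2$byEvent$impact, "gain")
  ## category counts sum to total hits
  expect_equal(sum(res2$featureTypeCounts$per_hit), nrow(res2$hits))
})

test_that("frame_preserving equals exon length mod 3 == 0", {
  models <- loadTranscriptModels(.writeToyGtf("+"))
  ev <- data.frame(event_id = c("x", "y"), gene_id = "GX", gene_symbol = "GX",
                   chrom = "chrT", strand = "+",
                   exon_start = c(100L, 100L), exon_end = c(160L, 161L),
                   direction = "skipping", stringsAsFactors = FALSE)
  res <- annotateEvents(ev, models, data.frame(
    protein_id = character(0), feature_type = character(0),
    start_res = integer(0), end_res = integer(0),
    description = character(0)))
  expect_equal(res$byEvent$frame_preserving, c(TRUE, FALSE))
})

test_that("annotation output matches the generator's per-base truth exactly", {
  ann <- simulateAnnotation(30, seed = 3)
  models <- loadTranscriptModels(ann$gtf)
  res <- annotateEvents(ann$events, models, ann$featureTable)
  m <- merge(res$byEvent, ann$truth, by = "event_id",
             suffixes = c("_obs", "_exp"))
  expect_equal(nrow(m), 30L)
  expect_equal(m$n_hits_obs, m$n_hits_exp)
  expect_equal(m$impact_obs, m$impact_exp)
  expect_equal(m$frame_preserving_obs, m$frame_preserving_exp)
  bt <- merge(res$byTranscript, ann$truth, by = "event_id")
  expect_equal(bt$first_res.x, bt$first_res.y)
  expect_equal(bt$last_res.x, bt$last_res.y)
})

test_that("feature type labels normalize onto the reported categories", {
  expect_equal(normalizeFeatureType(c("DOMAIN", "DISULFID", "MOD_RES",
                                      "SIGNAL", "HELIX", "weird")),
               c("domain", "disulfide_bond", "modified_residue",
                 "localization_signal", "other", "other"))
})

test_that("filterKinases yields nested subsets and rejects empty lists", {
  be <- data.frame(event_id = paste0("e", 1:4),
                   gene_id = c("AKT1", "CLK1", "GAPDH", "SRPK1"),
                   gene_symbol = c("AKT1", "CLK1", "GAPDH", "SRPK1"),
                   direction = "skipping", impact = "loss",
                   stringsAsFactors = FALSE)
  out <- filterKinases(be, kinaseGenes = c("AKT1", "CLK1", "SRPK1"),
                       splicingRegulatorKinases = c("CLK1", "SRPK1"))
  expect_setequal(out$kinase$gene_symbol, c("AKT1", "CLK1", "SRPK1"))
  expect_setequal(out$splicing_regulator$gene_symbol, c("CLK1", "SRPK1"))
  expect_true(all(out$splicing_regulator$event_id %in% out$kinase$event_id))
  expect_equal(nrow(filterKinases(be, "NOTAGENE")$kinase), 0L)
  expect_error(filterKinases(be, character(0)), "empty")
})
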