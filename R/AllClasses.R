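#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

.EVENT_COLUMNS <- c("gene_id", "gene_symbol", "chrom", "strand",
                    "exon_start", "exon_end",
                    "upstream_start", "upstream_end",
                    "downstream_start", "downstream_end",
                    "ijc", "sjc", "inc_form_len", "skip_form_len", "psi")

#' SpliceEventTable: one sample's splice events
#'
#' Holds one sample's events of a single splice type (SE, A5SS, A3SS, RI)
#' with junction counts and percent-spliced-in (PSI). Coordinates are
#' 0-based half-open genomic intervals, the rMATS `exonStart_0base`
#' convention; conversion to 1-based GTF coordinates happens only inside the
#' functional-impact stage.
#'
#' @slot sampleId single sample identifier.
#' @slot spliceType one of `"SE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @slot events data.frame with one row per event; required columns are
#'   gene_id, gene_symbol, chrom, strand, exon_start, exon_end,
#'   upstream_start, upstream_end, downstream_start, downstream_end, ijc,
#'   sjc, inc_form_len, skip_form_len, psi.
#'
#' @export
setClass("SpliceEventTable",
         slots = c(sampleId = "character",
                   spliceType = "character",
                   events = "data.frame"))

setValidity("SpliceEventTable", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (!object@spliceType %in% c("SE", "A5SS", "A3SS", "RI"))
    msgs <- c(msgs, "spliceType must be one of SE, A5SS, A3SS, RI")
  ev <- object@events
  miss <- setdiff(.EVENT_COLUMNS, names(ev))
  if (length(miss))
    msgs <- c(msgs, paste("missing event columns:",
                          paste(miss, collapse = ", ")))
  if (!length(msgs) && nrow(ev)) {
    if (any(ev$ijc < 0 | ev$sjc < 0, na.rm = TRUE))
      msgs <- c(msgs, "junction counts must be non-negative")
    if (any(ev$inc_form_len <= 0 | ev$skip_form_len <= 0, na.rm = TRUE))
      msgs <- c(msgs, "form lengths must be positive")
    supp <- ev$ijc + ev$sjc
    bad <- xor(is.na(ev$psi), supp == 0)
    if (any(bad, na.rm = TRUE))
      msgs <- c(msgs, "psi must be missing exactly when ijc + sjc = 0")
    ok <- !is.na(ev$psi)
    if (any(ev$psi[ok] < 0 | ev$psi[ok] > 1))
      msgs <- c(msgs, "psi must lie in [0, 1]")
    if (any(ev$exon_start >= ev$exon_end))
      msgs <- c(msgs, "exon_start must be < exon_end")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpliceEventTable
#'
#' @param sampleId sample identifier.
#' @param spliceType splice type code.
#' @param events event data.frame (see [SpliceEventTable-class]).
#' @return A [SpliceEventTable-class] object.
#' @examples
#' ev <- data.frame(gene_id = "G1", gene_symbol = "G1", chrom = "chr1",
#'                  strand = "+", exon_start = 100L, exon_end = 200L,
#'                  upstream_start = 0L, upstream_end = 50L,
#'                  downstream_start = 300L, downstream_end = 400L,
#'                  ijc = 20L, sjc = 10L, inc_form_len = 2L,
#'                  skip_form_len = 1L, psi = 0.5)
#' SpliceEventTable("s1", "SE", ev)
#' @export
SpliceEventTable <- function(sampleId, spliceType, events) {
  new("SpliceEventTable", sampleId = as.character(sampleId),
      spliceType = spliceType, events = events)
}

#' @describeIn SpliceEventTable-class sample identifier accessor
#' @param x a `SpliceEventTable`.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn SpliceEventTable-class splice type accessor
#' @export
spliceType <- function(x) x@spliceType

#' @describeIn SpliceEventTable-class event data.frame accessor
#' @export
eventData <- function(x) x@events

#' @describeIn SpliceEventTable-class number of events
#' @export
nEvents <- function(x) nrow(x@events)

setMethod("show", "SpliceEventTable", function(object) {
  cat("SpliceEventTable for sample", object@sampleId,
      "(", object@spliceType, ")\n")
  cat(" ", nrow(object@events), "events;",
      sum(is.na(object@events$psi)), "with zero junction support\n")
})

#' PsiExperiment: cohort PSI matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' harmonized events-by-samples PSI matrix (`psi` assay, fractions in
#' `[0, 1]` with `NA` where a sample lacks the event) and the parallel
#' junction-read support matrix (`support` assay, `ijc + sjc`). Row metadata
#' carries the splice-event key; column metadata carries the clinical table.
#'
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
  msgs <- character()
  if (!all(c("psi", "support") %in% assayNames(object)))
    msgs <- c(msgs, "assays must include 'psi' and 'support'")
  else {
    p <- assay(object, "psi")
    if (any(p < 0 | p > 1, na.rm = TRUE))
      msgs <- c(msgs, "psi values must lie in [0, 1]")
    if (any(assay(object, "support") < 0, na.rm = TRUE))
      msgs <- c(msgs, "support must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "event identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PsiExperiment
#'
#' @param psi events-by-samples numeric matrix of PSI fractions with `NA`
#'   allowed; dimnames required and unique.
#' @param support matrix of the same shape with total junction reads.
#' @param rowData optional event-key metadata (one row per event).
#' @param colData optional sample metadata (clinical table).
#' @param metadata optional list of run metadata.
#' @return A [PsiExperiment-class].
#' @export
PsiExperiment <- function(psi, support, rowData = NULL, colData = NULL,
                          metadata = list()) {
  if (is.null(rowData))
    rowData <- S4Vectors::DataFrame(row.names = rownames(psi))
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(psi))
  se <- SummarizedExperiment(
    assays = list(psi = psi, support = support),
    rowData = rowData, colData = colData, metadata = metadata)
  new("PsiExperiment", se)
}

#' @describeIn PsiExperiment-class PSI assay accessor
#' @param x a `PsiExperiment`.
#' @export
psiValues <- function(x) assay(x, "psi")

#' @describeIn PsiExperiment-class junction-support assay accessor
#' @export
supportValues <- function(x) assay(x, "support")

setMethod("show", "PsiExperiment", function(object) {
  p <- assay(object, "psi")
  cat("PsiExperiment:", nrow(p), "events x", ncol(p), "samples\n")
  cat("  missing cells:", sum(is.na(p)),
      sprintf("(%.1f%%)\n", 100 * mean(is.na(p))))
  st <- metadata(object)$splice_type
  if (!is.null(st)) cat("  splice type:", st, "\n")
})
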