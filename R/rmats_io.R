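## rMATS turbo JC column schemas per splice type, mapped onto the generic
## (exon, upstream, downstream) key used internally. A5SS/A3SS use the
## long/short/flanking exon naming, RI the retained-intron naming.
.RMATS_COORD_MAP <- list(
  SE = c(exon_start = "exonStart_0base", exon_end = "exonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  A5SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           upstream_start = "shortES", upstream_end = "shortEE",
           downstream_start = "flankingES", downstream_end = "flankingEE"),
  A3SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           upstream_start = "shortES", upstream_end = "shortEE",
           downstream_start = "flankingES", downstream_end = "flankingEE"),
  RI = c(exon_start = "riExonStart_0base", exon_end = "riExonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"))

.RMATS_FIXED <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncFormLen", "SkipFormLen",
                  "IncLevel1")

#' Compute percent spliced-in from junction counts
#'
#' Length-normalized PSI:
#' \deqn{\psi = \frac{I/l_I}{I/l_I + S/l_S}}
#' where \eqn{I} and \eqn{S} are inclusion and skipping junction reads and
#' \eqn{l_I}, \eqn{l_S} the effective inclusion/skipping form lengths. PSI is
#' `NA` when no junction reads support the event.
#'
#' @param ijc,sjc non-negative inclusion/skipping junction read counts
#'   (vectorized).
#' @param incFormLen,skipFormLen positive effective form lengths.
#' @return Numeric vector of PSI fractions in `[0, 1]`, `NA` where
#'   `ijc + sjc == 0`.
#' @examples
#' computePsi(20, 10, 2, 1)  # 0.5
#' @export
computePsi <- function(ijc, sjc, incFormLen, skipFormLen) {
  if (any(incFormLen <= 0 | skipFormLen <= 0, na.rm = TRUE))
    stop("form lengths must be positive")
  if (any(ijc < 0 | sjc < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  inc <- ijc / incFormLen
  skp <- sjc / skipFormLen
  psi <- inc / (inc + skp)
  psi[ijc + sjc == 0] <- NA_real_
  psi
}

.parseReplicateField <- function(x, label, lines) {
  xc <- as.character(x)
  xc[is.na(xc)] <- "NA"  # read.delim may have eaten a literal NA already
  parts <- strsplit(xc, ",", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    p <- trimws(p)
    p[p %in% c("", "NA")] <- NA
    suppressWarnings(as.numeric(p))
  })
  bad <- vapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    any(!is.na(p) & !(p %in% c("", "NA")) & is.na(vals[[i]]))
  }, logical(1))
  if (any(bad))
    stop(sprintf("non-numeric %s value at line %d", label,
                 lines[which(bad)[1]]))
  vals
}

#' Read an rMATS-style JC event table
#'
#' Parses a tab-delimited rMATS turbo `*.MATS.JC.txt` table into a
#' [SpliceEventTable-class]. PSI is taken from `IncLevel1` when present and
#' recomputed with [computePsi()] otherwise. Comma-separated replicate
#' fields (paired-mode rMATS output) are split per replicate.
#'
#' @param path path to the tab-delimited table.
#' @param spliceType one of `"SE"`, `"A5SS"`, `"A3SS"`, `"RI"`; selects the
#'   coordinate column schema.
#' @param sampleId sample identifier; defaults to the file name stem.
#' @return A [SpliceEventTable-class] when the file carries one replicate, or
#'   a list of them (one per replicate, ids suffixed `_rep<i>`) for
#'   multi-replicate files.
#' @export
readRmatsTable <- function(path, spliceType = "SE",
                           sampleId = sub("\\..*$", "", basename(path))) {
  spliceType <- match.arg(spliceType, names(.RMATS_COORD_MAP))
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  cmap <- .RMATS_COORD_MAP[[spliceType]]
  needed <- c(.RMATS_FIXED, unname(cmap))
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop(sprintf("rMATS format error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  if (!nrow(raw)) {
    ev <- as.data.frame(setNames(
      rep(list(numeric(0)), length(.EVENT_COLUMNS)), .EVENT_COLUMNS))
    ev$gene_id <- character(0); ev$gene_symbol <- character(0)
    ev$chrom <- character(0); ev$strand <- character(0)
    return(SpliceEventTable(sampleId, spliceType, ev))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1

  coords <- lapply(cmap, function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric coordinate in column %s at line %d",
                   col, lines[which(is.na(v))[1]]))
    v
  })
  ijcL <- .parseReplicateField(raw$IJC_SAMPLE_1, "IJC_SAMPLE_1", lines)
  sjcL <- .parseReplicateField(raw$SJC_SAMPLE_1, "SJC_SAMPLE_1", lines)
  psiL <- .parseReplicateField(raw$IncLevel1, "IncLevel1", lines)
  incLen <- suppressWarnings(as.numeric(raw$IncFormLen))
  skpLen <- suppressWarnings(as.numeric(raw$SkipFormLen))
  if (anyNA(incLen) || anyNA(skpLen))
    stop(sprintf("non-numeric form length at line %d",
                 lines[which(is.na(incLen) | is.na(skpLen))[1]]))

  nrep <- max(lengths(ijcL))
  buildRep <- function(r, id) {
    pick <- function(lst) vapply(lst, function(v)
      if (length(v) >= r) v[r] else NA_real_, numeric(1))
    ijc <- pick(ijcL); sjc <- pick(sjcL); psi <- pick(psiL)
    recompute <- is.na(psi)
    psi[recompute] <- computePsi(ijc[recompute], sjc[recompute],
                                 incLen[recompute], skpLen[recompute])
    psi[ijc + sjc == 0] <- NA_real_
    ev <- data.frame(
      gene_id = raw$GeneID, gene_symbol = raw$geneSymbol,
      chrom = raw$chr, strand = raw$strand,
      exon_start = coords$exon_start, exon_end = coords$exon_end,
      upstream_start = coords$upstream_start,
      upstream_end = coords$upstream_end,
      downstream_start = coords$downstream_start,
      downstream_end = coords$downstream_end,
      ijc = ijc, sjc = sjc,
      inc_form_len = incLen, skip_form_len = skpLen,
      psi = psi, stringsAsFactors = FALSE)
    SpliceEventTable(id, spliceType, ev)
  }
  if (nrep == 1L) return(buildRep(1L, sampleId))
  lapply(seq_len(nrep), function(r)
    buildRep(r, paste0(sampleId, "_rep", r)))
}

#' Write a SpliceEventTable as an rMATS-style JC table
#'
#' Inverse of [readRmatsTable()]; IncLevel1 is written at full double
#' precision so PSI round-trips.
#'
#' @param x a [SpliceEventTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRmatsTable <- function(x, path) {
  ev <- eventData(x)
  cmap <- .RMATS_COORD_MAP[[spliceType(x)]]
  out <- data.frame(ID = seq_len(nrow(ev)), GeneID = ev$gene_id,
                    geneSymbol = ev$gene_symbol, chr = ev$chrom,
                    strand = ev$strand, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (g in names(cmap)) out[[cmap[[g]]]] <- ev[[g]]
  out$IJC_SAMPLE_1 <- ev$ijc
  out$SJC_SAMPLE_1 <- ev$sjc
  out$IncFormLen <- ev$inc_form_len
  out$SkipFormLen <- ev$skip_form_len
  out$IncLevel1 <- ifelse(is.na(ev$psi), "NA",
                          formatC(ev$psi, digits = 17, format = "g"))
  writeTsv(out, path)
}

#' Filter events by junction-read support
#'
#' Retains events with `ijc + sjc >= minReads` (default 10 junction reads),
#' preserving row order. Idempotent and monotone in `minReads`.
#'
#' @param x a [SpliceEventTable-class].
#' @param minReads non-negative integer read-support threshold.
#' @return Filtered [SpliceEventTable-class].
#' @export
applyJunctionFilter <- function(x, minReads = 10) {
  stopifnot(minReads >= 0)
  ev <- eventData(x)
  keep <- (ev$ijc + ev$sjc) >= minReads
  SpliceEventTable(sampleId(x), spliceType(x),
                   ev[keep, , drop = FALSE])
}

#' Harmonize per-sample event tables into a cohort PSI matrix
#'
#' Events are keyed by their canonical coordinate tuple (splice type, chrom,
#' strand, exon interval, upstream end, downstream start); gene annotation
#' differences on identical coordinates are reconciled to the first-seen
#' symbol with a warning. Cells are `NA` where a sample lacks the event (or
#' it was removed by the junction filter). Events measured in fewer than
#' `minSampleFraction` of samples are dropped.
#'
#' @param tables list of [SpliceEventTable-class] objects with unique sample
#'   ids and a common splice type.
#' @param minSampleFraction completeness floor in `[0, 1]`; default 0.8.
#' @param clinical optional clinical data.frame (from [readClinical()]) whose
#'   rows matching the sample ids become `colData`.
#' @return A [PsiExperiment-class].
#' @export
buildPsiMatrix <- function(tables, minSampleFraction = 0.8, clinical = NULL) {
  stopifnot(length(tables) >= 1)
  ids <- vapply(tables, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  types <- unique(vapply(tables, spliceType, character(1)))
  if (length(types) != 1)
    stop("all tables must share one splice type")

  evs <- lapply(tables, eventData)
  keys <- lapply(evs, function(e) {
    e$splice_type <- types
    canonicalEventId(e)
  })
  allKeys <- unique(unlist(keys, use.names = FALSE))
  psi <- matrix(NA_real_, length(allKeys), length(ids),
                dimnames = list(allKeys, ids))
  supp <- matrix(NA_real_, length(allKeys), length(ids),
                 dimnames = list(allKeys, ids))
  firstSeen <- rep(NA_integer_, length(allKeys))
  for (j in seq_along(tables)) {
    idx <- match(keys[[j]], allKeys)
    if (anyDuplicated(idx)) {
      dup <- duplicated(idx)
      warning("duplicate event keys within sample ", ids[j],
              "; keeping first occurrence")
      idx <- idx[!dup]
      evs[[j]] <- evs[[j]][!dup, , drop = FALSE]
    }
    psi[idx, j] <- evs[[j]]$psi
    supp[idx, j] <- evs[[j]]$ijc + evs[[j]]$sjc
    new <- is.na(firstSeen[idx])
    firstSeen[idx[new]] <- j
  }
  ## row metadata from the table that first contributed each event
  rowTab <- do.call(rbind, lapply(seq_along(tables), function(j) {
    take <- which(firstSeen[match(keys[[j]], allKeys)] == j &
                    !duplicated(keys[[j]]))
    cbind(evs[[j]][take, c("gene_id", "gene_symbol", "chrom", "strand",
                           "exon_start", "exon_end", "upstream_start",
                           "upstream_end", "downstream_start",
                           "downstream_end"), drop = FALSE],
          key = keys[[j]][take])
  }))
  rowTab <- rowTab[match(allKeys, rowTab$key), , drop = FALSE]
  ## flag gene-annotation drift on identical coordinates
  for (j in seq_along(tables)) {
    idx <- match(keys[[j]], allKeys)
    clash <- evs[[j]]$gene_symbol != rowTab$gene_symbol[idx]
    if (any(clash, na.rm = TRUE))
      warning(sprintf(
        "sample %s: %d event(s) with conflicting gene symbols reconciled to first-seen",
        ids[j], sum(clash, na.rm = TRUE)))
  }

  measuredFrac <- rowMeans(!is.na(psi))
  keep <- measuredFrac >= minSampleFraction
  dropped <- sum(!keep)
  psi <- psi[keep, , drop = FALSE]
  supp <- supp[keep, , drop = FALSE]
  rowTab <- rowTab[keep, , drop = FALSE]

  cd <- NULL
  if (!is.null(clinical)) {
    cd <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    rownames(cd) <- ids
    cd <- S4Vectors::DataFrame(cd)
  }
  rd <- S4Vectors::DataFrame(rowTab[setdiff(names(rowTab), "key")],
                             row.names = rowTab$key)
  PsiExperiment(psi, supp, rowData = rd, colData = cd,
                metadata = list(splice_type = types,
                                min_sample_fraction = minSampleFraction,
                                events_dropped_incomplete = dropped))
}

#' Read a clinical annotation table
#'
#' Expects a TSV with at least `sample_id`; recognized optional columns are
#' histology, molecular_subtype, age_at_diagnosis, resection, os_days,
#' os_status, efs_days, efs_status, tmb. Unknown histology strings are kept
#' verbatim.
#'
#' @param path TSV path.
#' @return data.frame with typed columns and attribute `has_tmb`.
#' @export
readClinical <- function(path) {
  df <- readTsv(path)
  if (!"sample_id" %in% names(df))
    stop("clinical table must contain a sample_id column")
  num <- intersect(c("age_at_diagnosis", "os_days", "efs_days", "tmb"),
                   names(df))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in intersect(c("os_days", "efs_days"), names(df)))
    if (any(df[[cn]] < 0, na.rm = TRUE))
      stop("negative survival time in column ", cn)
  for (cn in intersect(c("os_status", "efs_status"), names(df))) {
    df[[cn]] <- as.integer(df[[cn]])
    if (any(!df[[cn]] %in% c(0L, 1L), na.rm = TRUE))
      stop("status column ", cn, " must be 0/1")
  }
  attr(df, "has_tmb") <- "tmb" %in% names(df)
  df
}

#' Read a gene-by-sample expression matrix (TPM) from TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path TSV path.
#' @return numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
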