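#' Load transcript models from a GTF file
#'
#' Parses exon and CDS features (1-based inclusive GTF coordinates) via
#' `rtracklayer` and converts them to the package-internal 0-based half-open
#' convention. Models whose CDS falls outside the exon union, or whose CDS
#' length is not divisible by three, are flagged (`valid`, `frame_ok`) but
#' not dropped.
#'
#' @param path GTF path.
#' @return Named list (by transcript_id) of transcript models: transcript_id,
#'   gene_id, gene_symbol, protein_id, chrom, strand, `exons` and `cds`
#'   (matrices of 0-based half-open intervals, genomic ascending), exon
#'   intervals also in transcript orientation (`exons_tx`), `cds_len`, and
#'   the validity flags. Attribute `gene_index` maps gene_id to transcript
#'   ids.
#' @export
loadTranscriptModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  txIds <- as.character(md$transcript_id)
  models <- lapply(split(seq_along(gr), txIds), function(ii) {
    sub <- gr[ii]; sm <- md[ii, , drop = FALSE]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    toMat <- function(sel) {
      s <- GenomicRanges::start(sub[sel]) - 1L  # 1-based -> 0-based
      e <- GenomicRanges::end(sub[sel])         # inclusive end == half-open end
      o <- order(s)
      cbind(start = s[o], end = e[o])
    }
    exons <- toMat(sm$type == "exon")
    cds <- toMat(sm$type == "CDS")
    txOrd <- if (strand == "-") rev(seq_len(nrow(exons))) else
      seq_len(nrow(exons))
    cdsInExons <- !nrow(cds) || all(vapply(seq_len(nrow(cds)), function(i)
      any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2]), logical(1)))
    cdsLen <- if (nrow(cds)) sum(cds[, 2] - cds[, 1]) else 0L
    pid <- if (!is.null(sm$protein_id) && !is.na(sm$protein_id[1]))
      as.character(sm$protein_id[1]) else paste0(txIds[ii[1]], "_prot")
    sym <- if (!is.null(sm$gene_name) && !is.na(sm$gene_name[1]))
      as.character(sm$gene_name[1]) else as.character(sm$gene_id[1])
    list(transcript_id = txIds[ii[1]],
         gene_id = as.character(sm$gene_id[1]),
         gene_symbol = sym,
         protein_id = pid,
         chrom = as.character(GenomicRanges::seqnames(sub))[1],
         strand = strand,
         exons = exons, exons_tx = exons[txOrd, , drop = FALSE],
         cds = cds, cds_len = cdsLen,
         valid = cdsInExons && nrow(cds) > 0,
         frame_ok = cdsLen %% 3 == 0)
  })
  geneIndex <- split(names(models),
                     vapply(models, `[[`, character(1), "gene_id"))
  attr(models, "gene_index") <- geneIndex
  models
}

#' Map a genomic interval to protein residue coordinates
#'
#' Projects the CDS-overlapping part of a 0-based half-open genomic interval
#' onto 1-based protein residues of a transcript model: a CDS base at
#' transcript-orientation coding offset `o` (0-based) belongs to residue
#' `floor(o / 3) + 1`. Returns `NULL` when the interval does not intersect
#' the CDS (pure UTR or intron).
#'
#' @param tm one transcript model from [loadTranscriptModels()].
#' @param start,end 0-based half-open genomic interval on `tm$chrom`.
#' @return Integer `c(first_res, last_res)` or `NULL`.
#' @export
genomicToProtein <- function(tm, start, end) {
  stopifnot(start < end, start >= 0)
  cds <- tm$cds
  if (!nrow(cds)) return(NULL)
  if (end > 5e8) stop("interval beyond chromosome model")
  txOrd <- if (tm$strand == "-") rev(seq_len(nrow(cds))) else
    seq_len(nrow(cds))
  cum <- 0L
  lo <- Inf; hi <- -Inf
  for (i in txOrd) {
    bs <- cds[i, 1]; be <- cds[i, 2]
    os <- max(start, bs); oe <- min(end, be)
    if (os < oe) {
      if (tm$strand == "+") {
        lo <- min(lo, cum + (os - bs))
        hi <- max(hi, cum + (oe - 1L - bs))
      } else {
        lo <- min(lo, cum + (be - oe))
        hi <- max(hi, cum + (be - 1L - os))
      }
    }
    cum <- cum + (be - bs)
  }
  if (!is.finite(lo)) return(NULL)
  c(first_res = as.integer(lo %/% 3L + 1L),
    last_res = as.integer(hi %/% 3L + 1L))
}

#' Normalize protein feature type labels
#'
#' Maps UniProt-style feature keys onto the four reported categories
#' (domain, disulfide_bond, modified_residue, localization_signal) plus
#' `other`.
#'
#' @param x character vector of raw feature type labels.
#' @return character vector of normalized categories.
#' @export
normalizeFeatureType <- function(x) {
  key <- tolower(gsub("[ -]", "_", trimws(x)))
  map <- c(domain = "domain", region = "domain", repeat_ = "domain",
           zn_finger = "domain", dna_bind = "domain",
           disulfid = "disulfide_bond", disulfide_bond = "disulfide_bond",
           mod_res = "modified_residue", modified_residue = "modified_residue",
           carbohyd = "modified_residue", lipid = "modified_residue",
           crosslnk = "modified_residue",
           signal = "localization_signal", transit = "localization_signal",
           signal_peptide = "localization_signal",
           transit_peptide = "localization_signal",
           localization_signal = "localization_signal")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Annotate splice events with protein functional-site overlaps
#'
#' Maps each cassette (skipped) exon onto protein residues for every
#' transcript of its gene whose CDS overlaps the exon, intersects the
#' residue span with protein features (closed intervals; overlap means
#' sharing at least one residue), and classifies the event by its call
#' direction: `gain` for inclusion gains hitting a feature, `loss` for
#' skipping, `mixed` for mixed-direction events, `none` without hits. The
#' event-level annotation is the union of hits over transcripts.
#'
#' @param events data.frame with event_id, gene_id, chrom, strand,
#'   exon_start, exon_end (0-based half-open), direction.
#' @param models transcript models from [loadTranscriptModels()].
#' @param features data.frame with protein_id, feature_type, start_res,
#'   end_res, description (1-based inclusive residues).
#' @return list with `byEvent` (event_id, gene_id, direction,
#'   frame_preserving, n_transcripts, n_hits, functional, impact),
#'   `byTranscript` (per event x transcript residue spans), `hits`
#'   (per-feature overlaps), and `featureTypeCounts` (`per_hit` and
#'   `per_event` tables over normalized feature types).
#' @export
annotateEvents <- function(events, models, features) {
  features$feature_type <- normalizeFeatureType(features$feature_type)
  stopifnot(all(features$start_res >= 1),
            all(features$start_res <= features$end_res))
  geneIndex <- attr(models, "gene_index")
  byTx <- list(); hits <- list(); byEv <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    txs <- geneIndex[[as.character(ev$gene_id)]]
    framePres <- (ev$exon_end - ev$exon_start) %% 3 == 0
    nHits <- 0L; nTx <- 0L; evTypes <- character(0)
    if (is.null(txs)) {
      message("gene without transcript model: ", ev$gene_id)
    } else {
      for (tx in sort(txs)) {
        tm <- models[[tx]]
        if (!tm$valid || tm$chrom != ev$chrom) next
        span <- genomicToProtein(tm, ev$exon_start, ev$exon_end)
        if (is.null(span)) next
        nTx <- nTx + 1L
        byTx[[length(byTx) + 1L]] <- data.frame(
          event_id = ev$event_id, transcript_id = tx,
          protein_id = tm$protein_id,
          first_res = span[1], last_res = span[2],
          frame_preserving = framePres, stringsAsFactors = FALSE)
        ft <- features[features$protein_id == tm$protein_id &
                         features$start_res <= span[2] &
                         features$end_res >= span[1], , drop = FALSE]
        if (nrow(ft)) {
          ft$overlap_residues <- pmin(ft$end_res, span[2]) -
            pmax(ft$start_res, span[1]) + 1L
          ft$event_id <- ev$event_id
          ft$transcript_id <- tx
          hits[[length(hits) + 1L]] <- ft
          nHits <- nHits + nrow(ft)
          evTypes <- union(evTypes, ft$feature_type)
        }
      }
    }
    impact <- if (nHits == 0L) "none"
      else switch(as.character(ev$direction),
                  inclusion_gain = "gain", skipping = "loss",
                  mixed = "mixed", "none")
    byEv[[length(byEv) + 1L]] <- data.frame(
      event_id = ev$event_id, gene_id = ev$gene_id,
      gene_symbol = if ("gene_symbol" %in% names(ev)) ev$gene_symbol
                    else NA_character_,
      direction = ev$direction, frame_preserving = framePres,
      n_transcripts = nTx, n_hits = nHits,
      functional = nHits > 0L, impact = impact,
      feature_types = paste(sort(evTypes), collapse = ","),
      stringsAsFactors = FALSE)
  }
  byEvent <- do.call(rbind, byEv)
  hitsDf <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(0), feature_type = character(0),
               start_res = integer(0), end_res = integer(0),
               description = character(0), overlap_residues = integer(0),
               event_id = character(0), transcript_id = character(0))
  perHit <- table(hitsDf$feature_type)
  perEvent <- table(unlist(lapply(
    strsplit(byEvent$feature_types[byEvent$functional], ","), unique)))
  list(byEvent = byEvent,
       byTranscript = if (length(byTx)) do.call(rbind, byTx) else NULL,
       hits = hitsDf,
       featureTypeCounts = list(per_hit = perHit, per_event = perEvent))
}

#' Restrict functional annotations to kinases
#'
#' Two nested subsets of the event-level annotations: events in kinase genes
#' and, within those, events in kinases with a known splicing-regulatory
#' role.
#'
#' @param annotations result of [annotateEvents()] or its `byEvent`
#'   data.frame.
#' @param kinaseGenes nonempty character vector of kinase gene symbols.
#' @param splicingRegulatorKinases optional character vector (typically a
#'   subset of `kinaseGenes`).
#' @return list with `kinase` and `splicing_regulator` data.frames.
#' @export
filterKinases <- function(annotations, kinaseGenes,
                          splicingRegulatorKinases = NULL) {
  if (!length(kinaseGenes)) stop("empty kinase gene list")
  be <- if (is.list(annotations) && !is.data.frame(annotations))
    annotations$byEvent else annotations
  sym <- ifelse(is.na(be$gene_symbol), be$gene_id, be$gene_symbol)
  kin <- be[sym %in% kinaseGenes, , drop = FALSE]
  spl <- if (is.null(splicingRegulatorKinases)) NULL else {
    symk <- ifelse(is.na(kin$gene_symbol), kin$gene_id, kin$gene_symbol)
    kin[symk %in% splicingRegulatorKinases, , drop = FALSE]
  }
  list(kinase = kin, splicing_regulator = spl)
}
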