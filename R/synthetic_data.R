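#' Specification for a synthetic splicing cohort
#'
#' Collects the generative parameters for [simulateCohort()]: cohort and
#' event counts, cluster structure, per-sample aberrant fractions, the
#' expression-burden coupling for designated splicing-factor genes, and a
#' proportional-hazards survival model. The defaults describe a mid-sized
#' cohort with moderate event noise (PSI SD 0.05), well-separated clusters,
#' and 100x junction-read depth.
#'
#' @param nSamples number of samples.
#' @param nEvents named integer vector of events per splice type.
#' @param nClusters number of planted clusters.
#' @param withinSd within-cluster PSI standard deviation.
#' @param informativeFraction fraction of events carrying cluster signal.
#' @param clusterSeparation cluster-center offset in units of `withinSd`.
#' @param aberrantFraction per-sample fraction of aberrant events (scalar
#'   or length-`nSamples` vector, values in `[0, 1]`).
#' @param aberrantShift aberrant-event PSI shift in units of `withinSd`.
#' @param histologyAccuracy probability that a sample's histology label
#'   matches its cluster's dominant histology.
#' @param nSfGenes,nBgGenes numbers of splicing-factor-like (burden-coupled)
#'   and background genes in the TPM matrix.
#' @param sfIntercept,sfSlope,exprNoiseSd linear expression-burden coupling
#'   `TPM = a + b * f_i + noise` for the splicing-factor genes.
#' @param lambda0 baseline exponential hazard (per day).
#' @param betaCluster log-hazard per cluster (`NULL`: evenly spaced in
#'   `[-0.5, 0.5]`).
#' @param betaF log-hazard coefficient on the aberrant fraction.
#' @param censorFraction target fraction of censored samples.
#' @param depth junction-read depth used to back-compute counts.
#' @param missingRate fraction of cells rendered unmeasured (zero support).
#' @param seed integer seed; fully determines the output.
#' @return A validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(nSamples = 120, nEvents = c(SE = 2000),
                       nClusters = 4, withinSd = 0.05,
                       informativeFraction = 0.2, clusterSeparation = 4,
                       aberrantFraction = 0.05, aberrantShift = 3,
                       histologyAccuracy = 0.8,
                       nSfGenes = 10, nBgGenes = 90,
                       sfIntercept = 10, sfSlope = 50, exprNoiseSd = 1,
                       lambda0 = 1 / 1000, betaCluster = NULL, betaF = 2,
                       censorFraction = 0.3, depth = 100,
                       missingRate = 0, seed = 1) {
  f <- rep_len(aberrantFraction, nSamples)
  if (any(f < 0 | f > 1)) stop("aberrant fractions must lie in [0, 1]")
  if (missingRate < 0 || missingRate >= 1) stop("invalid missingRate")
  if (censorFraction < 0 || censorFraction >= 1)
    stop("invalid censorFraction")
  if (is.null(names(nEvents))) names(nEvents) <- "SE"
  if (is.null(betaCluster))
    betaCluster <- if (nClusters > 1)
      seq(-0.5, 0.5, length.out = nClusters) else 0
  stopifnot(length(betaCluster) == nClusters, depth >= 10, withinSd > 0)
  structure(list(
    nSamples = nSamples, nEvents = nEvents, nClusters = nClusters,
    withinSd = withinSd, informativeFraction = informativeFraction,
    clusterSeparation = clusterSeparation, aberrantFraction = f,
    aberrantShift = aberrantShift, histologyAccuracy = histologyAccuracy,
    nSfGenes = nSfGenes, nBgGenes = nBgGenes, sfIntercept = sfIntercept,
    sfSlope = sfSlope, exprNoiseSd = exprNoiseSd, lambda0 = lambda0,
    betaCluster = betaCluster, betaF = betaF,
    censorFraction = censorFraction, depth = depth,
    missingRate = missingRate, seed = as.integer(seed)),
    class = "CohortSpec")
}

.eventCoordTemplate <- function(nE, type, prefix = "EV") {
  s0 <- seq(10000L, by = 2000L, length.out = nE)
  data.frame(
    gene_id = sprintf("G%s%05d", type, seq_len(nE)),
    gene_symbol = sprintf("G%s%05d", type, seq_len(nE)),
    chrom = paste0("chr", (seq_len(nE) - 1L) %% 22L + 1L),
    strand = rep(c("+", "-"), length.out = nE),
    upstream_start = s0, upstream_end = s0 + 150L,
    exon_start = s0 + 350L, exon_end = s0 + 440L,
    downstream_start = s0 + 640L, downstream_end = s0 + 790L,
    stringsAsFactors = FALSE)
}

.psiToCounts <- function(psi, depth, incLen = 2, skipLen = 1) {
  q <- psi * incLen / (psi * incLen + (1 - psi) * skipLen)
  ijc <- round(depth * q)
  list(ijc = ijc, sjc = depth - ijc)
}

#' Simulate an rMATS-style splicing cohort with known ground truth
#'
#' Draws per-sample PSI around cluster centers (clipped Gaussian noise),
#' plants aberrant events shifted by `aberrantShift` within-cluster SDs for
#' each sample's aberrant fraction, back-computes junction counts from PSI
#' at the specified read depth (so the recomputed PSI matches the drawn PSI
#' to within `1/depth`), and generates a matching clinical table
#' (cluster-conditional histology labels, proportional-hazards OS/EFS with
#' exponential baseline) and TPM matrix whose splicing-factor genes track
#' the sample's aberrant fraction linearly.
#'
#' @param spec a [cohortSpec()].
#' @param outDir optional directory; when given, per-sample rMATS JC files,
#'   `clinical.tsv`, `tpm.tsv`, `genesets.gmt`, and `truth.json` are
#'   written there.
#' @return list with `tables` (per splice type, list of
#'   [SpliceEventTable-class]), `clinical`, `tpm`, `geneSets`, and `truth`
#'   (cluster, aberrant fraction and event indices per sample, centers,
#'   survival coefficients).
#' @export
simulateCohort <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  k <- spec$nClusters
  cl <- sample(rep_len(seq_len(k), n))
  f <- spec$aberrantFraction

  tables <- list(); truthEvents <- list(); centersOut <- list()
  for (type in names(spec$nEvents)) {
    nE <- spec$nEvents[[type]]
    coords <- .eventCoordTemplate(nE, type)
    ## baseline support keeps >= 4 within-cluster SDs of margin from the
    ## PSI boundaries at the default withinSd so boundary clipping stays
    ## negligible and shift sizes remain controlled in SD units
    baseline <- 0.2 + 0.6 * rbeta(nE, 2, 2)
    informative <- if (k > 1) runif(nE) < spec$informativeFraction
                   else rep(FALSE, nE)
    centers <- matrix(baseline, nE, k)
    if (any(informative)) {
      off <- matrix(sample(c(-1, 1), sum(informative) * k, replace = TRUE),
                    ncol = k) * spec$clusterSeparation * spec$withinSd
      centers[informative, ] <- clip01(centers[informative, ] + off)
    }
    psi <- centers[, cl, drop = FALSE] +
      matrix(rnorm(nE * n, 0, spec$withinSd), nE, n)
    aberrant <- vector("list", n)
    for (j in seq_len(n)) {
      nab <- round(f[j] * nE)
      if (nab > 0) {
        idx <- sample.int(nE, nab)
        psi[idx, j] <- psi[idx, j] +
          sample(c(-1, 1), nab, replace = TRUE) *
          spec$aberrantShift * spec$withinSd
        aberrant[[j]] <- sort(idx)
      } else aberrant[[j]] <- integer(0)
    }
    psi <- clip01(psi)
    measured <- matrix(TRUE, nE, n)
    if (spec$missingRate > 0)
      measured[matrix(runif(nE * n) < spec$missingRate, nE, n)] <- FALSE

    cnt <- .psiToCounts(psi, spec$depth)
    typeTables <- lapply(seq_len(n), function(j) {
      ijc <- ifelse(measured[, j], cnt$ijc[, j], 0)
      sjc <- ifelse(measured[, j], cnt$sjc[, j], 0)
      ev <- coords
      ev$ijc <- as.integer(ijc)
      ev$sjc <- as.integer(sjc)
      ev$inc_form_len <- 2L
      ev$skip_form_len <- 1L
      ev$psi <- computePsi(ijc, sjc, 2, 1)
      SpliceEventTable(ids[j], type, ev)
    })
    tables[[type]] <- typeTables
    truthEvents[[type]] <- list(baseline = baseline,
                                informative = informative,
                                aberrant = setNames(aberrant, ids),
                                drawn_psi = psi)
    centersOut[[type]] <- centers
  }

  ## clinical table: cluster-conditional histology, PH survival
  hist <- paste0("HIST", cl)
  flip <- runif(n) >= spec$histologyAccuracy
  if (k > 1 && any(flip))
    hist[flip] <- paste0("HIST", vapply(cl[flip], function(c0)
      sample(setdiff(seq_len(k), c0), 1), integer(1)))
  rate <- spec$lambda0 * exp(spec$betaCluster[cl] + spec$betaF * f)
  tOs <- rexp(n, rate)
  cOs <- rexp(n, rate * spec$censorFraction / (1 - spec$censorFraction))
  rateE <- rate * 1.5
  tEfs <- rexp(n, rateE)
  cEfs <- rexp(n, rateE * spec$censorFraction / (1 - spec$censorFraction))
  clinical <- data.frame(
    sample_id = ids, histology = hist,
    molecular_subtype = paste0("SUB", cl),
    age_at_diagnosis = round(runif(n, 1, 18), 2),
    resection = sample(c("gross_total", "partial"), n, replace = TRUE,
                       prob = c(0.6, 0.4)),
    os_days = pmax(1, ceiling(pmin(tOs, cOs))),
    os_status = as.integer(tOs <= cOs),
    efs_days = pmax(1, ceiling(pmin(tEfs, cEfs))),
    efs_status = as.integer(tEfs <= cEfs),
    tmb = round(rlnorm(n, log(2), 0.8), 3),
    stringsAsFactors = FALSE)

  ## TPM: splicing-factor genes linearly coupled to the aberrant fraction
  sfGenes <- sprintf("SF%02d", seq_len(spec$nSfGenes))
  bgGenes <- sprintf("BG%03d", seq_len(spec$nBgGenes))
  sf <- matrix(spec$sfIntercept + spec$sfSlope * rep(f, each = spec$nSfGenes) +
                 rnorm(spec$nSfGenes * n, 0, spec$exprNoiseSd),
               spec$nSfGenes, n)
  bgMu <- rlnorm(spec$nBgGenes, log(5), 1)
  bg <- matrix(rlnorm(spec$nBgGenes * n, log(rep(bgMu, n)), 0.3),
               spec$nBgGenes, n)
  tpm <- pmax(rbind(sf, bg), 0.01)
  dimnames(tpm) <- list(c(sfGenes, bgGenes), ids)
  geneSets <- list(SPLICING_FACTORS = sfGenes,
                   BACKGROUND_A = bgGenes[seq_len(min(25, spec$nBgGenes))])

  truth <- list(cluster = setNames(cl, ids), aberrant_fraction = setNames(f, ids),
                events = truthEvents, centers = centersOut,
                beta_cluster = spec$betaCluster, beta_f = spec$betaF,
                histology = setNames(hist, ids))
  out <- list(tables = tables, clinical = clinical, tpm = tpm,
              geneSets = geneSets, truth = truth, spec = spec)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (type in names(tables))
      for (tb in tables[[type]])
        writeRmatsTable(tb, file.path(
          outDir, sprintf("%s.%s.MATS.JC.txt", sampleId(tb), type)))
    writeTsv(clinical, file.path(outDir, "clinical.tsv"))
    writeTsv(cbind(gene_id = rownames(tpm), as.data.frame(tpm)),
             file.path(outDir, "tpm.tsv"))
    writeGmt(geneSets, file.path(outDir, "genesets.gmt"))
    jsonlite::write_json(
      list(cluster = truth$cluster, aberrant_fraction = truth$aberrant_fraction,
           beta_cluster = truth$beta_cluster, beta_f = truth$beta_f),
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
    out$dir <- outDir
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene symbol vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(s)
    paste(c(s, "synthetic", sets[[s]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a paired two-arm perturbation design
#'
#' Plants `nDs` events with arm-B PSI shifted by `trueDpsi` (clipped to
#' `[0, 1]` with a warning when the shift leaves the unit interval);
#' replicate junction counts are binomial draws at the given depth.
#' Optionally simulates a gene-count matrix with `nDe` differentially
#' expressed genes for the expression arm of the comparison.
#'
#' @param nEvents number of splice events.
#' @param nDs number of truly differential events (first `nDs` event ids).
#' @param trueDpsi planted PSI shift in arm B.
#' @param repsPerArm replicates per arm (default 3).
#' @param depth junction read depth.
#' @param withinSd replicate-level PSI noise SD.
#' @param nGenes,nDe,lfc optional gene-count simulation (negative binomial,
#'   `nDe` genes at log2 fold change `lfc`).
#' @param seed integer seed.
#' @param outDir optional directory for per-replicate rMATS JC files.
#' @return list with `psiA`, `psiB` (recomputed from counts), `tablesA`,
#'   `tablesB`, optional `countsA`/`countsB`, and `truth` (ds event ids, de
#'   gene ids).
#' @export
simulatePerturbation <- function(nEvents = 500, nDs = 50, trueDpsi = 0.4,
                                 repsPerArm = 3, depth = 100,
                                 withinSd = 0.02, nGenes = 0, nDe = 0,
                                 lfc = 1, seed = 1, outDir = NULL) {
  stopifnot(nDs <= nEvents)
  set.seed(seed)
  coords <- .eventCoordTemplate(nEvents, "SE", "PV")
  base <- runif(nEvents, 0.15, 0.85)
  ## leave headroom for the planted shift on differential events
  if (nDs > 0 && abs(trueDpsi) < 0.9) {
    lo <- max(0.05, 0.05 - trueDpsi)
    hi <- min(0.95, 0.95 - trueDpsi)
    base[seq_len(nDs)] <- runif(nDs, lo, hi)
  }
  shiftVec <- c(rep(trueDpsi, nDs), rep(0, nEvents - nDs))
  centerB <- base + shiftVec
  if (any(centerB < 0 | centerB > 1)) {
    warning("planted shift leaves [0, 1]; clipped")
    centerB <- clip01(centerB)
  }
  evIds <- canonicalEventId(cbind(coords, splice_type = "SE"))
  drawArm <- function(center, armLabel) {
    psi <- matrix(NA_real_, nEvents, repsPerArm,
                  dimnames = list(evIds, paste0(armLabel, seq_len(repsPerArm))))
    tabs <- vector("list", repsPerArm)
    for (r in seq_len(repsPerArm)) {
      p <- clip01(center + rnorm(nEvents, 0, withinSd))
      q <- p * 2 / (p * 2 + (1 - p))
      ijc <- rbinom(nEvents, depth, q)
      sjc <- depth - ijc
      ev <- coords
      ev$ijc <- ijc; ev$sjc <- sjc
      ev$inc_form_len <- 2L; ev$skip_form_len <- 1L
      ev$psi <- computePsi(ijc, sjc, 2, 1)
      psi[, r] <- ev$psi
      tabs[[r]] <- SpliceEventTable(paste0(armLabel, r), "SE", ev)
    }
    list(psi = psi, tabs = tabs)
  }
  a <- drawArm(base, "ctrl_")
  b <- drawArm(centerB, "treat_")
  out <- list(psiA = a$psi, psiB = b$psi, tablesA = a$tabs, tablesB = b$tabs,
              truth = list(ds_events = evIds[seq_len(nDs)],
                           true_dpsi = trueDpsi))
  if (nGenes > 0) {
    genes <- sprintf("PG%04d", seq_len(nGenes))
    mu <- rlnorm(nGenes, log(200), 1)
    fcSign <- sample(c(-1, 1), nDe, replace = TRUE)
    fc <- rep(1, nGenes)
    if (nDe > 0) fc[seq_len(nDe)] <- 2^(lfc * fcSign)
    draw <- function(mus) matrix(
      rnbinom(nGenes * repsPerArm, mu = rep(mus, repsPerArm), size = 10),
      nGenes, repsPerArm, dimnames = list(genes, NULL))
    out$countsA <- draw(mu)
    out$countsB <- draw(mu * fc)
    colnames(out$countsA) <- paste0("ctrl_", seq_len(repsPerArm))
    colnames(out$countsB) <- paste0("treat_", seq_len(repsPerArm))
    out$truth$de_genes <- genes[seq_len(nDe)]
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (tb in c(a$tabs, b$tabs))
      writeRmatsTable(tb, file.path(outDir, paste0(sampleId(tb),
                                                   ".SE.MATS.JC.txt")))
    out$dir <- outDir
  }
  out
}

#' Simulate toy transcript models, protein features, and cassette events
#'
#' Generates random multi-exon transcripts on both strands with a CDS,
#' writes them as a GTF plus a protein-feature TSV, and records the exact
#' expected residue span and feature overlaps of one cassette exon per
#' transcript. The recorded truth is built by a per-base walk over the CDS
#' in transcript orientation (each coding base is assigned its residue
#' directly), independently of the arithmetic interval mapping in
#' [genomicToProtein()].
#'
#' @param nTranscripts number of transcripts.
#' @param seed integer seed.
#' @param outDir directory for `models.gtf` and `features.tsv` (a temporary
#'   directory when `NULL`).
#' @return list with `gtf` and `features` paths, `featureTable`, `events`
#'   (cassette-event table with direction), and `truth` (per event:
#'   first/last residue or NA, expected hit count and feature types,
#'   expected impact).
#' @export
simulateAnnotation <- function(nTranscripts = 20, seed = 1, outDir = NULL) {
  set.seed(seed)
  if (is.null(outDir)) outDir <- tempfile("synthann")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gtf <- character(0); featRows <- list(); evRows <- list(); trRows <- list()
  featTypes <- c("DOMAIN", "DISULFID", "MOD_RES", "SIGNAL", "HELIX")
  for (i in seq_len(nTranscripts)) {
    chrom <- paste0("chrS", i)
    strand <- sample(c("+", "-"), 1)
    nEx <- sample(3:6, 1)
    lens <- sample(30:180, nEx, replace = TRUE)
    gaps <- sample(50:300, nEx - 1, replace = TRUE)
    starts <- cumsum(c(sample(1000:5000, 1), lens[-nEx] + gaps))
    ends <- starts + lens  # 0-based half-open
    ## transcript-orientation base walk
    blockBases <- lapply(seq_len(nEx), function(e) starts[e]:(ends[e] - 1L))
    txBases <- if (strand == "+") unlist(blockBases)
               else unlist(lapply(rev(blockBases), rev))
    total <- length(txBases)
    utr5 <- sample(0:20, 1); utr3 <- sample(0:20, 1)
    cdsLen <- 3L * ((total - utr5 - utr3) %/% 3L)
    if (cdsLen < 30L) { utr5 <- 0L; utr3 <- 0L; cdsLen <- 3L * (total %/% 3L) }
    cdsBases <- txBases[(utr5 + 1L):(utr5 + cdsLen)]
    resOf <- rep(seq_len(cdsLen %/% 3L), each = 3L)
    names(resOf) <- as.character(cdsBases)
    P <- cdsLen %/% 3L
    ## genomic CDS blocks from the sorted coding bases
    sb <- sort(cdsBases)
    brk <- c(0L, which(diff(sb) > 1L), length(sb))
    gid <- paste0("GS", i); tid <- paste0("TS", i); pid <- paste0("PS", i)
    attrStr <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; protein_id "%s";',
      gid, tid, gid, pid)
    for (e in seq_len(nEx))
      gtf <- c(gtf, paste(chrom, "synth", "exon", starts[e] + 1L, ends[e],
                          ".", strand, ".", attrStr, sep = "\t"))
    for (bi in seq_len(length(brk) - 1L)) {
      seg <- sb[(brk[bi] + 1L):brk[bi + 1L]]
      gtf <- c(gtf, paste(chrom, "synth", "CDS", seg[1] + 1L,
                          seg[length(seg)] + 1L, ".", strand, ".", attrStr,
                          sep = "\t"))
    }
    ## protein features at known residues
    nf <- sample(1:3, 1)
    for (fi in seq_len(nf)) {
      sr <- sample.int(P, 1)
      er <- min(P, sr + sample(0:25, 1))
      featRows[[length(featRows) + 1L]] <- data.frame(
        protein_id = pid, feature_type = sample(featTypes, 1),
        start_res = sr, end_res = er,
        description = sprintf("feat_%d_%d", i, fi),
        stringsAsFactors = FALSE)
    }
    ## cassette event on one internal exon
    j <- if (nEx == 3L) 2L else sample(2:(nEx - 1L), 1)
    exBases <- blockBases[[j]]
    hitRes <- resOf[as.character(intersect(exBases, cdsBases))]
    direction <- sample(c("skipping", "inclusion_gain"), 1)
    evId <- sprintf("SE|%s|%s|%d|%d|%d|%d", chrom, strand, starts[j],
                    ends[j], ends[j - 1L], starts[j + 1L])
    evRows[[length(evRows) + 1L]] <- data.frame(
      event_id = evId, gene_id = gid, gene_symbol = gid, chrom = chrom,
      strand = strand, exon_start = starts[j], exon_end = ends[j],
      upstream_start = starts[j - 1L], upstream_end = ends[j - 1L],
      downstream_start = starts[j + 1L], downstream_end = ends[j + 1L],
      direction = direction, stringsAsFactors = FALSE)
    span <- if (length(hitRes)) range(hitRes) else c(NA_integer_, NA_integer_)
    myFeat <- do.call(rbind, featRows)
    myFeat <- myFeat[myFeat$protein_id == pid, , drop = FALSE]
    nHits <- if (length(hitRes))
      sum(myFeat$start_res <= span[2] & myFeat$end_res >= span[1]) else 0L
    trRows[[length(trRows) + 1L]] <- data.frame(
      event_id = evId, transcript_id = tid,
      first_res = span[1], last_res = span[2], n_hits = nHits,
      impact = if (nHits == 0L) "none"
               else if (direction == "skipping") "loss" else "gain",
      frame_preserving = (ends[j] - starts[j]) %% 3 == 0,
      stringsAsFactors = FALSE)
  }
  gtfPath <- file.path(outDir, "models.gtf")
  writeLines(gtf, gtfPath)
  featureTable <- do.call(rbind, featRows)
  featPath <- file.path(outDir, "features.tsv")
  writeTsv(featureTable, featPath)
  list(gtf = gtfPath, features = featPath, featureTable = featureTable,
       events = do.call(rbind, evRows), truth = do.call(rbind, trRows))
}

#' Simulate proportional-hazards survival data with a known hazard ratio
#'
#' Balanced binary exposure, exponential baseline hazard, and exponential
#' censoring calibrated to the target censoring fraction; used for
#' parameter-recovery checks of the Cox fit.
#'
#' @param n number of samples.
#' @param hr true hazard ratio of the exposed group.
#' @param baselineRate exponential baseline hazard (per day).
#' @param censorFraction target censoring fraction.
#' @param seed integer seed.
#' @return data.frame with time, status, group (0/1 exposure).
#' @export
simulateSurvival <- function(n = 600, hr = 2, baselineRate = 1 / 365,
                             censorFraction = 0.3, seed = 1) {
  set.seed(seed)
  g <- rep_len(c(0, 1), n)
  rate <- baselineRate * hr^g
  tt <- rexp(n, rate)
  cc <- rexp(n, rate * censorFraction / (1 - censorFraction))
  data.frame(time = pmin(tt, cc), status = as.integer(tt <= cc), group = g)
}
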