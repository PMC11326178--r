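#' Paired-replicate differential splicing by permutation
#'
#' For each event, the difference of arm means
#' \eqn{\Delta PSI = \bar\psi_B - \bar\psi_A} is tested against the
#' label-permutation distribution of the absolute mean difference:
#' exhaustively over all arm relabelings when their number is at most
#' `maxExact` (so a 3-vs-3 design has exactly C(6,3) = 20 relabelings and
#' p-value granularity 1/20), Monte-Carlo with a fixed seed otherwise.
#' P-values are BH-adjusted across events; an event is called when
#' `|delta_psi| >= dpsiMin` and `fdr < fdrMax`.
#'
#' @param psiA,psiB events-by-replicates PSI matrices with matching
#'   rownames (event ids).
#' @param dpsiMin minimum absolute delta-PSI for a call (default 0.1).
#' @param fdrMax FDR ceiling for a call (default 0.05).
#' @param maxExact largest number of relabelings enumerated exhaustively.
#' @param nMc Monte-Carlo permutations when exhaustive enumeration is too
#'   large.
#' @param seed seed for Monte-Carlo permutations.
#' @return data.frame with event_id, delta_psi, p, fdr, called, exact.
#' @export
pairedDeltaPsi <- function(psiA, psiB, dpsiMin = 0.1, fdrMax = 0.05,
                           maxExact = 10000, nMc = 2000, seed = 1) {
  stopifnot(identical(rownames(psiA), rownames(psiB)))
  nA <- ncol(psiA); nB <- ncol(psiB)
  n <- nA + nB
  exact <- choose(n, nA) <= maxExact
  if (exact) {
    splits <- combn(n, nA)  # columns: indices assigned to arm A
  } else set.seed(seed)
  res <- lapply(rownames(psiA), function(e) {
    a <- psiA[e, ]; b <- psiB[e, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    delta <- mean(b) - mean(a)
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(event_id = e, delta_psi = delta, p = NA_real_,
                        stringsAsFactors = FALSE))
    pool <- c(a, b)
    obs <- abs(delta)
    if (exact) {
      stats <- apply(splits, 2, function(idx)
        abs(mean(pool[-idx]) - mean(pool[idx])))
      p <- mean(stats >= obs - 1e-12)
    } else {
      stats <- replicate(nMc, {
        idx <- sample.int(length(pool), length(a))
        abs(mean(pool[-idx]) - mean(pool[idx]))
      })
      p <- (1 + sum(stats >= obs - 1e-12)) / (1 + nMc)
    }
    data.frame(event_id = e, delta_psi = delta, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- p.adjust(out$p[ok], method = "BH")
  out$called <- !is.na(out$fdr) & out$fdr < fdrMax &
    abs(out$delta_psi) >= dpsiMin
  out$exact <- exact
  rownames(out) <- NULL
  out
}

#' Gene-level differential expression between two arms
#'
#' Delegates to edgeR quasi-likelihood fits on raw counts; this package owns
#' only the thresholds and the downstream set logic.
#'
#' @param counts genes-by-samples integer count matrix.
#' @param condition factor/character of arm labels per column (2 levels).
#' @param lfcMin minimum absolute log2 fold change for a call (default 0).
#' @param padjMax FDR ceiling for a call (default 0.05).
#' @return data.frame with gene, log2fc, p, fdr, called.
#' @export
differentialExpression <- function(counts, condition, lfcMin = 0,
                                   padjMax = 0.05) {
  condition <- factor(condition)
  stopifnot(nlevels(condition) == 2, ncol(counts) == length(condition))
  dge <- edgeR::DGEList(counts = counts, group = condition)
  keep <- edgeR::filterByExpr(dge)
  dge <- dge[keep, , keep.lib.sizes = FALSE]
  dge <- edgeR::calcNormFactors(dge)
  design <- model.matrix(~condition)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmQLFit(dge, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  tab <- edgeR::topTags(qlf, n = Inf, sort.by = "none")$table
  data.frame(gene = rownames(tab), log2fc = tab$logFC, p = tab$PValue,
             fdr = tab$FDR,
             called = tab$FDR < padjMax & abs(tab$logFC) >= lfcMin,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-way set overlap (Venn decomposition)
#'
#' Exact membership decomposition of differentially spliced (DS),
#' differentially expressed (DE), and dependency (DG) gene sets into the
#' seven exclusive regions, with percentages relative to the union.
#'
#' @param dsGenes,deGenes,dgGenes character vectors of gene symbols
#'   (`dgGenes` may be empty for a two-set decomposition).
#' @return list with `counts` (named integer, regions `ds_only` ...
#'   `ds_de_dg`), `union_size`, and `percent` of the union.
#' @export
overlapSets <- function(dsGenes, deGenes, dgGenes = character(0)) {
  ds <- unique(dsGenes); de <- unique(deGenes); dg <- unique(dgGenes)
  u <- union(union(ds, de), dg)
  inDs <- u %in% ds; inDe <- u %in% de; inDg <- u %in% dg
  counts <- c(
    ds_only = sum(inDs & !inDe & !inDg),
    de_only = sum(!inDs & inDe & !inDg),
    dg_only = sum(!inDs & !inDe & inDg),
    ds_de = sum(inDs & inDe & !inDg),
    ds_dg = sum(inDs & !inDe & inDg),
    de_dg = sum(!inDs & inDe & inDg),
    ds_de_dg = sum(inDs & inDe & inDg))
  list(counts = counts, union_size = length(u),
       percent = if (length(u)) round(100 * counts / length(u), 4)
                 else counts)
}

#' Pathway over-representation by hypergeometric test
#'
#' Upper-tail hypergeometric p-value per gene set for a query gene list
#' against a universe, with Bonferroni adjustment across sets.
#'
#' @param genes query gene set (must be contained in `universe`).
#' @param universe background gene universe.
#' @param sets named list of gene sets.
#' @param adjust p.adjust method (default `"bonferroni"`).
#' @return data.frame with set, k (query hits), K (set size in universe),
#'   n (query size), N (universe size), p, p_adj.
#' @export
overrepresentation <- function(genes, universe, sets,
                               adjust = "bonferroni") {
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe))
    stop("query genes must be a subset of the universe")
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(sets), function(s) {
    set <- intersect(unique(sets[[s]]), universe)
    if (!length(set)) {
      warning("gene set with no genes in universe skipped: ", s)
      return(NULL)
    }
    K <- length(set)
    k <- length(intersect(genes, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Filter CRISPR dependency scores
#'
#' Genes passing both a Wald FDR ceiling and a strict dependency z-score
#' threshold (`z < zMax`, matching the printed `z-score < -1.5` convention)
#' in at least one cell line.
#'
#' @param scores data.frame with gene, cell line, z-score, and FDR columns.
#' @param zCol,fdrCol,geneCol,lineCol column names.
#' @param zMax dependency z ceiling, strict (default -1.5).
#' @param fdrMax FDR ceiling, strict (default 0.05).
#' @return list with `per_line` (named list of gene vectors) and
#'   `any_line` (character vector).
#' @export
dependencyFilter <- function(scores, zCol = "z", fdrCol = "fdr",
                             geneCol = "gene", lineCol = "line",
                             zMax = -1.5, fdrMax = 0.05) {
  need <- c(zCol, fdrCol, geneCol, lineCol)
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  pass <- scores[[zCol]] < zMax & scores[[fdrCol]] < fdrMax
  pass[is.na(pass)] <- FALSE
  hit <- scores[pass, , drop = FALSE]
  perLine <- lapply(split(hit[[geneCol]], hit[[lineCol]]), unique)
  list(per_line = perLine,
       any_line = sort(unique(hit[[geneCol]])))
}
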