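#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways`.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

.ssScoreOneSample <- function(x, setsIdx, alpha) {
  n <- length(x)
  rAsc <- rank(x, ties.method = "average")     # high expression -> high rank
  ord <- order(-x, names(x))                   # descending, ties by name
  w <- rAsc^alpha
  vapply(setsIdx, function(idx) {
    if (!length(idx)) return(NA_real_)
    inSet <- logical(n); inSet[idx] <- TRUE
    inSetOrd <- inSet[ord]
    nS <- sum(inSetOrd)
    if (nS == n) return(NA_real_)
    wOrd <- w[ord]
    step <- ifelse(inSetOrd, wOrd / sum(wOrd[inSetOrd]), -1 / (n - nS))
    sum(cumsum(step))
  }, numeric(1))
}

#' Single-sample gene-set activity scores
#'
#' Rank-based running-sum statistic per sample and gene set: genes are
#' walked in decreasing expression order; in-set genes increment the running
#' sum proportionally to their expression rank raised to `alpha` (weights
#' normalized to 1 over the set), out-of-set genes decrement it by
#' `1/(N - |S|)`; the score is the sum of the running-sum values (integral
#' form). With `alpha = 0` in-set increments are uniform and the walk is a
#' Kolmogorov-Smirnov-type running sum. Scores depend on ranks only, so any
#' strictly monotone transform of a sample's expression leaves them
#' unchanged.
#'
#' @param expr genes-by-samples numeric matrix with rownames.
#' @param sets named list of gene symbol vectors (or a single vector).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize optional cohort-level min-max normalization per set.
#' @return sets-by-samples numeric matrix with parameters in
#'   `attr(, "params")`.
#' @export
singleSampleScore <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  if (!is.list(sets)) sets <- list(set = sets)
  stopifnot(nrow(expr) >= 2, !is.null(rownames(expr)))
  setsIdx <- lapply(sets, function(g) {
    idx <- match(unique(g), rownames(expr))
    hit <- idx[!is.na(idx)]
    if (!length(hit))
      warning("gene set with no genes in the expression matrix")
    else if (length(hit) < length(unique(g)))
      warning(length(unique(g)) - length(hit),
              " gene(s) of a set absent from the expression matrix")
    hit
  })
  out <- vapply(seq_len(ncol(expr)), function(j)
    .ssScoreOneSample(setNames(expr[, j], rownames(expr)), setsIdx, alpha),
    numeric(length(sets)))
  out <- matrix(out, nrow = length(sets),
                dimnames = list(names(sets), colnames(expr)))
  if (normalize) {
    rng <- apply(out, 1, range, na.rm = TRUE)
    out <- (out - rng[1, ]) / (rng[2, ] - rng[1, ])
  }
  attr(out, "params") <- list(alpha = alpha, normalize = normalize)
  out
}

#' Compare gene-set scores between groups
#'
#' One-vs-rest two-sided Welch t-test per gene set and group, adjusted
#' across all tests (Bonferroni by default). The primary effect size is the
#' mean difference; a secondary log2 ratio is computed on positively shifted
#' scores (all scores shifted by `1 - min(score)` so ratios are defined).
#'
#' @param scores sets-by-samples matrix from [singleSampleScore()].
#' @param groups named vector mapping samples to groups.
#' @param adjust p.adjust method (default `"bonferroni"`).
#' @return data.frame with gene_set, group, n_group, mean_diff,
#'   log2FC_shifted, p, p_adj.
#' @export
compareScores <- function(scores, groups, adjust = "bonferroni") {
  groups <- groups[colnames(scores)]
  shift <- 1 - min(scores, na.rm = TRUE)
  rows <- list()
  for (s in rownames(scores)) {
    for (g in sort(unique(as.character(groups)))) {
      inG <- groups == g
      x <- scores[s, inG]; y <- scores[s, !inG]
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
        warning("group with <2 samples skipped: ", g)
        next
      }
      tt <- t.test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = s, group = g, n_group = sum(inG),
        mean_diff = mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE),
        log2FC_shifted = log2((mean(x, na.rm = TRUE) + shift) /
                                (mean(y, na.rm = TRUE) + shift)),
        p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Correlate pathway scores with protein abundance
#'
#' Pearson correlation, on the shared-sample intersection, between a
#' pathway's single-sample score and the per-sample mean abundance of the
#' pathway's proteins (pairwise-complete).
#'
#' @param scores sets-by-samples score matrix.
#' @param abundance proteins-by-samples abundance matrix.
#' @param pathwayGenes character vector of the pathway's gene/protein
#'   symbols.
#' @param set which score row to use (default the first).
#' @return list with `r`, `p`, `n`.
#' @export
correlateScoreWithAbundance <- function(scores, abundance, pathwayGenes,
                                        set = rownames(scores)[1]) {
  shared <- intersect(colnames(scores), colnames(abundance))
  genes <- intersect(pathwayGenes, rownames(abundance))
  if (!length(genes)) stop("no pathway genes in the abundance matrix")
  ab <- colMeans(abundance[genes, shared, drop = FALSE], na.rm = TRUE)
  sc <- scores[set, shared]
  ok <- !is.na(ab) & !is.na(sc)
  if (sum(ok) < 3) stop("fewer than 3 shared samples")
  ct <- cor.test(sc[ok], ab[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
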