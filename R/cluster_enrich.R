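#' Select the most variable events
#'
#' Ranks events by PSI variance over non-missing values and keeps the top
#' `kEvents` (default 5000, the usual cut for variable-event clustering).
#' Variance ties are broken by event-key lexicographic order so the
#' selection is deterministic and invariant to sample order.
#'
#' @param x a [PsiExperiment-class] or numeric matrix.
#' @param kEvents number of events to keep.
#' @return Object of the same class restricted to the selected rows,
#'   ordered by decreasing variance.
#' @export
selectVariableEvents <- function(x, kEvents = 5000) {
  m <- if (is(x, "PsiExperiment")) psiValues(x) else as.matrix(x)
  v <- rowSdsNA(m)^2
  v[is.na(v)] <- -Inf
  if (kEvents > nrow(m)) {
    warning("kEvents (", kEvents, ") exceeds available events (", nrow(m),
            "); keeping all")
    kEvents <- nrow(m)
  }
  ord <- order(-v, rownames(m))
  keep <- ord[seq_len(kEvents)]
  if (is(x, "PsiExperiment")) x[keep, ] else m[keep, , drop = FALSE]
}

#' Hierarchical clustering of samples on PSI values
#'
#' Missing cells are imputed (event mean by default), samples are clustered
#' agglomeratively (Ward on Euclidean distances by default) and the tree cut
#' into `k` clusters. When `k` is `NULL`, k in `kRange` maximizing the mean
#' silhouette width is chosen and the profile is returned.
#'
#' @param x a [PsiExperiment-class] or events-by-samples matrix.
#' @param k number of clusters, or `NULL` to pick by silhouette.
#' @param linkage `"ward"` (Ward.D2), `"complete"`, `"average"`, or
#'   `"single"`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param impute `"event_mean"` or `"zero"`.
#' @param kRange candidate k values when `k` is `NULL`.
#' @return list with `cluster` (named integer vector, ids contiguous from 1
#'   in dendrogram order), `k`, `tree` (hclust), the parameters, and
#'   `silhouette_profile` when k was chosen automatically.
#' @export
hierarchicalCluster <- function(x, k = NULL,
                                linkage = c("ward", "complete", "average",
                                            "single"),
                                metric = c("euclidean", "manhattan"),
                                impute = c("event_mean", "zero"),
                                kRange = 2:15) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  impute <- match.arg(impute)
  m <- if (is(x, "PsiExperiment")) psiValues(x) else as.matrix(x)
  if (impute == "event_mean") {
    mu <- rowMeansNA(m)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 1]]
  } else m[is.na(m)] <- 0
  ## order samples lexicographically before distance computation so the
  ## partition is invariant to input column order
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  d <- dist(t(m), method = metric)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(d, method = method)
  sil <- NULL
  if (is.null(k)) {
    kRange <- kRange[kRange >= 2 & kRange < ncol(m)]
    width <- vapply(kRange, function(kk) {
      cl <- cutree(tree, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    sil <- data.frame(k = kRange, mean_silhouette = width)
    k <- kRange[which.max(width)]
  }
  if (k > ncol(m)) stop("k exceeds the number of samples")
  cl <- cutree(tree, k = k)
  ## relabel so cluster ids are contiguous in order of first appearance in
  ## the dendrogram leaf order (deterministic, input-order independent)
  leafOrder <- tree$order
  first <- unique(cl[leafOrder])
  cl <- setNames(match(cl, first), names(cl))
  ## report in the caller's column order
  if (is(x, "PsiExperiment")) cl <- cl[colnames(psiValues(x))]
  else cl <- cl[colnames(as.matrix(x))]
  list(cluster = cl, k = k, tree = tree, linkage = linkage,
       metric = metric, impute = impute, silhouette_profile = sil)
}

## Exact hypergeometric probability of a 2x2 table from binomial
## coefficients; shared by the enrichment oracle tests.
.table2x2Prob <- function(a, b, c, d) {
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(a + b + c + d, a + c))
}

#' Cluster-label enrichment by Fisher's exact test
#'
#' For every (cluster, label) pair the 2x2 in-cluster x has-label table is
#' tested with a two-sided Fisher exact test. The reported odds ratio is the
#' sample cross-product ratio `(a*d)/(b*c)`; when any cell is zero a 0.5
#' Haldane-Anscombe correction is applied and flagged.
#'
#' @param assign cluster fit from [hierarchicalCluster()] or a named
#'   cluster vector.
#' @param labels named vector mapping every clustered sample to a label.
#' @param adjust multiplicity adjustment across all tests
#'   (default `"BH"`).
#' @return data.frame with cluster_id, label, a, b, c, d, odds_ratio,
#'   haldane, p, p_adj.
#' @export
clusterEnrichment <- function(assign, labels, adjust = "BH") {
  cl <- if (is.list(assign)) assign$cluster else assign
  miss <- setdiff(names(cl), names(labels))
  if (length(miss)) stop("labels missing for samples: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  labels <- labels[names(cl)]
  empty <- setdiff(unique(labels), labels)
  rows <- list()
  for (k in sort(unique(cl))) {
    for (lab in sort(unique(as.character(labels)))) {
      inC <- cl == k
      hasL <- labels == lab
      if (!any(hasL)) { warning("label with zero samples skipped: ", lab)
                        next }
      a <- sum(inC & hasL); b <- sum(inC & !hasL)
      c <- sum(!inC & hasL); d <- sum(!inC & !hasL)
      haldane <- any(c(a, b, c, d) == 0)
      or <- if (haldane) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
            else (a * d) / (b * c)
      p <- fisher.test(matrix(c(a, c, b, d), 2), alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = k, label = lab, a = a, b = b, c = c, d = d,
        odds_ratio = or, haldane = haldane, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
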