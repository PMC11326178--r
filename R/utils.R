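#' @importFrom stats median na.omit p.adjust pchisq phyper pnorm quantile
#'   rbeta rbinom rexp rlnorm rnorm runif sd setNames var cor cor.test
#'   fisher.test wilcox.test t.test rank dist hclust cutree as.formula
#'   model.matrix
#' @importFrom utils read.delim write.table combn packageVersion
NULL

## Canonical event identifier used to harmonize events across samples.
## Deliberately excludes gene identifiers so annotation-version drift on
## identical coordinates cannot split an event.
canonicalEventId <- function(df) {
  paste(df$splice_type, df$chrom, df$strand,
        df$exon_start, df$exon_end,
        df$upstream_end, df$downstream_start, sep = "|")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # keep x's attributes (dims)

#' Derive a child seed from a root seed
#'
#' All stochastic stages draw their seed from a single root seed so that a
#' pipeline run is reproducible end to end while stages stay decoupled.
#'
#' @param rootSeed integer root seed.
#' @param offset integer stage offset.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(rootSeed, offset = 0L) {
  s <- (as.numeric(rootSeed) * 48271 + 1009 * as.numeric(offset)) %%
    (.Machine$integer.max - 1)
  as.integer(s) + 1L
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

## Row-wise mean/sd over non-missing cells without apply() overhead.
rowMeansNA <- function(m) {
  n <- rowSums(!is.na(m))
  s <- rowSums(m, na.rm = TRUE)
  ifelse(n > 0, s / n, NA_real_)
}

rowSdsNA <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeansNA(m)
  ss <- rowSums(m^2, na.rm = TRUE)
  v <- (ss - n * mu^2) / (n - 1)
  v[n < 2] <- NA_real_
  sqrt(pmax(v, 0))
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to compare recovered clusters with planted truth.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return Numeric ARI in `[-1, 1]`; 1 means identical partitions up to
#'   relabeling.
#' @export
adjustedRand <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(x), 2)
  expected <- sumi * sumj / n2
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
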