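## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

## Per-base walk: assign every CDS base (transcript orientation) its residue,
## then read off the residue range of an arbitrary genomic interval.
perBaseResidueSpan <- function(tm, start, end) {
  cds <- tm$cds
  if (!nrow(cds)) return(NULL)
  blocks <- lapply(seq_len(nrow(cds)), function(i) cds[i, 1]:(cds[i, 2] - 1L))
  bases <- if (tm$strand == "+") unlist(blocks)
           else unlist(lapply(rev(blocks), rev))
  res <- (seq_along(bases) - 1L) %/% 3L + 1L
  hit <- res[bases >= start & bases < end]
  if (!length(hit)) return(NULL)
  c(first_res = min(hit), last_res = max(hit))
}

## Exact hypergeometric probability of one 2x2 table via binomial
## coefficients (no dhyper).
tableProb <- function(a, b, c, d) {
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(a + b + c + d, a + c))
}

## Two-sided Fisher p by enumerating all tables with the observed margins:
## sum the probabilities of tables no more probable than the observed one
## (the standard relative tolerance guards ties in floating point).
fisherTwoSidedOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  pObs <- tableProb(a, b, c, d)
  ps <- vapply(amin:amax, function(x)
    tableProb(x, r1 - x, c1 - x, n - r1 - c1 + x), numeric(1))
  sum(ps[ps <= pObs * (1 + 1e-7)])
}

## Upper-tail hypergeometric p via direct summation of the PMF.
hyperUpperOracle <- function(k, K, n, N) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  sum(vapply(k:kmax, function(x)
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)), numeric(1)))
}

## Step-up BH oracle by direct brute force of the definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  ## enforce monotonicity from the largest down
  for (i in rev(seq_len(m)))
    adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Exhaustive two-sample permutation p of |mean(B) - mean(A)| by direct
## enumeration of arm-A index sets.
permPOracle <- function(a, b) {
  pool <- c(a, b)
  nA <- length(a)
  idxSets <- combn(length(pool), nA)
  obs <- abs(mean(b) - mean(a))
  stats <- apply(idxSets, 2, function(i) abs(mean(pool[-i]) - mean(pool[i])))
  mean(stats >= obs - 1e-12)
}

## Minimal event data.frame for SpliceEventTable fixtures.
makeEvents <- function(n, ijc, sjc, psi = NULL, incLen = 2L, skipLen = 1L) {
  s0 <- seq(1000L, by = 1000L, length.out = n)
  df <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_symbol = sprintf("G%03d", seq_len(n)),
    chrom = "chr1", strand = "+",
    exon_start = s0 + 200L, exon_end = s0 + 300L,
    upstream_start = s0, upstream_end = s0 + 100L,
    downstream_start = s0 + 400L, downstream_end = s0 + 500L,
    ijc = ijc, sjc = sjc, inc_form_len = incLen, skip_form_len = skipLen,
    stringsAsFactors = FALSE)
  df$psi <- if (is.null(psi)) computePsi(ijc, sjc, incLen, skipLen) else psi
  df
}
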