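#' Per-event cohort z-scores of PSI
#'
#' Standardizes each sample's PSI against the event's cohort distribution:
#' \eqn{z = (\psi - \bar\psi_{event}) / s_{event}}, using the non-missing
#' cohort values of that event. By default the focal sample is included in
#' the moments (no matched-normal design is assumed); `leaveOneOut = TRUE`
#' excludes it. Events with fewer than three measured samples or cohort
#' standard deviation below `sdFloor` are non-informative and return an
#' all-missing row.
#'
#' @param x a [PsiExperiment-class] or numeric events-by-samples matrix.
#' @param sdFloor minimum cohort SD for an event to be informative
#'   (default 0.01; z-scores explode as the SD approaches zero).
#' @param leaveOneOut logical; exclude the focal sample from the moments.
#' @return Numeric z-score matrix with the input's dimnames.
#' @export
eventZScores <- function(x, sdFloor = 0.01, leaveOneOut = FALSE) {
  m <- if (is(x, "PsiExperiment")) psiValues(x) else as.matrix(x)
  n <- rowSums(!is.na(m))
  mu <- rowMeansNA(m)
  sdv <- rowSdsNA(m)
  if (!leaveOneOut) {
    z <- (m - mu) / sdv
  } else {
    ## leave-one-out moments from full-sample sufficient statistics
    s1 <- rowSums(m, na.rm = TRUE)
    s2 <- rowSums(m^2, na.rm = TRUE)
    muL <- (s1 - m) / (n - 1)
    varL <- (s2 - m^2 - (n - 1) * muL^2) / (n - 2)
    z <- (m - muL) / sqrt(pmax(varL, 0))
  }
  bad <- n < 3 | is.na(sdv) | sdv < sdFloor
  z[bad, ] <- NA_real_
  z[is.na(m)] <- NA_real_
  z
}

#' Call per-sample differential splice events
#'
#' Sign-aware calls from the cohort z-score matrix using a strict threshold
#' (the `|z| > 2` convention): `inclusion_gain` when `z > threshold`,
#' `skipping` when `z < -threshold`, otherwise `none`; `NA` where PSI was
#' missing or the event non-informative.
#'
#' @param z z-score matrix from [eventZScores()].
#' @param threshold positive z threshold (default 2).
#' @return Character matrix of calls with the same dimnames.
#' @export
callDifferential <- function(z, threshold = 2) {
  stopifnot(threshold > 0)
  calls <- matrix(NA_character_, nrow(z), ncol(z), dimnames = dimnames(z))
  calls[!is.na(z)] <- "none"
  calls[!is.na(z) & z > threshold] <- "inclusion_gain"
  calls[!is.na(z) & z < -threshold] <- "skipping"
  calls
}

#' Splicing Burden Index per sample
#'
#' The SBI is the proportion of a sample's measured events called
#' differential against the cohort distribution:
#' \eqn{SBI_i = n_{differential,i} / n_{measured,i}}. Samples are stratified
#' against the cohort SBI quartiles: `high` at or above Q3, `low` at or
#' below Q1 (boundary ties included in the stratum), `mid` otherwise.
#'
#' @param calls call matrix from [callDifferential()].
#' @param spliceType splice type label carried into the output.
#' @param denominator `"measured"` (default; per-sample measured events) or
#'   `"universe"` (all events in the matrix).
#' @return data.frame with columns sample_id, splice_type, n_differential,
#'   n_measured, sbi, stratum.
#' @export
splicingBurdenIndex <- function(calls, spliceType = "SE",
                                denominator = c("measured", "universe")) {
  denominator <- match.arg(denominator)
  nDiff <- colSums(calls == "inclusion_gain" | calls == "skipping",
                   na.rm = TRUE)
  nMeas <- if (denominator == "measured") colSums(!is.na(calls))
           else rep(nrow(calls), ncol(calls))
  sbi <- ifelse(nMeas > 0, nDiff / nMeas, NA_real_)
  if (any(nMeas == 0))
    warning(sum(nMeas == 0), " sample(s) with no measured events; SBI missing")
  q <- quantile(sbi, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  stratum <- ifelse(is.na(sbi), NA_character_,
                    ifelse(sbi >= q[2], "high",
                           ifelse(sbi <= q[1], "low", "mid")))
  data.frame(sample_id = colnames(calls), splice_type = spliceType,
             n_differential = as.integer(nDiff),
             n_measured = as.integer(nMeas),
             sbi = sbi, stratum = stratum,
             row.names = NULL, stringsAsFactors = FALSE)
}
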