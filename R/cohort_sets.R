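#' Recurrent differential splice events within groups
#'
#' For each group (histology or cluster), events with at least `minN`
#' differential calls among the group's samples. The event direction is
#' `inclusion_gain` or `skipping` when all supporting samples agree, and
#' `mixed` when both signs occur.
#'
#' @param calls call matrix from [callDifferential()].
#' @param groups named character vector mapping every sample (column) to a
#'   group label.
#' @param minN minimum number of supporting samples (default 2, the
#'   recurrence convention).
#' @return data.frame with columns group, event_id, direction,
#'   n_supporting.
#' @export
recurrentEvents <- function(calls, groups, minN = 2) {
  unknown <- setdiff(colnames(calls), names(groups))
  if (length(unknown))
    stop("samples without a group label: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  groups <- groups[colnames(calls)]
  out <- lapply(split(colnames(calls), groups), function(smp) {
    sub <- calls[, smp, drop = FALSE]
    nGain <- rowSums(sub == "inclusion_gain", na.rm = TRUE)
    nSkip <- rowSums(sub == "skipping", na.rm = TRUE)
    nSup <- nGain + nSkip
    keep <- nSup >= minN
    if (!any(keep)) return(NULL)
    data.frame(event_id = rownames(sub)[keep],
               direction = ifelse(nGain[keep] > 0 & nSkip[keep] > 0, "mixed",
                                  ifelse(nGain[keep] > 0, "inclusion_gain",
                                         "skipping")),
               n_supporting = as.integer(nSup[keep]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(group = character(0), event_id = character(0),
                      direction = character(0), n_supporting = integer(0)))
  cbind(group = rep(names(out), vapply(out, nrow, integer(1))),
        do.call(rbind, out), stringsAsFactors = FALSE)
}

#' Decompose group event sets into shared and group-specific parts
#'
#' Exact set-intersection (UpSet-style) decomposition of the recurrent event
#' sets: a boolean membership matrix, the count of every non-empty
#' membership pattern, and the per-group unique (in that group only) counts.
#'
#' @param recurrent data.frame from [recurrentEvents()] (needs >= 2 groups).
#' @return list with `membership` (event x group logical matrix),
#'   `pattern_counts` (data.frame of pattern and n), and `unique_counts`
#'   (named integer per group).
#' @export
groupSetDecomposition <- function(recurrent) {
  grps <- sort(unique(recurrent$group))
  if (length(grps) < 2) stop("need at least 2 groups")
  evs <- sort(unique(recurrent$event_id))
  membership <- matrix(FALSE, length(evs), length(grps),
                       dimnames = list(evs, grps))
  membership[cbind(match(recurrent$event_id, evs),
                   match(recurrent$group, grps))] <- TRUE
  pattern <- apply(membership, 1, function(r)
    paste(grps[r], collapse = "&"))
  pc <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(pc) <- c("pattern", "n")
  pc <- pc[order(-pc$n, pc$pattern), , drop = FALSE]
  rownames(pc) <- NULL
  uniq <- vapply(grps, function(g)
    sum(membership[, g] & rowSums(membership) == 1L), integer(1))
  list(membership = membership, pattern_counts = pc, unique_counts = uniq)
}

#' Group-specific event counts normalized per patient
#'
#' Unique (group-specific) recurrent event counts divided by the number of
#' patients in the group, reported to six decimals and ordered by decreasing
#' total unique events.
#'
#' @param recurrent data.frame from [recurrentEvents()].
#' @param nPatients named integer vector of patients per group (all > 0).
#' @return data.frame with group, n_unique, n_patients, events_per_patient.
#' @export
perPatientNormalizedCounts <- function(recurrent, nPatients) {
  dec <- groupSetDecomposition(recurrent)
  grps <- names(dec$unique_counts)
  miss <- setdiff(grps, names(nPatients))
  if (length(miss)) stop("missing patient counts for: ",
                         paste(miss, collapse = ", "))
  np <- nPatients[grps]
  if (any(np <= 0)) stop("n_patients must be > 0")
  out <- data.frame(group = grps,
                    n_unique = as.integer(dec$unique_counts),
                    n_patients = as.integer(np),
                    events_per_patient =
                      round(dec$unique_counts / np, 6),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_unique, out$group), , drop = FALSE]
}
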