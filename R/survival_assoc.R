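#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group and a two-sided log-rank
#' p-value. With an all-censored input the curves are still returned and the
#' p-value is `NA` with `p_defined = FALSE`.
#'
#' @param data data.frame with time, status (0/1) and a grouping column.
#' @param groupCol name of the grouping column.
#' @param timeCol,statusCol column names (defaults `"time"`, `"status"`).
#' @return list with `fit` (a `survfit`), `p`, `p_defined`, `chisq`.
#' @export
kmLogrank <- function(data, groupCol, timeCol = "time",
                      statusCol = "status") {
  stopifnot(all(c(groupCol, timeCol, statusCol) %in% names(data)))
  df <- data.frame(time = data[[timeCol]], status = data[[statusCol]],
                   group = factor(data[[groupCol]]))
  if (nlevels(df$group) < 2) stop("need at least 2 groups")
  fit <- survfit(Surv(time, status) ~ group, data = df)
  if (sum(df$status) == 0)
    return(list(fit = fit, p = NA_real_, p_defined = FALSE,
                chisq = NA_real_))
  sd <- survdiff(Surv(time, status) ~ group, data = df)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  list(fit = fit, p = p, p_defined = TRUE, chisq = unname(sd$chisq))
}

.hazardTable <- function(fit, data) {
  s <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  out <- data.frame(term = rownames(s),
                    hazard_ratio = unname(s[, "exp(coef)"]),
                    ci_low = unname(ci[, "lower .95"]),
                    ci_high = unname(ci[, "upper .95"]),
                    p = unname(s[, "Pr(>|z|)"]),
                    is_reference = FALSE, stringsAsFactors = FALSE)
  ## reference rows for factor covariates (rendered as gray diamonds in
  ## forest plots)
  xl <- fit$xlevels
  if (length(xl)) {
    ref <- data.frame(term = paste0(names(xl),
                                    vapply(xl, `[`, character(1), 1),
                                    " (reference)"),
                      hazard_ratio = 1, ci_low = 1, ci_high = 1,
                      p = NA_real_, is_reference = TRUE,
                      stringsAsFactors = FALSE)
    out <- rbind(ref, out)
  }
  rownames(out) <- NULL
  attr(out, "n") <- fit$n
  attr(out, "nevent") <- fit$nevent
  out
}

#' Cox proportional-hazards fit with hazard table output
#'
#' Partial-likelihood PH fit (Efron tie handling) over the requested
#' covariates and optional interaction pairs. Character covariates are
#' treated as factors with the first (alphabetical) level as the explicit
#' reference, for which a reference row is emitted.
#'
#' @param data data.frame with time, status and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param interactions optional list of 2-element character vectors naming
#'   interaction pairs (also added as main effects if absent).
#' @param timeCol,statusCol column names.
#' @return data.frame hazard table (term, hazard_ratio, ci_low, ci_high, p,
#'   is_reference) with attributes `n`, `nevent`, `converged`,
#'   `separation_flag`, and the fit in `attr(, "fit")`.
#' @export
coxFit <- function(data, covariates, interactions = NULL,
                   timeCol = "time", statusCol = "status") {
  stopifnot(all(c(timeCol, statusCol, covariates) %in% names(data)))
  df <- data
  df$.time <- df[[timeCol]]; df$.status <- df[[statusCol]]
  for (cv in covariates)
    if (is.character(df[[cv]]) || is.logical(df[[cv]]))
      df[[cv]] <- factor(df[[cv]])
  for (cv in covariates) {
    v <- df[[cv]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2) ||
        (is.numeric(v) && var(v, na.rm = TRUE) == 0))
      stop("covariate constant within the risk set: ", cv)
  }
  terms <- covariates
  if (!is.null(interactions))
    terms <- c(terms, vapply(interactions, paste, character(1),
                             collapse = ":"))
  fml <- as.formula(paste("Surv(.time, .status) ~",
                          paste(terms, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = "efron",
          control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("did not converge|Ran out of iterations", warns))
  if (!converged)
    stop("Cox fit did not converge after ", fit$iter, " iterations: ",
         paste(warns, collapse = "; "))
  separation <- any(is.na(coef(fit))) ||
    any(abs(coef(fit)) > 15, na.rm = TRUE) ||
    any(grepl("infinite", warns))
  out <- .hazardTable(fit, df)
  attr(out, "converged") <- converged
  attr(out, "separation_flag") <- separation
  attr(out, "fit") <- fit
  out
}

#' Quartile-stratified Cox model
#'
#' Discretizes a score by its cohort quartiles (boundary ties assigned to
#' the lower stratum) and fits a Cox model on the quartile factor with the
#' lowest quartile (Q1) as reference, so the Q4 row is the highest-versus-
#' lowest comparison.
#'
#' @param data data.frame with time, status, and the score column.
#' @param scoreCol numeric score column name.
#' @param timeCol,statusCol column names.
#' @return Hazard table as in [coxFit()], with `attr(, "breaks")`.
#' @export
quartileModel <- function(data, scoreCol, timeCol = "time",
                          statusCol = "status") {
  stopifnot(scoreCol %in% names(data))
  x <- data[[scoreCol]]
  if (sum(!is.na(x)) < 8) stop("need at least 8 samples")
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  if (anyDuplicated(q))
    stop("tied quartile boundaries collapse strata at ",
         q[duplicated(q)][1])
  grp <- cut(x, breaks = c(-Inf, q, Inf), labels = paste0("Q", 1:4),
             right = TRUE)  # right-closed: boundary ties fall in the lower stratum
  df <- data
  df$.quartile <- grp
  out <- coxFit(df, ".quartile", timeCol = timeCol, statusCol = statusCol)
  out$term <- sub("^\\.quartile", "quartile ", out$term)
  attr(out, "breaks") <- q
  out
}

#' Per-gene correlation of an expression panel with a sample statistic
#'
#' Correlates every row of a genes-by-samples matrix with a per-sample
#' vector (for example SBI), on pairwise-complete observations, with BH FDR
#' across the panel. Zero-variance genes are excluded from the FDR and
#' reported with `NA` correlation.
#'
#' @param x genes-by-samples numeric matrix.
#' @param y named per-sample vector (matched to `colnames(x)`).
#' @param method `"pearson"` or `"spearman"`.
#' @param adjust p.adjust method across the panel (default `"BH"`).
#' @param log2Transform apply `log2(v + pseudocount)` to both sides before
#'   correlating.
#' @param pseudocount used by `log2Transform` (default 1).
#' @return data.frame with gene, r, p, fdr, n.
#' @export
correlatePanel <- function(x, y, method = c("pearson", "spearman"),
                           adjust = "BH", log2Transform = FALSE,
                           pseudocount = 1) {
  method <- match.arg(method)
  if (!is.null(names(y))) y <- y[colnames(x)]
  stopifnot(length(y) == ncol(x))
  if (log2Transform) {
    x <- log2(x + pseudocount)
    y <- log2(y + pseudocount)
  }
  res <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    ok <- !is.na(v) & !is.na(y)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(v[ok], y[ok], method = method))
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- p.adjust(out$p[ok], method = adjust)
  if (any(!ok)) message(sum(!ok), " gene(s) excluded from FDR ",
                        "(zero variance or <3 pairs)")
  out
}

#' Compare PSI between ordered groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests (BH-adjusted) between groups
#' ordered by an ordinal factor (for example age categories), with group
#' medians and a Spearman monotone-trend summary of PSI against the group
#' order.
#'
#' @param psi numeric per-sample PSI vector.
#' @param groups factor (ordered by level) of the same length; each level
#'   needs at least 3 samples.
#' @return list with `pairwise` (group1, group2, p, p_adj, delta_median),
#'   `medians`, and `trend` (rho, p).
#' @export
comparePsiGroups <- function(psi, groups) {
  groups <- factor(groups, levels = if (is.factor(groups)) levels(groups)
                   else unique(groups))
  stopifnot(length(psi) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 3)) stop("each group needs at least 3 samples")
  lev <- levels(groups)
  pr <- t(combn(lev, 2))
  rows <- apply(pr, 1, function(g) {
    x <- psi[groups == g[1]]; y <- psi[groups == g[2]]
    p <- if (sd(c(x, y)) == 0) 1 else
      suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    data.frame(group1 = g[1], group2 = g[2], p = p,
               delta_median = median(y) - median(x),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  trend <- suppressWarnings(
    cor.test(psi, as.integer(groups), method = "spearman"))
  list(pairwise = pw,
       medians = tapply(psi, groups, median),
       trend = list(rho = unname(trend$estimate), p = trend$p.value))
}
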