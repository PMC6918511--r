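#' Analyte-wise two-group t tests with FDR control
#'
#' Pooled-variance (equal group variance assumed) two-sample t test per
#' analyte between the high- and low-heterosis groups, with
#' Benjamini-Hochberg adjustment across all tested analytes. Analytes whose
#' pooled variance is zero cannot be tested and are reported as untested
#' with a warning.
#'
#' @param X_high,X_low numeric matrices (samples x analytes, same analyte
#'   columns), each with >= 2 rows.
#' @param alpha adjusted-p cutoff for the significance flag (default 0.05).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return a `differential_result` data frame: analyte_id, mean_high,
#'   mean_low, t, p, p_adj, significant, tested.
#' @export
test_analytes <- function(X_high, X_low, alpha = 0.05,
                          adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!identical(colnames(X_high), colnames(X_low))) {
    stop("analyte columns must match between groups")
  }
  n1 <- nrow(X_high); n2 <- nrow(X_low)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  m1 <- colMeans(X_high); m2 <- colMeans(X_low)
  v1 <- apply(X_high, 2, stats::var); v2 <- apply(X_low, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tested <- sp2 > 0
  if (any(!tested)) {
    warning(sum(!tested), " analyte(s) with zero pooled variance skipped")
  }
  tstat <- rep(NA_real_, length(m1))
  pval <- rep(NA_real_, length(m1))
  se <- sqrt(sp2[tested] * (1 / n1 + 1 / n2))
  tstat[tested] <- (m1[tested] - m2[tested]) / se
  pval[tested] <- 2 * stats::pt(-abs(tstat[tested]), df = n1 + n2 - 2)
  padj <- rep(NA_real_, length(m1))
  padj[tested] <- stats::p.adjust(pval[tested], method = adjust)
  out <- data.frame(
    analyte_id = colnames(X_high),
    mean_high = m1, mean_low = m2,
    t = tstat, p = pval, p_adj = padj,
    significant = !is.na(padj) & padj <= alpha,
    tested = tested,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("differential_result", "data.frame"),
            alpha = alpha, adjust = adjust)
}

#' Overlap accounting between two analyte selections
#'
#' @param set_a,set_b character vectors of analyte ids.
#' @return list with counts `only_a`, `intersection`, `only_b` and the
#'   corresponding id vectors.
#' @export
selection_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- intersect(set_a, set_b)
  list(only_a = length(setdiff(set_a, set_b)),
       intersection = length(both),
       only_b = length(setdiff(set_b, set_a)),
       ids = list(only_a = setdiff(set_a, set_b),
                  intersection = both,
                  only_b = setdiff(set_b, set_a)))
}

#' Compare pathway-average metabolite levels between two groups
#'
#' Per sample, the arithmetic mean of the (autoscaled) levels of the
#' pathway's member analytes; the two classes are then compared by an
#' independent-samples t test (pooled variance unless Levene's test rejects,
#' see [group_compare()]).
#'
#' @param X numeric matrix (samples x analytes) with rownames.
#' @param subset analyte ids of the pathway members.
#' @param labels named character vector or [split_by_quantiles()] labels
#'   mapping sample ids to "low"/"high".
#' @return list with `scores` (per-sample pathway means), `group_means`,
#'   `statistic`, `p.value`.
#' @export
pathway_mean_compare <- function(X, subset, labels) {
  if (inherits(labels, "subgroup_labels")) labels <- labels$labels
  members <- intersect(subset, colnames(X))
  if (length(members) == 0) stop("pathway subset disjoint from the matrix")
  ids <- intersect(names(labels), rownames(X))
  if (length(unique(labels[ids])) < 2) stop("need both classes present")
  scores <- rowMeans(X[ids, members, drop = FALSE])
  hi <- scores[labels[ids] == "high"]
  lo <- scores[labels[ids] == "low"]
  cmp <- group_compare(hi, lo)
  list(scores = scores,
       group_means = c(high = mean(hi), low = mean(lo)),
       statistic = cmp$statistic, p.value = cmp$p.value,
       n_members = length(members))
}
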