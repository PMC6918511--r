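#' Compute better-parent heterosis for yield per plant
#'
#' For each hybrid in the design, F1 and both parental YPPs are taken as
#' replicate means; the high-value parent PH is the larger parental mean and
#' BPH-YPP = (F1 - PH) / PH. The measure is dimensionless, invariant to a
#' common rescaling of all yields, and symmetric in the two parents.
#'
#' @param phenos a [phenotype_table()].
#' @param design a [cross_design()].
#' @param year optional year/environment restriction passed to
#'   [genotype_means()].
#' @return a `heterosis_table`: data frame with columns hybrid_id, female,
#'   male, population, F1, PH, BPH_YPP, year.
#' @export
compute_bph <- function(phenos, design, year = NULL) {
  means <- genotype_means(phenos, year = year)
  need <- unique(c(design$hybrid_id, design$female, design$male))
  missing <- setdiff(need, names(means))
  if (length(missing) > 0) {
    stop("no phenotype for genotype(s): ", paste(missing, collapse = ", "))
  }
  f1 <- unname(means[design$hybrid_id])
  p1 <- unname(means[design$female])
  p2 <- unname(means[design$male])
  ph <- pmax(p1, p2)
  if (any(ph <= 0)) stop("high-parent YPP must be positive")
  out <- data.frame(
    hybrid_id = design$hybrid_id,
    female = design$female,
    male = design$male,
    population = design$population,
    F1 = f1,
    PH = ph,
    BPH_YPP = (f1 - ph) / ph,
    year = if (is.null(year)) NA_character_ else year,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("heterosis_table", "data.frame"))
}

#' Levene's test for equality of variances
#'
#' Classic Levene: one-way ANOVA on absolute deviations from the group mean.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return list with `statistic` (F) and `p.value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  ctr <- tapply(values, groups, mean)
  z <- abs(values - ctr[groups])
  fit <- stats::anova(stats::lm(z ~ groups))
  list(statistic = fit[["F value"]][1], p.value = fit[["Pr(>F)"]][1])
}

#' Two-group comparison by t test
#'
#' Independent-samples (two-tailed) or paired t test. For independent samples
#' the pooled equal-variance statistic is used by default; Levene's test is
#' always computed and, when it rejects equal variances at 0.05, the Welch
#' statistic is reported instead (`var_equal` overrides this choice).
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired paired test flag.
#' @param var_equal force pooled (`TRUE`) or Welch (`FALSE`); `NULL` (default)
#'   lets Levene's test decide.
#' @return list with `statistic`, `p.value`, `df`, `method` and (independent
#'   case) `levene_p`.
#' @export
group_compare <- function(a, b, paired = FALSE, var_equal = NULL) {
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal length")
    if (length(a) < 2) stop("need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      # constant difference: t test degenerate; zero difference means p = 1
      if (all(d == 0)) {
        return(list(statistic = 0, p.value = 1, df = length(d) - 1,
                    method = "paired t"))
      }
      stop("constant nonzero paired difference: zero variance")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    return(list(statistic = unname(tt$statistic), p.value = tt$p.value,
                df = unname(tt$parameter), method = "paired t"))
  }
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p.value = 1, df = length(a) + length(b) - 2,
                  method = "pooled t", levene_p = NA_real_))
    }
    stop("zero variance in both groups")
  }
  lev <- levene_test(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  pooled <- if (is.null(var_equal)) lev$p.value >= 0.05 else var_equal
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter),
       method = if (pooled) "pooled t" else "Welch t",
       levene_p = lev$p.value)
}
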