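#' Transform parental metabolite profiles into per-hybrid predictive variables
#'
#' For every hybrid of the design, the chosen formula combines the female
#' (P1) and male (P2) parental levels per analyte: means (P1 + P2)/2,
#' differences P1 - P2, or ratios P1/P2. Parental means are the transform
#' that tracks measured hybrid profiles most closely and are the default
#' predictive variables throughout the package.
#'
#' Ratios are only meaningful on positive abundances, so the `ratios`
#' transform requires state `sum_normalized`; means and differences default
#' to the `autoscaled` matrix used for modeling but accept any single state.
#'
#' @param parents a [metabolite_matrix()] whose genotypes cover all parents
#'   of the design (state `replicate_averaged`, `sum_normalized` or
#'   `autoscaled`).
#' @param design a [cross_design()].
#' @param transform one of `"means"`, `"differences"`, `"ratios"`.
#' @return an object of class `predictive_variables`: list with `values`
#'   (hybrids x analytes, rows in design order), `transform`, `design`.
#' @export
transform_parents <- function(parents, design,
                              transform = c("means", "differences", "ratios")) {
  transform <- match.arg(transform)
  validate_design(design, parents)
  if (transform == "ratios" && parents$state == "autoscaled") {
    stop("ratios of autoscaled (signed) values are ill-defined; ",
         "supply a sum_normalized matrix")
  }
  geno <- parents$sample_meta$genotype[match(rownames(parents$values),
                                             parents$sample_meta$sample_id)]
  if (anyDuplicated(geno)) {
    stop("parent matrix has several rows per genotype; average replicates first")
  }
  rownames(parents$values) <- geno
  p1 <- parents$values[design$female, , drop = FALSE]
  p2 <- parents$values[design$male, , drop = FALSE]
  v <- switch(transform,
    means = (p1 + p2) / 2,
    differences = p1 - p2,
    ratios = {
      zero <- colnames(p2)[apply(p2 == 0, 2, any)]
      if (length(zero) > 0) {
        stop("male-parent level is zero for analyte(s): ",
             paste(utils::head(zero, 5), collapse = ", "))
      }
      p1 / p2
    }
  )
  rownames(v) <- design$hybrid_id
  structure(list(values = v, transform = transform, design = design),
            class = "predictive_variables")
}

#' @export
print.predictive_variables <- function(x, ...) {
  cat(sprintf("<predictive_variables> %d hybrids x %d analytes, transform = %s\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' Substitute one parent for another throughout a cross design
#'
#' Supports the maintainer-line scenario: replacing a cytoplasmic
#' male-sterile female parent by its near-isogenic maintainer line in the
#' calculation of predictive variables.
#'
#' @param design a [cross_design()].
#' @param old_id parent id to replace (must occur in the design).
#' @param new_id replacement parent id.
#' @return a [cross_design()] with every occurrence replaced.
#' @export
substitute_parent <- function(design, old_id, new_id) {
  hit <- design$female == old_id | design$male == old_id
  if (!any(hit)) stop("parent '", old_id, "' does not occur in the design")
  design$female[design$female == old_id] <- new_id
  design$male[design$male == old_id] <- new_id
  cross_design(as.data.frame(design))
}

#' Correlate measured hybrid profiles with transformed parental levels
#'
#' For each profiled hybrid, the Pearson correlation across shared analytes
#' between its own measured metabolite profile and its transformed-parental
#' row. Ranking the mean correlation across transforms shows which parental
#' combination best represents hybrid metabolomes (means > differences >
#' ratios).
#'
#' @param hybrids a [metabolite_matrix()] containing profiled hybrids (rows
#'   named by hybrid genotype).
#' @param pv a [predictive_variables()] object from [transform_parents()].
#' @return data frame with hybrid_id and Pearson `r`.
#' @export
compare_hybrid_to_transforms <- function(hybrids, pv) {
  geno <- hybrids$sample_meta$genotype[match(rownames(hybrids$values),
                                             hybrids$sample_meta$sample_id)]
  shared_h <- intersect(geno, rownames(pv$values))
  if (length(shared_h) == 0) stop("no profiled hybrids present in the design")
  shared_a <- intersect(colnames(hybrids$values), colnames(pv$values))
  if (length(shared_a) < 3) stop("fewer than 3 shared analytes")
  r <- vapply(shared_h, function(h) {
    row <- hybrids$values[match(h, geno), shared_a]
    stats::cor(row, pv$values[h, shared_a])
  }, numeric(1))
  data.frame(hybrid_id = shared_h, r = unname(r), stringsAsFactors = FALSE)
}
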