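#' Construct a phenotype table
#'
#' Long-format yield phenotypes: one row per genotype x replicate, with yield
#' per plant (YPP) in grams per plant and an optional year/environment label.
#'
#' @param df data frame with columns `genotype_id`, `ypp` and optionally
#'   `replicate`, `year`.
#' @return an object of class `phenotype_table` (a validated data frame).
#' @export
phenotype_table <- function(df) {
  if (!all(c("genotype_id", "ypp") %in% names(df))) {
    stop("phenotype table needs columns genotype_id and ypp")
  }
  if (!is.numeric(df$ypp) || any(!is.finite(df$ypp)) || any(df$ypp <= 0)) {
    stop("YPP values must be positive and finite")
  }
  if (is.null(df$replicate)) df$replicate <- stats::ave(df$ypp, df$genotype_id,
                                                        FUN = seq_along)
  if (is.null(df$year)) df$year <- NA_character_
  structure(df, class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype table from delimited text
#'
#' @param path CSV/TSV file with columns genotype_id, ypp and optionally
#'   replicate, year.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  phenotype_table(df)
}

#' Replicate-mean YPP per genotype
#'
#' @param phenos a [phenotype_table()].
#' @param year optional year/environment label to restrict to.
#' @return named numeric vector of mean YPP per genotype.
#' @export
genotype_means <- function(phenos, year = NULL) {
  df <- as.data.frame(phenos)
  if (!is.null(year)) {
    df <- df[!is.na(df$year) & df$year == year, , drop = FALSE]
    if (nrow(df) == 0) stop("no phenotypes for year ", year)
  }
  tapply(df$ypp, df$genotype_id, mean)
}

#' Construct a cross-design table
#'
#' Maps each hybrid to its female and male parent and a population label.
#'
#' @param df data frame with columns `hybrid_id`, `female`, `male`,
#'   `population`.
#' @return an object of class `cross_design` (a validated data frame).
#' @export
cross_design <- function(df) {
  need <- c("hybrid_id", "female", "male", "population")
  if (!all(need %in% names(df))) {
    stop("cross design needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$hybrid_id)) {
    stop("duplicate hybrid ids: ",
         paste(unique(df$hybrid_id[duplicated(df$hybrid_id)]), collapse = ", "))
  }
  structure(df, class = c("cross_design", "data.frame"))
}

#' Read a cross design from delimited text
#'
#' @param path CSV/TSV file with columns hybrid_id, female, male, population.
#' @param parents optional [metabolite_matrix()] or character vector of
#'   genotype ids the parents must resolve against.
#' @return a [cross_design()].
#' @export
read_design <- function(path, parents = NULL) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  d <- cross_design(df)
  if (!is.null(parents)) validate_design(d, parents)
  d
}

#' Check that every parent in a design resolves to a known genotype
#'
#' @param design a [cross_design()].
#' @param parents a [metabolite_matrix()] (its genotypes are used) or a
#'   character vector of genotype ids.
#' @return `design`, invisibly; errors listing unresolvable parents.
#' @export
validate_design <- function(design, parents) {
  ids <- if (inherits(parents, "metabolite_matrix")) {
    unique(parents$sample_meta$genotype)
  } else {
    parents
  }
  missing <- setdiff(unique(c(design$female, design$male)), ids)
  if (length(missing) > 0) {
    stop("parent id(s) not found in parent matrix: ",
         paste(missing, collapse = ", "))
  }
  invisible(design)
}
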