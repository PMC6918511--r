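#' Construct a metabolite matrix
#'
#' The central container of the package: a samples x analytes table of
#' relative LC-MS abundances plus per-sample metadata and a processing-state
#' flag. The state records where the matrix sits in the normalization chain
#' (`raw` -> `replicate_averaged` -> `sum_normalized` -> `autoscaled`) and is
#' checked by every operation that has a state precondition.
#'
#' @param values numeric matrix, one row per sample, one column per analyte;
#'   rownames are sample ids, colnames analyte ids. Both must be unique.
#' @param sample_meta data frame with columns `sample_id`, `genotype`, `role`
#'   (one of parent/hybrid/maintainer/QC), `population`, `replicate`. If
#'   `NULL`, a minimal frame is derived from rownames (role "parent",
#'   population "pop1", replicate 1, genotype = sample id).
#' @param state processing state flag, see above.
#' @return an object of class `metabolite_matrix` with elements `values`,
#'   `sample_meta`, `state` and (after autoscaling) `scaling`.
#' @export
metabolite_matrix <- function(values,
                              sample_meta = NULL,
                              state = c("raw", "replicate_averaged",
                                        "sum_normalized", "autoscaled")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and analyte ids as colnames")
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(
      sample_id = rownames(values),
      genotype = rownames(values),
      role = "parent",
      population = "pop1",
      replicate = 1L,
      stringsAsFactors = FALSE
    )
  }
  mm <- structure(
    list(values = values, sample_meta = sample_meta, state = state),
    class = "metabolite_matrix"
  )
  validate_metabolite_matrix(mm)
  mm
}

#' Validate a metabolite matrix against its state invariants
#'
#' Checks id uniqueness, finiteness, nonnegativity before autoscaling,
#' constant row sums in the `sum_normalized` state and column mean 0 / sd 1
#' in the `autoscaled` state.
#'
#' @param mm a [metabolite_matrix()].
#' @param tol relative tolerance for the row-sum and column-moment checks.
#' @return `mm`, invisibly; errors on violation.
#' @export
validate_metabolite_matrix <- function(mm, tol = 1e-9) {
  v <- mm$values
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(v))) stop("duplicate analyte ids")
  if (!all(is.finite(v))) stop("non-finite values in metabolite matrix")
  meta <- mm$sample_meta
  need <- c("sample_id", "genotype", "role", "population", "replicate")
  if (!all(need %in% names(meta))) {
    stop("sample_meta must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(meta$sample_id, rownames(v)) ||
      anyDuplicated(meta$sample_id)) {
    stop("sample_meta$sample_id must match matrix rownames one-to-one")
  }
  if (mm$state %in% c("raw", "replicate_averaged", "sum_normalized") &&
      any(v < 0)) {
    stop("negative abundances are not allowed in state ", mm$state)
  }
  if (mm$state == "sum_normalized") {
    rs <- rowSums(v)
    if (max(abs(rs - rs[1])) > tol * max(abs(rs[1]), 1)) {
      stop("row sums are not constant in state sum_normalized")
    }
  }
  if (mm$state == "autoscaled") {
    cm <- colMeans(v)
    cs <- apply(v, 2, stats::sd)
    if (max(abs(cm)) > tol || max(abs(cs - 1)) > 1e-6) {
      stop("autoscaled matrix must have column mean 0 and sd 1")
    }
  }
  invisible(mm)
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d analytes, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  cat("roles: ", paste(sprintf("%s (%d)", names(table(x$sample_meta$role)),
                               table(x$sample_meta$role)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# sniff the field separator from the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a wide metabolite table from delimited text
#'
#' Reads a CSV/TSV matrix with one id header row and one id column. The
#' on-disk orientation may be either samples-in-rows or analytes-in-rows;
#' the returned matrix is always samples x analytes.
#'
#' @param path file path to a CSV or TSV table (separator sniffed from the
#'   header line).
#' @param orientation `"rows-are-samples"` (default) or `"rows-are-analytes"`.
#' @param meta optional sample-metadata data frame or path to a sidecar
#'   CSV/TSV with columns sample_id, genotype, role, population, replicate.
#' @param na_action `"reject"` (default) errors on missing cells;
#'   `"half_min"` imputes half the analyte minimum.
#' @return a [metabolite_matrix()] in state `raw`.
#' @export
read_metabolite_table <- function(path,
                                  orientation = c("rows-are-samples",
                                                  "rows-are-analytes"),
                                  meta = NULL,
                                  na_action = c("reject", "half_min")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate ids in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1, drop = FALSE]
  if (anyDuplicated(names(body))) {
    stop("duplicate ids in header of ", path)
  }
  m <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
              dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[bad[1]], names(body)[j], path))
    }
    num[raw == "" | raw == "NA"] <- NA_real_
    m[, j] <- num
  }
  if (orientation == "rows-are-analytes") m <- t(m)
  if (anyNA(m)) {
    if (na_action == "reject") {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at sample '%s', analyte '%s' (na_action = reject)",
                   rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- min(m[!nas, j]) / 2
    }
  }
  if (is.character(meta) && length(meta) == 1) {
    msep <- .detect_sep(meta)
    meta <- utils::read.table(meta, header = TRUE, sep = msep,
                              stringsAsFactors = FALSE, check.names = FALSE)
  }
  metabolite_matrix(m, sample_meta = meta, state = "raw")
}

#' Write a metabolite matrix (and its metadata sidecar) to delimited text
#'
#' @param mm a [metabolite_matrix()].
#' @param path output path; `.tsv` extension writes tab-separated, else CSV.
#' @param meta_path optional path for the sample-metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(mm, path, meta_path = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample_id = rownames(mm$values),
                   mm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    msep <- if (grepl("\\.tsv$", meta_path)) "\t" else ","
    utils::write.table(mm$sample_meta, meta_path, sep = msep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Subset a metabolite matrix by sample role and/or population
#'
#' QC injections are profiled alongside experimental samples but are excluded
#' before the analysis matrix is normalized; this filter is how that is done.
#'
#' @param mm a [metabolite_matrix()].
#' @param roles,populations character vectors of levels to keep (`NULL` keeps
#'   all).
#' @return a [metabolite_matrix()] in the same state.
#' @export
filter_samples <- function(mm, roles = NULL, populations = NULL) {
  keep <- rep(TRUE, nrow(mm$values))
  meta <- mm$sample_meta[match(rownames(mm$values), mm$sample_meta$sample_id), ]
  if (!is.null(roles)) keep <- keep & meta$role %in% roles
  if (!is.null(populations)) keep <- keep & meta$population %in% populations
  if (!any(keep)) stop("no samples left after filtering")
  metabolite_matrix(mm$values[keep, , drop = FALSE],
                    sample_meta = meta[keep, , drop = FALSE],
                    state = mm$state)
}

#' Average biological replicates to one row per genotype
#'
#' Samples sharing a genotype are collapsed to their arithmetic mean;
#' genotypes with a single replicate pass through unchanged. Replicates of a
#' genotype must agree on role and population.
#'
#' @param mm a [metabolite_matrix()] in state `raw`.
#' @return a [metabolite_matrix()] in state `replicate_averaged` with one row
#'   per genotype (sample ids become genotype ids).
#' @export
average_replicates <- function(mm) {
  if (mm$state != "raw") stop("average_replicates expects state raw, got ", mm$state)
  meta <- mm$sample_meta[match(rownames(mm$values), mm$sample_meta$sample_id), ]
  genos <- unique(meta$genotype)
  out <- matrix(0, nrow = length(genos), ncol = ncol(mm$values),
                dimnames = list(genos, colnames(mm$values)))
  new_meta <- data.frame(sample_id = genos, genotype = genos,
                         role = NA_character_, population = NA_character_,
                         replicate = 1L, stringsAsFactors = FALSE)
  for (i in seq_along(genos)) {
    rows <- which(meta$genotype == genos[i])
    if (length(unique(meta$role[rows])) > 1 ||
        length(unique(meta$population[rows])) > 1) {
      stop("conflicting role/population metadata for genotype ", genos[i])
    }
    out[i, ] <- colMeans(mm$values[rows, , drop = FALSE])
    new_meta$role[i] <- meta$role[rows[1]]
    new_meta$population[i] <- meta$population[rows[1]]
  }
  metabolite_matrix(out, sample_meta = new_meta, state = "replicate_averaged")
}

#' Sum-normalize each sample row to a common constant
#'
#' @param mm a [metabolite_matrix()] in state `replicate_averaged`.
#' @param row_constant positive total each row is rescaled to. Only relative
#'   structure matters once columns are autoscaled, so the default of 1
#'   (compositional profiles) is as good as any.
#' @return a [metabolite_matrix()] in state `sum_normalized`.
#' @export
sum_normalize <- function(mm, row_constant = 1) {
  if (mm$state != "replicate_averaged") {
    stop("sum_normalize expects state replicate_averaged, got ", mm$state)
  }
  if (!is.numeric(row_constant) || row_constant <= 0) {
    stop("row_constant must be a positive number")
  }
  rs <- rowSums(mm$values)
  if (any(rs == 0)) {
    stop("sample row(s) summing to zero: ",
         paste(rownames(mm$values)[rs == 0], collapse = ", "))
  }
  v <- sweep(mm$values, 1, rs / row_constant, "/")
  metabolite_matrix(v, sample_meta = mm$sample_meta, state = "sum_normalized")
}

#' Autoscale analyte columns to mean 0, sd 1
#'
#' Columns that are constant after sum normalization carry no information and
#' cannot be scaled; they are dropped with a warning. The sample (n - 1)
#' standard deviation is used, matching common chemometrics practice.
#'
#' @param mm a [metabolite_matrix()] in state `sum_normalized`.
#' @return a [metabolite_matrix()] in state `autoscaled`, with the per-column
#'   `center` and `scale` parameters retained in `$scaling`.
#' @export
autoscale <- function(mm) {
  if (mm$state != "sum_normalized") {
    stop("autoscale expects state sum_normalized, got ", mm$state)
  }
  v <- mm$values
  ctr <- colMeans(v)
  scl <- apply(v, 2, stats::sd)
  const <- scl == 0
  if (any(const)) {
    warning(sum(const), " all-constant analyte column(s) dropped before autoscaling: ",
            paste(utils::head(colnames(v)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
    v <- v[, !const, drop = FALSE]
    ctr <- ctr[!const]
    scl <- scl[!const]
  }
  v <- sweep(sweep(v, 2, ctr, "-"), 2, scl, "/")
  out <- metabolite_matrix(v, sample_meta = mm$sample_meta, state = "autoscaled")
  out$scaling <- list(center = ctr, scale = scl)
  out
}

#' Full normalization chain: sum normalization then autoscaling
#'
#' Convenience wrapper reproducing the standard metabolomics preprocessing
#' recipe (normalization by sum, no transformation, autoscaling) applied
#' after replicate averaging.
#'
#' @inheritParams sum_normalize
#' @return a [metabolite_matrix()] in state `autoscaled` (see [autoscale()]).
#' @export
normalize_metabolites <- function(mm, row_constant = 1) {
  autoscale(sum_normalize(mm, row_constant = row_constant))
}
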