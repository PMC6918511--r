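#' Principal component analysis with a fixed sign convention
#'
#' Column-centered PCA via singular value decomposition. SVD leaves the sign
#' of each component arbitrary; to make PC1-ordered core selection
#' reproducible across platforms, every loading vector is oriented so that
#' its largest-absolute-value entry is positive.
#'
#' @param X numeric matrix (samples x variables) with rownames.
#' @param n_components number of components to retain (capped at
#'   min(n - 1, p) with a warning).
#' @return an object of class `pca_result`: `scores` (n x A), `loadings`
#'   (p x A), `explained` (proportion of variance per component), `center`,
#'   `sample_ids`.
#' @export
run_pca <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples for PCA")
  cap <- min(n - 1, ncol(X))
  if (is.null(n_components)) n_components <- cap
  if (n_components > cap) {
    warning("n_components truncated to ", cap)
    n_components <- cap
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = expl[seq_len(k)], center = pc$center,
                 sample_ids = rownames(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select core hybrids by interval sampling along the PC1 ordering
#'
#' A population's hybrids are ranked by their first-principal-component
#' score from high to low (ties broken by hybrid id) and every k-th hybrid,
#' starting at `offset`, becomes a core hybrid. Cores sample the whole span
#' of the population structure and form the training set; the remaining
#' (noncore) hybrids are held out for evaluation.
#'
#' @param pca a [run_pca()] result whose samples include the hybrids.
#' @param ids hybrid ids of one population (subset of `pca$sample_ids`).
#' @param k selection interval (k = 2, 3, 4 give the 1/2N, 1/3N, 1/4N sets);
#'   k = 1 degenerately selects everything.
#' @param offset 0-based start position in the ordering (0 = the hybrid with
#'   the highest PC1 score).
#' @param population optional population label carried into the result.
#' @return an object of class `core_selection`: `ordering` (ids by
#'   descending PC1 score), `core`, `noncore`, `k`, `offset`, `population`.
#' @export
select_core <- function(pca, ids, k, offset = 0L, population = NA_character_) {
  if (length(ids) == 0) stop("empty population")
  if (k < 1) stop("k must be >= 1")
  if (offset < 0 || offset >= k) stop("offset must satisfy 0 <= offset < k")
  missing <- setdiff(ids, pca$sample_ids)
  if (length(missing) > 0) {
    stop("ids absent from PCA: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  s <- pca$scores[ids, 1]
  ordering <- ids[order(-s, ids)]
  take <- seq.int(offset + 1L, length(ordering), by = k)
  structure(list(population = population, ordering = ordering,
                 k = k, offset = offset,
                 core = ordering[take],
                 noncore = setdiff(ordering, ordering[take])),
            class = "core_selection")
}

#' Assemble a mixed-population training set from core selections
#'
#' Core hybrids of all selections are pooled into the training set; each
#' population's noncore hybrids become a held-out evaluation set. X rows and
#' y are aligned by hybrid id throughout.
#'
#' @param selections list of [select_core()] results from distinct
#'   populations.
#' @param pv a [transform_parents()] predictive-variable object covering all
#'   hybrids.
#' @param het a `heterosis_table` with BPH_YPP for all hybrids.
#' @return list with `X`, `y`, `training_ids` and `eval` (named list per
#'   population of `X`, `y`, `ids`).
#' @export
assemble_training <- function(selections, pv, het) {
  pops <- vapply(selections, function(s) s$population, character(1))
  if (anyDuplicated(pops[!is.na(pops)])) {
    stop("core selections must come from distinct populations")
  }
  bph <- stats::setNames(het$BPH_YPP, het$hybrid_id)
  train_ids <- unlist(lapply(selections, function(s) s$core), use.names = FALSE)
  all_ids <- unlist(lapply(selections, function(s) c(s$core, s$noncore)),
                    use.names = FALSE)
  no_bph <- setdiff(all_ids, names(bph))
  if (length(no_bph) > 0) {
    stop("hybrid(s) lacking BPH value: ",
         paste(utils::head(no_bph, 5), collapse = ", "))
  }
  eval_sets <- lapply(selections, function(s) {
    list(X = pv$values[s$noncore, , drop = FALSE],
         y = unname(bph[s$noncore]),
         ids = s$noncore)
  })
  names(eval_sets) <- pops
  list(X = pv$values[train_ids, , drop = FALSE],
       y = unname(bph[train_ids]),
       training_ids = train_ids,
       eval = eval_sets)
}

#' Ward dendrogram of parent metabolite profiles
#'
#' Agglomerative hierarchical clustering of parents with Euclidean distance
#' and Ward's minimum-variance criterion (`hclust` method `ward.D2`, the
#' variant that operates on unsquared Euclidean distances).
#'
#' @param parents a [metabolite_matrix()] with at least 3 parent rows.
#' @return an `hclust` tree with parent ids as labels.
#' @export
cluster_parents <- function(parents) {
  v <- parents$values
  if (nrow(v) < 3) stop("need at least 3 parents to cluster")
  stats::hclust(stats::dist(v, method = "euclidean"), method = "ward.D2")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` tree (e.g., from [cluster_parents()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
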