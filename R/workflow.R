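#' Run the full heterosis-prediction workflow on a data bundle
#'
#' Orchestrates the whole procedure on a synthetic (or identically shaped
#' real) bundle: replicate averaging -> sum normalization + autoscaling of
#' the parent matrix -> parental-mean predictive variables -> BPH-YPP from
#' phenotypes -> per-population PCA of all predictive variables -> PC1
#' interval selection of core hybrids -> mixed-population training set ->
#' all-variable PLS model -> mean-VIP feature sweep -> best reduced model
#' and held-out predictions. Identical inputs and seed give byte-identical
#' result tables and manifest.
#'
#' @param bundle a [generate_synthetic()] bundle, or a list with the same
#'   `metabolites`, `design`, `phenotypes` elements.
#' @param k_core named integer vector of PC1 selection intervals per
#'   population (default `c(pop1 = 3, pop2 = 2)`, the 1/3N + 1/2N set).
#' @param offset 0-based start position of the interval selection.
#' @param grid variable counts for the feature sweep (default 100-step grid,
#'   see [feature_sweep()]); `NULL` uses the default, `NA` skips the sweep.
#' @param vip_mode VIP statistic for the sweep ranking (default `"all"`,
#'   the explained-variance-weighted VIP over all latent factors; see
#'   [feature_sweep()]).
#' @param A_max latent-factor cap (default 17).
#' @param out_dir optional directory; when given, result tables (TSV) and a
#'   JSON run manifest are written there.
#' @return list with `heterosis`, `pv`, `pca` (per population), `cores`,
#'   `training`, `full_prediction`, `sweep`, `manifest`.
#' @export
run_workflow <- function(bundle,
                         k_core = c(pop1 = 3L, pop2 = 2L),
                         offset = 0L,
                         grid = NULL,
                         vip_mode = "all",
                         A_max = 17L,
                         out_dir = NULL) {
  parents_raw <- filter_samples(bundle$metabolites, roles = "parent")
  parents <- normalize_metabolites(average_replicates(parents_raw))
  het <- compute_bph(bundle$phenotypes, bundle$design)
  pv <- transform_parents(parents, bundle$design, transform = "means")

  pops <- intersect(names(k_core), unique(bundle$design$population))
  if (length(pops) == 0) stop("k_core names do not match any population")
  pca <- list()
  cores <- list()
  for (pop in pops) {
    ids <- bundle$design$hybrid_id[bundle$design$population == pop]
    pca[[pop]] <- run_pca(pv$values[ids, , drop = FALSE])
    cores[[pop]] <- select_core(pca[[pop]], ids, k = k_core[[pop]],
                                offset = offset, population = pop)
  }
  training <- assemble_training(cores, pv, het)
  full_prediction <- run_prediction(training$X, training$y, training$eval,
                                    A_max = A_max)
  sweep <- NULL
  if (!(length(grid) == 1 && is.na(grid))) {
    sweep <- feature_sweep(training$X, training$y, training$eval,
                           grid = grid, vip_mode = vip_mode, A_max = A_max)
  }

  manifest <- list(
    seed = if (!is.null(bundle$config$seed)) bundle$config$seed else NA,
    n_hybrids = stats::setNames(
      as.list(vapply(pops, function(pop)
        sum(bundle$design$population == pop), numeric(1))), pops),
    n_analytes = ncol(pv$values),
    k_core = as.list(k_core[pops]),
    offset = offset,
    n_training = length(training$training_ids),
    full_model = list(A = full_prediction$A,
                      adj_r2 = full_prediction$adj_r2,
                      predictability = stats::setNames(
                        as.list(full_prediction$summary$r),
                        full_prediction$summary$set))
  )
  if (!is.null(sweep)) {
    manifest$sweep <- list(
      vip_mode = sweep$vip_mode,
      best_k = sweep$best_k,
      A = sweep$best_prediction$A,
      predictability = stats::setNames(
        as.list(sweep$best_prediction$summary$r),
        sweep$best_prediction$summary$set),
      selected_analytes = sweep$ranking[seq_len(sweep$best_k)])
  }

  out <- list(heterosis = het, pv = pv, pca = pca, cores = cores,
              training = training, full_prediction = full_prediction,
              sweep = sweep, manifest = manifest)
  if (!is.null(out_dir)) write_workflow_results(out, out_dir)
  out
}

#' Write workflow result tables and the run manifest
#'
#' @param wf a [run_workflow()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_workflow_results <- function(wf, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(as.data.frame(wf$heterosis), "heterosis.tsv")
  core_df <- do.call(rbind, lapply(wf$cores, function(cs) {
    data.frame(population = cs$population,
               hybrid_id = cs$ordering,
               rank = seq_along(cs$ordering),
               core = cs$ordering %in% cs$core,
               stringsAsFactors = FALSE)
  }))
  tsv(core_df, "core_selection.tsv")
  tsv(wf$full_prediction$results, "predictions_full.tsv")
  tsv(wf$full_prediction$summary, "predictability_full.tsv")
  if (!is.null(wf$sweep)) {
    tsv(wf$sweep$curve, "sweep_curve.tsv")
    tsv(wf$sweep$best_prediction$results, "predictions_best.tsv")
    tsv(wf$sweep$best_prediction$summary, "predictability_best.tsv")
  }
  jsonlite::write_json(wf$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery of planted analytes by the workflow's feature selection
#'
#' Fraction of the generator's planted informative analytes found among the
#' top-s analytes of the workflow's VIP ranking (s = number planted).
#'
#' @param wf a [run_workflow()] result with a sweep.
#' @param truth the bundle's `truth` element.
#' @return fraction in \[0, 1\].
#' @export
planted_recovery <- function(wf, truth) {
  s <- length(truth$planted_ids)
  top_s <- wf$sweep$ranking[seq_len(s)]
  length(intersect(top_s, truth$planted_ids)) / s
}
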