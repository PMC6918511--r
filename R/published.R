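#' Reproduce the published two-population study from supplementary tables
#'
#' Runs the complete published analysis when the study's supplementary
#' tables are supplied on disk (they are not bundled with the package; the
#' raw data live in the MetaboLights repository under study MTBLS742).
#' Expected files in `data_dir`:
#'
#' * `metabolites.csv` — wide table, samples x 3,746 analytes, raw relative
#'   abundances of all parent (and profiled hybrid) samples.
#' * `sample_meta.csv` — sample_id, genotype, role, population
#'   (`pop2012`/`pop2015`), replicate.
#' * `phenotypes.csv` — genotype_id, ypp, replicate, year (`2012`/`2015`).
#' * `design.csv` — hybrid_id, female, male, population.
#' * optional `design_2015.csv` + phenotype rows with year `2015` for the
#'   41-hybrid across-year validation.
#'
#' The returned statistics correspond to the study's printed values:
#' latent-factor count and adjusted R-square of the all-variable model on
#' the diallel population (3 factors, adjusted R2 0.3647); its
#' predictabilities on both populations (0.61 / 0.24); PLS-DA VIP cutoffs
#' for the top-1000 and top-500 screens (1.0198 / 1.4631); core-hybrid
#' predictabilities with the top-1000 and all variables (0.34 / 0.44); the
#' mean-VIP sweep optimum (1,400 variables, r = 0.58); the number of
#' FDR-significant analytes between the 72-vs-72 subgroups (1,311); and the
#' across-year validation r (0.62).
#'
#' @param data_dir directory holding the files above.
#' @param grid sweep grid (default 100-step).
#' @return named list of the reproduced statistics.
#' @export
reproduce_published_stats <- function(data_dir, grid = NULL) {
  path <- function(f) file.path(data_dir, f)
  for (f in c("metabolites.csv", "sample_meta.csv", "phenotypes.csv",
              "design.csv")) {
    if (!file.exists(path(f))) stop("required file missing: ", path(f))
  }
  mm <- read_metabolite_table(path("metabolites.csv"),
                              meta = path("sample_meta.csv"))
  phenos <- read_phenotypes(path("phenotypes.csv"))
  design <- read_design(path("design.csv"))

  parents <- normalize_metabolites(average_replicates(
    filter_samples(mm, roles = "parent")))
  het <- compute_bph(phenos, design, year = "2012")
  pv <- transform_parents(parents, design, transform = "means")

  pops <- sort(unique(design$population))
  pop1 <- pops[1]; pop2 <- pops[2]  # pop2012, pop2015
  ids1 <- design$hybrid_id[design$population == pop1]
  ids2 <- design$hybrid_id[design$population == pop2]
  bph <- stats::setNames(het$BPH_YPP, het$hybrid_id)

  out <- list()

  # all-variable model trained on the whole diallel population
  sel <- select_latent_factors(pv$values[ids1, ], unname(bph[ids1]))
  out$A_full <- sel$A
  out$adj_r2_full <- sel$adj_r2[sel$A]
  pred1 <- predict(sel$model, pv$values[ids1, ])
  pred2 <- predict(sel$model, pv$values[ids2, ])
  out$r_pop1_full <- predictability(unname(bph[ids1]), pred1)$r
  out$r_pop2_full <- predictability(unname(bph[ids2]), pred2)$r

  # PLS-DA screening: 72 high vs 72 low hybrids of the diallel population
  labels <- split_by_quantiles(het[het$population == pop1, ],
                               n_per_group = 72L)
  da <- fit_plsda(pv$values[ids1, ], labels, A = 2L)
  v1 <- vip(da, components = 1)
  out$vip_cutoff_1000 <- top_k_by_vip(v1, 1000L)$threshold
  out$vip_cutoff_500 <- top_k_by_vip(v1, 500L)$threshold

  # population structure from all predictive variables; 1/3N + 1/2N cores
  pca1 <- run_pca(pv$values[ids1, ])
  pca2 <- run_pca(pv$values[ids2, ])
  cores <- list(select_core(pca1, ids1, k = 3L, population = pop1),
                select_core(pca2, ids2, k = 2L, population = pop2))
  training <- assemble_training(cores, pv, het)

  top1000 <- top_k_by_vip(v1, 1000L)$ids
  pr_1000 <- run_prediction(training$X[, top1000], training$y,
                            lapply(training$eval, function(es) {
                              list(X = es$X[, top1000], y = es$y, ids = es$ids)
                            }))
  out$r_pop2_top1000_cores <-
    pr_1000$summary$r[pr_1000$summary$set == pop2]

  pr_full <- run_prediction(training$X, training$y, training$eval)
  out$r_pop2_all_cores <- pr_full$summary$r[pr_full$summary$set == pop2]

  # mean VIP over all latent factors: variable-count sweep
  sw <- feature_sweep(training$X, training$y, training$eval,
                      grid = grid, vip_mode = "mean_all")
  out$best_k <- sw$best_k
  out$r_pop2_best <-
    sw$best_prediction$summary$r[sw$best_prediction$summary$set == pop2]

  # differential analytes between the 72-vs-72 subgroups
  hi <- names(labels$labels)[labels$labels == "high"]
  lo <- names(labels$labels)[labels$labels == "low"]
  dr <- test_analytes(pv$values[hi, ], pv$values[lo, ], alpha = 0.05)
  out$n_significant <- sum(dr$significant)
  out$overlap_with_selected <- selection_overlap(
    sw$ranking[seq_len(sw$best_k)],
    dr$analyte_id[dr$significant])$intersection

  # across-year validation of the frozen best model
  if (file.exists(path("design_2015.csv"))) {
    design_val <- read_design(path("design_2015.csv"))
    het_val <- compute_bph(phenos, design_val, year = "2015")
    pv_val <- transform_parents(parents, design_val, transform = "means")
    val <- validate_holdout(sw$best_model, pv_val, het_val)
    out$r_validation_2015 <- attr(val, "r")
    out$n_validation <- attr(val, "n")
  }
  out
}
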