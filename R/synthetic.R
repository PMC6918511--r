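#' Configuration of the synthetic two-population study
#'
#' The generator emulates the shape of a two-population hybrid-rice design:
#' a main population whose parents are crossed in a complete diallel
#' (reciprocals included) and a second population of inbred lines
#' test-crossed to one cytoplasmic male-sterile (CMS) female, whose
#' near-isogenic maintainer line is profiled alongside. Parent metabolomes
#' follow a latent-factor model on the log scale with a fixed
#' population-shift direction, log-normal raw abundances, multiplicative
#' replicate noise and a few QC injections. Better-parent heterosis of every
#' hybrid is linear in the planted analytes of the normalized parental
#' means, plus Gaussian noise.
#'
#' The planted analytes form `n_modules` correlated modules: each planted
#' analyte loads (loading `a_j ~ N(1, module_loading_sd^2) * beta_sd`) on
#' its module's latent "heterosis program" factor of the parent metabolome,
#' and the same loadings serve as the effect vector of the hybrid signal.
#' Heterosis-associated metabolites in real data are coherent pathway
#' modules rather than isolated features; module structure is what makes a
#' planted set of hundreds of analytes identifiable at all from a training
#' set of ~150 hybrids whose rows share only ~130 distinct parents.
#'
#' @param n_parents_pop1 parents of the diallel population (default 18,
#'   giving 18 x 17 = 306 ordered hybrids).
#' @param n_parents_pop2 inbred lines test-crossed to the CMS female
#'   (default 107 hybrids).
#' @param p number of analytes (default 2000).
#' @param s number of planted informative analytes (default 200).
#' @param d latent dimension of the parent metabolome (default 10).
#' @param delta population mean-shift magnitude in per-analyte SD units; the
#'   shift is applied along a fixed random direction so that it survives sum
#'   normalization (default 1).
#' @param beta_sd overall scale of the planted module loadings / effect
#'   sizes; 0 gives the null (no-signal) configuration (default 2).
#' @param module_loading_sd spread of the per-analyte module loadings
#'   around 1 (default 0.3).
#' @param n_modules number of planted pathway modules (default 1: one
#'   coherent heterosis program).
#' @param signal_r2 fraction of BPH-YPP variance explained by the planted
#'   signal; used to derive `sigma_y` when that is `NULL` (default 0.5).
#' @param sigma_y SD of the heterosis noise; `NULL` derives it from
#'   `signal_r2`.
#' @param sigma_rep replicate (measurement) noise SD on the log scale
#'   (default 0.3).
#' @param sigma_analyte parent-level biological noise SD beyond the latent
#'   factors (default 1).
#' @param n_rep biological replicates per profiled genotype (default 2).
#' @param base_ypp parental yield per plant in g/plant (default 50).
#' @param bph_mean,bph_signal_sd location and signal SD of BPH-YPP (defaults
#'   0.1 and 0.15, a typical published spread of rice BPH-YPP).
#' @param maintainer_sd log-scale divergence of the maintainer line from its
#'   CMS counterpart (default 0.3).
#' @param n_profiled_hybrid_pairs reciprocal hybrid pairs of pop1 whose own
#'   metabolomes are measured (default 3).
#' @param n_qc number of pooled QC injections (default 3).
#' @param seed integer seed; a fixed seed makes the whole bundle
#'   byte-identical across runs.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_parents_pop1 = 18L, n_parents_pop2 = 107L,
                             p = 2000L, s = 200L, d = 10L,
                             delta = 1, beta_sd = 2, module_loading_sd = 0.3,
                             n_modules = 1L,
                             signal_r2 = 0.5, sigma_y = NULL,
                             sigma_rep = 0.3, sigma_analyte = 1,
                             n_rep = 2L, base_ypp = 50,
                             bph_mean = 0.1, bph_signal_sd = 0.15,
                             maintainer_sd = 0.3,
                             n_profiled_hybrid_pairs = 3L, n_qc = 3L,
                             seed = 1L) {
  cfg <- list(n_parents_pop1 = as.integer(n_parents_pop1),
              n_parents_pop2 = as.integer(n_parents_pop2),
              p = as.integer(p), s = as.integer(s), d = as.integer(d),
              delta = delta, beta_sd = beta_sd,
              module_loading_sd = module_loading_sd,
              n_modules = as.integer(n_modules),
              signal_r2 = signal_r2, sigma_y = sigma_y,
              sigma_rep = sigma_rep, sigma_analyte = sigma_analyte,
              n_rep = as.integer(n_rep), base_ypp = base_ypp,
              bph_mean = bph_mean, bph_signal_sd = bph_signal_sd,
              maintainer_sd = maintainer_sd,
              n_profiled_hybrid_pairs = as.integer(n_profiled_hybrid_pairs),
              n_qc = as.integer(n_qc), seed = as.integer(seed))
  if (cfg$s > cfg$p) stop("s must not exceed p")
  sds <- c(cfg$sigma_rep, cfg$sigma_analyte, cfg$beta_sd, cfg$maintainer_sd)
  if (!is.null(cfg$sigma_y)) sds <- c(sds, cfg$sigma_y)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (is.null(cfg$sigma_y) &&
      (cfg$signal_r2 <= 0 || cfg$signal_r2 > 1)) {
    stop("signal_r2 must lie in (0, 1] when sigma_y is derived from it")
  }
  if (cfg$n_parents_pop1 < 2) stop("need >= 2 parents in pop1")
  if (cfg$n_rep < 1) stop("n_rep must be >= 1")
  structure(cfg, class = "synthetic_config")
}

# normalization formulas repeated here so the ground truth is planted on the
# exact quantities the modeling path sees (noise-free version)
.norm_autoscale <- function(raw) {
  v <- sweep(raw, 1, rowSums(raw), "/")
  ctr <- colMeans(v)
  scl <- apply(v, 2, stats::sd)
  scl[scl == 0] <- 1
  sweep(sweep(v, 2, ctr, "-"), 2, scl, "/")
}

#' Generate a synthetic two-population study with known ground truth
#'
#' See [synthetic_config()] for the generative model. The returned phenotype
#' table is constructed so that [compute_bph()] recovers the planted BPH-YPP
#' exactly: every parent yields `base_ypp` in each replicate and the hybrid
#' yields `base_ypp * (1 + BPH-YPP)`.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle` with elements `metabolites`
#'   (raw [metabolite_matrix()] with replicates: parents, maintainer,
#'   profiled hybrids, QC), `design` ([cross_design()]), `phenotypes`
#'   ([phenotype_table()]), `truth` (planted analyte ids, effect vector,
#'   true signal per hybrid, shift vector, realized `sigma_y`) and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  p <- cfg$p

  analyte_ids <- sprintf("A%04d", seq_len(p))
  pop1_ids <- sprintf("P%02d", seq_len(cfg$n_parents_pop1))
  ril_ids <- sprintf("R%03d", seq_len(cfg$n_parents_pop2))
  cms_id <- "CMS_A"
  maint_id <- "CMS_B"
  parent_ids <- c(pop1_ids, ril_ids, cms_id)

  # latent-factor log-profiles with extra "heterosis program" factors
  # loading only on the planted modules
  L <- matrix(stats::rnorm(p * cfg$d, sd = 1 / sqrt(cfg$d)), p, cfg$d)
  planted <- sort(sample(p, cfg$s))
  # population divergence along a fixed direction disjoint from the planted
  # module, so population identity does not mimic the heterosis signal
  shift_dir <- stats::rnorm(p)
  shift_dir[planted] <- 0
  n_mod <- max(1L, min(cfg$n_modules, cfg$s))
  module_of <- rep(seq_len(n_mod), length.out = cfg$s)
  loading <- matrix(0, p, n_mod)
  a_j <- (1 + stats::rnorm(cfg$s, sd = cfg$module_loading_sd)) * cfg$beta_sd
  loading[cbind(planted, module_of)] <- a_j
  is_pop2 <- c(rep(FALSE, length(pop1_ids)), rep(TRUE, length(ril_ids) + 1))
  program <- matrix(stats::rnorm(length(parent_ids) * n_mod),
                    nrow = length(parent_ids))
  z_clean <- t(vapply(seq_along(parent_ids), function(i) {
    drop(L %*% stats::rnorm(cfg$d)) + drop(loading %*% program[i, ]) +
      (if (is_pop2[i]) cfg$delta * shift_dir else 0) +
      stats::rnorm(p, sd = cfg$sigma_analyte)
  }, numeric(p)))
  rownames(z_clean) <- parent_ids
  z_maint <- z_clean[cms_id, ] + stats::rnorm(p, sd = cfg$maintainer_sd)

  # log-normal raw abundances: per-analyte baseline spanning decades
  mu0 <- stats::rnorm(p, mean = log(100), sd = 1)
  to_raw <- function(z) exp(sweep(z * 0.2, 2, mu0, "+"))
  raw_clean <- to_raw(z_clean)

  # cross design: complete diallel (ordered pairs) + testcross to the CMS female
  pairs <- expand.grid(male = pop1_ids, female = pop1_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$female != pairs$male, c("female", "male")]
  design <- rbind(
    data.frame(hybrid_id = paste0("H1_", pairs$female, "x", pairs$male),
               female = pairs$female, male = pairs$male,
               population = "pop1", stringsAsFactors = FALSE),
    data.frame(hybrid_id = paste0("H2_", ril_ids),
               female = cms_id, male = ril_ids,
               population = "pop2", stringsAsFactors = FALSE)
  )
  design <- cross_design(design)

  # planted signal on the normalized, autoscaled, noise-free parental
  # means; the module loadings double as the effect vector
  Zn <- .norm_autoscale(raw_clean)
  beta <- a_j
  pv_clean <- (Zn[design$female, planted, drop = FALSE] +
               Zn[design$male, planted, drop = FALSE]) / 2
  g <- drop(pv_clean %*% beta)
  if (stats::sd(g) > 0) {
    signal <- cfg$bph_mean + cfg$bph_signal_sd * (g - mean(g)) / stats::sd(g)
  } else {
    signal <- rep(cfg$bph_mean, length(g))
  }
  sigma_y <- if (!is.null(cfg$sigma_y)) cfg$sigma_y else {
    if (stats::sd(g) > 0) {
      cfg$bph_signal_sd * sqrt((1 - cfg$signal_r2) / cfg$signal_r2)
    } else {
      cfg$bph_signal_sd
    }
  }
  bph <- signal + stats::rnorm(length(signal), sd = sigma_y)
  for (tries in seq_len(100)) {
    bad <- bph <= -1
    if (!any(bad)) break
    warning(sum(bad), " infeasible BPH value(s) resampled")
    bph[bad] <- signal[bad] + stats::rnorm(sum(bad), sd = sigma_y)
  }
  if (any(bph <= -1)) stop("could not draw feasible BPH values")
  names(bph) <- design$hybrid_id

  # metabolite samples with replicates; profiled reciprocal hybrid pairs; QC
  profiled <- character(0)
  z_hyb <- NULL
  if (cfg$n_profiled_hybrid_pairs > 0) {
    n_pairs <- min(cfg$n_profiled_hybrid_pairs, floor(length(pop1_ids) / 2))
    fp <- pop1_ids[seq_len(n_pairs) * 2 - 1]
    mp <- pop1_ids[seq_len(n_pairs) * 2]
    profiled <- c(paste0("H1_", fp, "x", mp), paste0("H1_", mp, "x", fp))
    z_hyb <- (z_clean[c(fp, mp), , drop = FALSE] +
              z_clean[c(mp, fp), , drop = FALSE]) / 2 +
      matrix(stats::rnorm(length(profiled) * p, sd = cfg$sigma_analyte / 2),
             ncol = p)
    rownames(z_hyb) <- profiled
  }
  z_all <- rbind(z_clean, CMS_B = z_maint, z_hyb)
  roles <- c(rep("parent", length(parent_ids)), "maintainer",
             rep("hybrid", length(profiled)))
  pops <- c(ifelse(is_pop2, "pop2", "pop1"), "pop2",
            rep("pop1", length(profiled)))

  rows <- list(); meta <- list()
  for (i in seq_len(nrow(z_all))) {
    for (r in seq_len(cfg$n_rep)) {
      sid <- sprintf("%s_r%d", rownames(z_all)[i], r)
      zr <- z_all[i, ] + stats::rnorm(p, sd = cfg$sigma_rep)
      rows[[sid]] <- exp(zr * 0.2 + mu0)
      meta[[sid]] <- data.frame(sample_id = sid,
                                genotype = rownames(z_all)[i],
                                role = roles[i], population = pops[i],
                                replicate = r, stringsAsFactors = FALSE)
    }
  }
  if (cfg$n_qc > 0) {
    z_pool <- colMeans(z_all)
    for (r in seq_len(cfg$n_qc)) {
      sid <- sprintf("QC_r%d", r)
      zr <- z_pool + stats::rnorm(p, sd = cfg$sigma_rep / 2)
      rows[[sid]] <- exp(zr * 0.2 + mu0)
      meta[[sid]] <- data.frame(sample_id = sid, genotype = "QC_pool",
                                role = "QC", population = "QC",
                                replicate = r, stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- analyte_ids
  mm <- metabolite_matrix(values, sample_meta = do.call(rbind, meta),
                          state = "raw")

  phenos <- rbind(
    do.call(rbind, lapply(c(parent_ids, maint_id), function(g) {
      data.frame(genotype_id = g, ypp = rep(cfg$base_ypp, 3),
                 replicate = 1:3, year = "Y1", stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(design$hybrid_id, function(h) {
      data.frame(genotype_id = h, ypp = rep(cfg$base_ypp * (1 + bph[h]), 3),
                 replicate = 1:3, year = "Y1", stringsAsFactors = FALSE)
    }))
  )

  truth <- list(planted_ids = analyte_ids[planted],
                beta = stats::setNames(beta, analyte_ids[planted]),
                signal = stats::setNames(signal, design$hybrid_id),
                bph = bph,
                shift = cfg$delta * shift_dir,
                sigma_y = sigma_y)
  structure(list(metabolites = mm, design = design,
                 phenotypes = phenotype_table(phenos),
                 truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk in the package's file formats
#'
#' Emits the same delimited formats the real-data readers consume:
#' `metabolites.csv` + `sample_meta.csv`, `phenotypes.csv`, `design.csv`,
#' and `truth.json`. Files round-trip losslessly through
#' [read_metabolite_table()], [read_phenotypes()] and [read_design()].
#'
#' @param bundle a [generate_synthetic()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_metabolite_table(bundle$metabolites,
                         file.path(dir, "metabolites.csv"),
                         meta_path = file.path(dir, "sample_meta.csv"))
  utils::write.table(as.data.frame(bundle$phenotypes),
                     file.path(dir, "phenotypes.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$design),
                     file.path(dir, "design.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_ids = bundle$truth$planted_ids,
         beta = unname(bundle$truth$beta),
         signal = unname(bundle$truth$signal),
         bph = unname(bundle$truth$bph),
         sigma_y = bundle$truth$sigma_y,
         seed = bundle$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
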