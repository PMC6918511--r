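#' Predictability: Pearson correlation between observed and predicted values
#'
#' The predictability of a model on an evaluation set is the two-tailed
#' Pearson correlation r between observed and predicted BPH-YPP, with the
#' p-value from the t transform t = r sqrt((n - 2)/(1 - r^2)).
#'
#' @param observed,predicted numeric vectors of equal length >= 3, both with
#'   nonzero variance.
#' @return list with `r`, `p.value`, `n`.
#' @export
predictability <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need n >= 3 for a p-value")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance in observed or predicted values")
  }
  ct <- stats::cor.test(observed, predicted, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(observed))
}

#' Fit on a training set and predict every evaluation set
#'
#' Selects the number of latent factors by adjusted R-square
#' ([select_latent_factors()]), fits the model, predicts each evaluation set
#' and computes its predictability.
#'
#' @param X,y training predictive variables and BPH-YPP.
#' @param eval_sets named list of evaluation sets, each a list with `X`, `y`,
#'   `ids` (as produced by [assemble_training()]).
#' @param A_max latent-factor cap (default 17).
#' @return an object of class `prediction_result`: `model`, `A`, `adj_r2`
#'   (at the selected A), and `results` — a data frame per evaluation set
#'   with hybrid ids, observed, predicted — plus a `summary` data frame of
#'   (set, n, r, p).
#' @export
run_prediction <- function(X, y, eval_sets, A_max = 17L) {
  sel <- select_latent_factors(X, y, A_max = A_max)
  model <- sel$model
  results <- lapply(names(eval_sets), function(nm) {
    es <- eval_sets[[nm]]
    pred <- predict(model, es$X)
    data.frame(set = nm, hybrid_id = es$ids, observed = es$y,
               predicted = pred, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, results)
  summary <- do.call(rbind, lapply(names(eval_sets), function(nm) {
    rows <- results[results$set == nm, ]
    pr <- predictability(rows$observed, rows$predicted)
    data.frame(set = nm, n = pr$n, r = pr$r, p.value = pr$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(model = model, A = sel$A,
                 adj_r2 = sel$adj_r2[sel$A],
                 adj_r2_trace = sel$adj_r2,
                 results = results, summary = summary),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> A = %d latent factors, adjusted R2 = %.4f\n",
              x$A, x$adj_r2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep the number of predictive variables by VIP ranking
#'
#' The analyte ranking is computed once from the all-variable training model
#' using the chosen VIP statistic and then frozen while the count k varies.
#' For each k the model is refitted on the top-k analytes with latent
#' factors re-selected, and every evaluation set is scored. The best count
#' maximizes the mean predictability across evaluation sets.
#'
#' The default ranking statistic `"all"` is the multi-component VIP over all
#' fitted latent factors, which weights each factor by the y variance it
#' explains. The unweighted arithmetic mean of per-component VIPs
#' (`"mean_all"`) is retained as an option but is a poor ranking whenever
#' the signal is concentrated in few factors: analytes whose variance is
#' captured (and deflated away) by the informative early components receive
#' near-zero weights in the later noise components, so averaging over all
#' factors ranks exactly the informative analytes below the rest.
#'
#' @inheritParams run_prediction
#' @param grid strictly increasing variable counts (default 100, 200, ...,
#'   p plus p itself).
#' @param vip_mode `"all"` (explained-variance-weighted VIP over all
#'   factors), `"mean_all"`, `"component1"` or `"mean_first_m"`.
#' @param m number of leading factors when `vip_mode = "mean_first_m"`.
#' @return an object of class `sweep_result`: `curve` (data frame of count x
#'   evaluation-set predictability), `best_k`, `best_model`,
#'   `best_prediction`, `ranking` (analyte ids, VIP-descending), `vip_mode`.
#' @export
feature_sweep <- function(X, y, eval_sets, grid = NULL,
                          vip_mode = c("all", "mean_all", "component1",
                                       "mean_first_m"),
                          m = 3L, A_max = 17L) {
  vip_mode <- match.arg(vip_mode)
  p <- ncol(X)
  if (is.null(grid)) grid <- unique(c(seq(100L, p, by = 100L), p))
  grid <- as.integer(grid)
  if (length(grid) == 0) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (max(grid) > p) stop("grid values must not exceed p = ", p)

  full_sel <- select_latent_factors(X, y, A_max = A_max)
  full <- full_sel$model
  stat <- switch(vip_mode,
    all = vip(full),
    component1 = vip(full, components = 1),
    mean_first_m = vip(full, components = seq_len(min(m, full$A)),
                       mode = "mean"),
    mean_all = vip(full, mode = "mean")
  )
  ranking <- top_k_by_vip(stat, p)$ids

  rows <- list()
  best <- NULL
  for (k in grid) {
    ids_k <- ranking[seq_len(k)]
    pr <- run_prediction(X[, ids_k, drop = FALSE], y,
                         lapply(eval_sets, function(es) {
                           list(X = es$X[, ids_k, drop = FALSE],
                                y = es$y, ids = es$ids)
                         }),
                         A_max = A_max)
    row <- data.frame(k = k, A = pr$A, t(stats::setNames(pr$summary$r,
                                                         pr$summary$set)))
    rows[[length(rows) + 1]] <- row
    mean_r <- mean(pr$summary$r)
    if (is.null(best) || mean_r > best$mean_r) {
      best <- list(k = k, mean_r = mean_r, prediction = pr)
    }
  }
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, best_k = best$k,
                 best_model = best$prediction$model,
                 best_prediction = best$prediction,
                 ranking = ranking, vip_mode = vip_mode),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> vip_mode = %s, %d counts tried, best k = %d\n",
              x$vip_mode, nrow(x$curve), x$best_k))
  invisible(x)
}

#' Remove redundant (highly correlated) predictive variables
#'
#' Among the model's selected analytes, pairs whose training-set Pearson
#' correlation exceeds the threshold are pruned greedily: the pair of
#' largest |r| loses its lower-VIP member, repeating until no pair exceeds
#' the threshold or only `k_keep` analytes remain.
#'
#' @param model a fitted `pls_model` on the selected analytes.
#' @param X training matrix containing the model's analytes.
#' @param k_keep target number of analytes to retain.
#' @param threshold absolute-correlation threshold (default 0.9).
#' @return character vector of kept analyte ids.
#' @export
redundancy_filter <- function(model, X, k_keep, threshold = 0.9) {
  ids <- model$analyte_ids
  if (k_keep >= length(ids)) {
    warning("k_keep >= current selection size; nothing removed")
    return(ids)
  }
  v <- vip(model, mode = "mean")
  C <- abs(stats::cor(X[, ids, drop = FALSE]))
  diag(C) <- 0
  keep <- ids
  while (length(keep) > k_keep) {
    sub <- C[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    idx <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    drop_id <- pair[which.min(v[pair])]
    keep <- setdiff(keep, drop_id)
  }
  keep
}

#' Apply a frozen model to a new season's observations
#'
#' Pure application of a fitted model to new predictive variables and
#' phenotypes (no refitting): the across-year validation scenario. The model
#' object is not modified.
#'
#' @param model a `pls_model`.
#' @param pv_new predictive-variable object or matrix for the new hybrids
#'   (must contain all model analytes).
#' @param het_new `heterosis_table` with the new observed BPH-YPP.
#' @return a data frame of hybrid_id, observed, predicted with attributes
#'   `r`, `p.value`, `n`.
#' @export
validate_holdout <- function(model, pv_new, het_new) {
  Xn <- if (inherits(pv_new, "predictive_variables")) pv_new$values else pv_new
  bph <- stats::setNames(het_new$BPH_YPP, het_new$hybrid_id)
  ids <- intersect(rownames(Xn), names(bph))
  if (length(ids) < 3) stop("fewer than 3 hybrids with both profiles and phenotypes")
  pred <- predict(model, Xn[ids, , drop = FALSE])
  out <- data.frame(hybrid_id = ids, observed = unname(bph[ids]),
                    predicted = pred, stringsAsFactors = FALSE)
  pr <- predictability(out$observed, out$predicted)
  attr(out, "r") <- pr$r
  attr(out, "p.value") <- pr$p.value
  attr(out, "n") <- pr$n
  out
}
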