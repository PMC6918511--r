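#' Split hybrids into low- and high-heterosis subgroups
#'
#' Either by quantile cutpoints of BPH-YPP (default the 25th/75th
#' percentiles) or, when `n_per_group` is given, by taking exactly the n
#' lowest and n highest hybrids (the 50/72/100-per-group screening variants).
#'
#' @param het a `heterosis_table` from [compute_bph()] (or any data frame
#'   with hybrid_id and BPH_YPP).
#' @param low_q,high_q quantile fractions, 0 < low_q < high_q < 1.
#' @param n_per_group optional exact group size.
#' @return an object of class `subgroup_labels`: named character vector
#'   `labels` (hybrid_id -> "low"/"high"), `cuts`, `counts`.
#' @export
split_by_quantiles <- function(het, low_q = 0.25, high_q = 0.75,
                               n_per_group = NULL) {
  if (!(low_q > 0 && low_q < high_q && high_q < 1)) {
    stop("need 0 < low_q < high_q < 1")
  }
  bph <- stats::setNames(het$BPH_YPP, het$hybrid_id)
  n <- length(bph)
  if (!is.null(n_per_group)) {
    if (2 * n_per_group > n) {
      stop("2 * n_per_group = ", 2 * n_per_group, " exceeds population size ", n)
    }
    ord <- order(bph, names(bph))  # ties broken by hybrid id
    low_ids <- names(bph)[ord[seq_len(n_per_group)]]
    high_ids <- names(bph)[rev(ord)[seq_len(n_per_group)]]
    cuts <- c(low = max(bph[low_ids]), high = min(bph[high_ids]))
  } else {
    cuts <- stats::quantile(bph, c(low_q, high_q), names = FALSE)
    if (cuts[1] >= cuts[2]) stop("degenerate quantiles: low and high cutpoints coincide")
    cuts <- c(low = cuts[1], high = cuts[2])
    low_ids <- names(bph)[bph <= cuts["low"]]
    high_ids <- names(bph)[bph >= cuts["high"]]
  }
  labels <- c(stats::setNames(rep("low", length(low_ids)), low_ids),
              stats::setNames(rep("high", length(high_ids)), high_ids))
  structure(list(labels = labels, cuts = cuts,
                 counts = c(low = length(low_ids), high = length(high_ids))),
            class = "subgroup_labels")
}

# +1/-1 class coding shared by the PLS-DA routines
.plsda_response <- function(labels) {
  ifelse(labels == "high", 1, -1)
}

#' PLS discriminant analysis of two heterosis subgroups
#'
#' PLS1 regression of the class membership coded +1 (high) / -1 (low) on the
#' predictive variables; the same model object as [fit_pls()], so [vip()]
#' and score plots apply unchanged. The class coding is equivalent to any
#' affine recoding for VIP ranking purposes.
#'
#' @param X numeric matrix of predictive variables (rows named by hybrid id).
#' @param labels a [split_by_quantiles()] object or named character vector of
#'   "low"/"high".
#' @param A number of components (default 2, enough for score plots;
#'   screening uses component 1).
#' @return a `pls_model` with an extra `classes` element.
#' @export
fit_plsda <- function(X, labels, A = 2L) {
  if (inherits(labels, "subgroup_labels")) labels <- labels$labels
  labels <- labels[intersect(names(labels), rownames(X))]
  if (length(unique(labels)) < 2) stop("need both classes present")
  if (min(table(labels)) < 2) stop("need >= 2 members per class")
  Xs <- X[names(labels), , drop = FALSE]
  model <- fit_pls(Xs, .plsda_response(labels), A = A)
  model$classes <- labels
  model
}

#' Select the k analytes of largest VIP
#'
#' Returns the top-k analytes and the realized threshold (the k-th largest
#' VIP). Ties at the boundary are broken by analyte id order with a warning,
#' so repeated calls are deterministic.
#'
#' @param vip_vector named numeric vector of VIPs (from [vip()]).
#' @param k number of analytes to keep, 1 <= k <= p.
#' @return list with `ids` (selected analyte ids, VIP-descending) and
#'   `threshold`.
#' @export
top_k_by_vip <- function(vip_vector, k) {
  p <- length(vip_vector)
  if (k < 1 || k > p) stop("k must lie in 1..", p)
  ord <- order(-vip_vector, names(vip_vector))
  thr <- vip_vector[ord[k]]
  if (k < p && vip_vector[ord[k + 1]] == thr) {
    warning("VIP ties at the selection boundary (", format(thr),
            "); broken by analyte id order")
  }
  list(ids = names(vip_vector)[ord[seq_len(k)]], threshold = unname(thr))
}

# between/within separation of component-1 scores for two classes
.plsda_separation <- function(X, y) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(0)
  t1 <- drop(X %*% (w / nw))
  m1 <- mean(t1[y > 0]); m0 <- mean(t1[y < 0])
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  sp <- sqrt(((n1 - 1) * stats::var(t1[y > 0]) +
              (n0 - 1) * stats::var(t1[y < 0])) / (n1 + n0 - 2))
  if (sp == 0) return(Inf)
  abs(m1 - m0) / sp
}

#' Permutation test of PLS-DA class separation
#'
#' The observed statistic is the absolute difference of class-mean
#' component-1 scores divided by the pooled within-class standard deviation;
#' the null is built by refitting component 1 under label permutations. The
#' add-one estimator p = (1 + #\{perm >= obs\})/(1 + n_perm) is reported, so
#' p is always in (0, 1].
#'
#' @inheritParams fit_plsda
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `statistic`, `p.value`, `n_perm`, `null` (permuted
#'   statistics).
#' @export
permutation_test_plsda <- function(X, labels, n_perm = 1000L, seed = NULL) {
  if (inherits(labels, "subgroup_labels")) labels <- labels$labels
  if (n_perm < 100) stop("n_perm must be >= 100")
  labels <- labels[intersect(names(labels), rownames(X))]
  Xs <- X[names(labels), , drop = FALSE]
  Xs <- scale(Xs)
  Xs[is.na(Xs)] <- 0  # constant columns carry no class information
  y <- .plsda_response(labels)
  ys <- (y - mean(y)) / stats::sd(y)
  obs <- .plsda_separation(Xs, ys)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    .plsda_separation(Xs, sample(ys))
  }, numeric(1))
  list(statistic = obs,
       p.value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = n_perm, null = null)
}

#' Stratified cross-validation of PLS-DA
#'
#' Stratified k-fold CV over a grid of component counts, reporting
#' classification accuracy (sign of the prediction) and Q2
#' (1 - PRESS/SS_tot on the +1/-1 response).
#'
#' @inheritParams fit_plsda
#' @param folds number of folds (>= 2, at most the smaller class size).
#' @param A_grid component counts to evaluate.
#' @param seed optional integer seed for fold assignment.
#' @return data frame with columns A, accuracy, Q2.
#' @export
cross_validate_plsda <- function(X, labels, folds = 7L, A_grid = 1:5,
                                 seed = NULL) {
  if (inherits(labels, "subgroup_labels")) labels <- labels$labels
  labels <- labels[intersect(names(labels), rownames(X))]
  if (folds < 2) stop("folds must be >= 2")
  if (folds > min(table(labels))) {
    stop("folds exceed the smaller class size (", min(table(labels)), ")")
  }
  Xs <- X[names(labels), , drop = FALSE]
  y <- .plsda_response(labels)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  ss_tot <- sum((y - mean(y))^2)
  res <- lapply(A_grid, function(A) {
    pred <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      m <- suppressWarnings(fit_pls(Xs[tr, , drop = FALSE], y[tr], A = A))
      pred[!tr] <- predict(m, Xs[!tr, , drop = FALSE])
    }
    data.frame(A = A,
               accuracy = mean(sign(pred) == y),
               Q2 = 1 - sum((y - pred)^2) / ss_tot)
  })
  do.call(rbind, res)
}
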