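#' Fit a univariate partial least squares regression (NIPALS PLS1)
#'
#' NIPALS with X-deflation only (deflating y is redundant for a univariate
#' response). X columns and y are internally centered and scaled to unit
#' (n - 1) standard deviation from the training rows; the returned
#' coefficient vector `b` and constant `b0` are back-transformed to the
#' original input scale, so `X %*% b + b0` predicts on the scale of `y`.
#'
#' Per component a: weight w_a = X'y / ||X'y||, scores t_a = X w_a, X-loading
#' p_a = X't_a / t_a't_a, y-loading q_a = y't_a / t_a't_a, then X is deflated
#' by t_a p_a'. Components are truncated (with a warning) when X or the
#' covariance with y is numerically exhausted.
#'
#' @param X numeric matrix, n samples x p analytes, with column names.
#' @param y numeric response of length n with nonzero variance.
#' @param A number of latent factors requested (1 <= A <= min(n - 1, p)).
#' @param tol convergence tolerance on the weight vector (PLS1 converges in
#'   one pass analytically; the loop is kept for generality).
#' @param max_iter iteration cap per component.
#' @return an object of class `pls_model`: number of factors `A`, weights
#'   `W` (p x A), X-loadings `P_load`, y-loadings `q`, scores `T_scores`
#'   (n x A), coefficients `b`/`b0` on the input scale, standardization
#'   parameters, per-factor explained y variance, cumulative `R2`/`adj_R2`
#'   traces, single-component VIP matrix `vip_by_component`, `analyte_ids`.
#' @export
fit_pls <- function(X, y, A, tol = 1e-12, max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (stats::sd(y) == 0) stop("y has zero variance")
  A_cap <- min(n - 1, p)
  if (A < 1) stop("A must be >= 1")
  if (A > A_cap) {
    warning("A = ", A, " exceeds min(n - 1, p) = ", A_cap, "; truncated")
    A <- A_cap
  }

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1  # constant columns get zero weight anyway
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  Xs <- sweep(sweep(X, 2, x_center, "-"), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  W <- matrix(0, p, A)
  P_load <- matrix(0, p, A)
  T_scores <- matrix(0, n, A)
  q <- numeric(A)
  ss_y <- sum(ys^2)
  Xd <- Xs
  yd <- ys
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ss_y))) {
      warning("X exhausted after ", a_done, " components; A truncated")
      break
    }
    w <- w / nw
    for (it in seq_len(max_iter)) {
      t_a <- drop(Xd %*% w)
      w_new <- drop(crossprod(Xd, yd))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-24) {
      warning("degenerate scores after ", a_done, " components; A truncated")
      break
    }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    W[, a] <- w
    P_load[, a] <- p_a
    T_scores[, a] <- t_a
    q[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS component could be extracted")
  A <- a_done
  W <- W[, seq_len(A), drop = FALSE]
  P_load <- P_load[, seq_len(A), drop = FALSE]
  T_scores <- T_scores[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]

  # explained y variance per factor (scores are orthogonal)
  ss_comp <- q^2 * colSums(T_scores^2)
  r2 <- cumsum(ss_comp) / ss_y
  adj_r2 <- ifelse(n - seq_len(A) - 1 > 0,
                   1 - (1 - r2) * (n - 1) / (n - seq_len(A) - 1),
                   NA_real_)

  # b on the standardized scale: W (P'W)^{-1} q, then back-transform
  R <- crossprod(P_load, W)
  b_std <- drop(W %*% solve(R, q))
  b <- b_std * y_scale / x_scale
  b0 <- y_center - sum(x_center * b)

  w_norm2 <- colSums(W^2)  # = 1 by construction, kept for clarity
  vip_by_component <- sqrt(p) * abs(W) / rep(sqrt(w_norm2), each = p)
  rownames(vip_by_component) <- colnames(X)

  structure(list(
    A = A, W = W, P_load = P_load, q = q, T_scores = T_scores,
    b = stats::setNames(b, colnames(X)), b0 = b0,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    explained_y_variance = ss_comp / ss_y,
    R2 = r2, adj_R2 = adj_r2,
    vip_by_component = vip_by_component,
    analyte_ids = colnames(X), n = n, p = p
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent factors, %d analytes, n = %d\n",
              x$A, x$p, x$n))
  cat(sprintf("  cumulative R2 = %.4f, adjusted R2 = %.4f\n",
              x$R2[x$A], x$adj_R2[x$A]))
  invisible(x)
}

#' Select the number of latent factors by adjusted R-square
#'
#' Factors are extracted incrementally (up to `A_max`, default 17) and the
#' count maximizing the adjusted R-square of cumulative Y variance,
#' 1 - (1 - R2_a)(n - 1)/(n - a - 1), is returned together with the full
#' trace for plotting.
#'
#' @inheritParams fit_pls
#' @param A_max cap on the number of factors tried.
#' @return list with `A` (selected count), `adj_r2` and `r2` traces, and the
#'   model refitted at the selected `A`.
#' @export
select_latent_factors <- function(X, y, A_max = 17L) {
  n <- nrow(X)
  if (A_max < 1) stop("A_max must be >= 1")
  A_try <- min(A_max, n - 2, ncol(X))
  if (A_try < 1) stop("too few samples to fit any factor with a finite adjusted R2")
  full <- suppressWarnings(fit_pls(X, y, A = A_try))
  trace <- full$adj_R2
  if (all(is.na(trace))) stop("adjusted R2 undefined for every factor count")
  A_sel <- which.max(trace)
  model <- if (A_sel == full$A) full else fit_pls(X, y, A = A_sel)
  list(A = A_sel, adj_r2 = trace, r2 = full$R2, model = model)
}

#' Variable importance in projection (VIP)
#'
#' Two summaries over a component subset S are available. `"cumulative"` is
#' the standard multi-component VIP,
#' sqrt(p * sum_a SS_a (w_ja/||w_a||)^2 / sum_a SS_a) with
#' SS_a = q_a^2 t_a't_a, which reduces to the familiar component-1 VIP when
#' S = \{1\}. `"mean"` is the arithmetic mean over S of the single-component
#' VIPs, the statistic used for the "mean VIP of all latent factors" feature
#' screening.
#'
#' For any single component, sum_j VIP_j^2 = p.
#'
#' @param model a [fit_pls()] model.
#' @param components integer vector of components (default all fitted).
#' @param mode `"cumulative"` or `"mean"`.
#' @return named numeric vector of per-analyte VIPs.
#' @export
vip <- function(model, components = NULL, mode = c("cumulative", "mean")) {
  mode <- match.arg(mode)
  if (is.null(components)) components <- seq_len(model$A)
  if (length(components) == 0) stop("empty component set")
  if (any(components < 1 | components > model$A)) {
    stop("components must lie in 1..", model$A)
  }
  if (mode == "mean") {
    return(rowMeans(model$vip_by_component[, components, drop = FALSE]))
  }
  ss <- model$q[components]^2 *
    colSums(model$T_scores[, components, drop = FALSE]^2)
  wn <- sweep(model$W[, components, drop = FALSE], 2,
              sqrt(colSums(model$W[, components, drop = FALSE]^2)), "/")
  v <- sqrt(model$p * drop(wn^2 %*% ss) / sum(ss))
  stats::setNames(v, model$analyte_ids)
}

#' Predict from a fitted PLS model
#'
#' Applies the coefficient form yhat = X_new b + b0. Columns of `newdata`
#' are matched to the model's analytes by id; any missing or extra analytes
#' raise an error listing them.
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix with analyte ids as column names.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  ids <- colnames(newdata)
  missing <- setdiff(object$analyte_ids, ids)
  if (length(missing) > 0) {
    stop("newdata lacks model analyte(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  drop(newdata[, object$analyte_ids, drop = FALSE] %*% object$b) + object$b0
}

#' Serialize a PLS model to a JSON document
#'
#' Writes analyte ids, coefficients, constant, factor count, fit statistics
#' and VIP table as plain text so a frozen model can be reloaded and applied
#' to new seasons.
#'
#' @param model a `pls_model`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  doc <- list(
    A = model$A,
    analyte_ids = model$analyte_ids,
    b = unname(model$b), b0 = model$b0,
    R2 = model$R2, adj_R2 = model$adj_R2,
    vip_by_component = unname(model$vip_by_component),
    y_center = model$y_center, y_scale = model$y_scale,
    n = model$n, p = model$p
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a serialized PLS model for prediction
#'
#' Restores the fields needed by [predict.pls_model()] and [vip()] in
#' `"mean"` mode from a [write_pls_model()] document.
#'
#' @param path path written by [write_pls_model()].
#' @return a `pls_model` (prediction-capable subset).
#' @export
read_pls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  vbc <- matrix(unlist(doc$vip_by_component), ncol = doc$A,
                dimnames = list(doc$analyte_ids, NULL))
  structure(list(
    A = doc$A, analyte_ids = doc$analyte_ids,
    b = stats::setNames(doc$b, doc$analyte_ids), b0 = doc$b0,
    R2 = doc$R2, adj_R2 = doc$adj_R2,
    vip_by_component = vbc,
    y_center = doc$y_center, y_scale = doc$y_scale,
    n = doc$n, p = doc$p
  ), class = "pls_model")
}
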