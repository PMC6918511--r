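test_that("a perfect single-factor signal is fit exactly at A = 1", {
  set.seed(2)
  # centered orthogonal predictors, so internal standardization preserves
  # orthogonality and the single weight vector isolates the signal
  X <- qr.Q(qr(scale(matrix(stats::rnorm(40 * 6), 40, 6), scale = FALSE)))
  colnames(X) <- paste0("V", 1:6)
  y <- 2.5 * X[, 3] + 1
  m <- fit_pls(X, y, A = 1)
  expect_gt(m$R2[1], 1 - 1e-10)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
  for (seed in 1:5) {
    prob <- random_pls_problem(n = 30, p = 10, seed = seed)
    m <- fit_pls(prob$X, prob$y, A = 10)
    b_ols <- stats::coef(stats::lm(prob$y ~ prob$X))
    expect_lt(max(abs(m$b - b_ols[-1])), 1e-6)
    expect_lt(abs(m$b0 - b_ols[1]), 1e-6)
  }
})

test_that("row permutation leaves the fitted model unchanged", {
  prob <- random_pls_problem(n = 25, p = 8, seed = 3)
  m1 <- fit_pls(prob$X, prob$y, A = 4)
  set.seed(99); idx <- sample(25)
  m2 <- fit_pls(prob$X[idx, ], prob$y[idx], A = 4)
  expect_equal(m1$b, m2$b, tolerance = 1e-10)
  expect_equal(m1$b0, m2$b0, tolerance = 1e-10)
})

test_that("scores are orthogonal and deflation exhausts X at full rank", {
  prob <- random_pls_problem(n = 20, p = 6, seed = 4)
  m <- fit_pls(prob$X, prob$y, A = 6)
  G <- crossprod(m$T_scores)
  off <- abs(G[upper.tri(G)])
  norms <- sqrt(diag(G))
  expect_lt(max(off / tcrossprod(norms)[upper.tri(G)]), 1e-8)
  # residual X after rank(X) components
  Xs <- scale(prob$X)
  resid <- Xs - tcrossprod(m$T_scores, m$P_load)
  expect_lt(norm(resid, "F"), 1e-8 * norm(Xs, "F"))
})

test_that("explained Y variance is cumulative and non-decreasing", {
  prob <- random_pls_problem(n = 30, p = 12, seed = 5)
  m <- fit_pls(prob$X, prob$y, A = 8)
  expect_true(all(diff(m$R2) >= -1e-12))
  expect_true(all(m$explained_y_variance >= 0))
})

test_that("rescaling y rescales coefficients equivariantly", {
  prob <- random_pls_problem(n = 30, p = 12, seed = 6)
  m1 <- fit_pls(prob$X, prob$y, A = 3)
  m2 <- fit_pls(prob$X, 7 * prob$y, A = 3)
  expect_equal(7 * m1$b, m2$b, tolerance = 1e-10)
  expect_equal(7 * m1$b0, m2$b0, tolerance = 1e-10)
})

test_that("requesting too many factors truncates with a warning", {
  prob <- random_pls_problem(n = 8, p = 20, seed = 7)
  expect_warning(m <- fit_pls(prob$X, prob$y, A = 15), "truncated")
  expect_lte(m$A, 7)
  expect_error(fit_pls(prob$X, rep(1, 8), A = 2), "zero variance")
})

test_that("latent-factor selection maximizes adjusted R-square", {
  set.seed(8)
  X <- qr.Q(qr(scale(matrix(stats::rnorm(50 * 10), 50, 10), scale = FALSE)))
  colnames(X) <- paste0("V", 1:10)
  y <- X[, 1] - X[, 2]  # noiseless rank-1 signal in the weight direction
  sel <- select_latent_factors(X, y, A_max = 17)
  expect_equal(sel$A, 1L)
  expect_lte(length(sel$adj_r2), 17L)
  # oracle: the adjusted R2 formula at the selected A
  m <- fit_pls(X, y, A = sel$A)
  expect_equal(sel$adj_r2[sel$A],
               1 - (1 - m$R2[sel$A]) * (50 - 1) / (50 - sel$A - 1))
})

test_that("VIP matches a literal formula-by-loops oracle", {
  prob <- random_pls_problem(n = 20, p = 6, seed = 9)
  m <- fit_pls(prob$X, prob$y, A = 4)
  ss <- m$q^2 * colSums(m$T_scores^2)
  for (S in list(1L, 1:2, 1:4, c(2L, 4L))) {
    oracle <- numeric(6)
    for (j in 1:6) {
      num <- 0; den <- 0
      for (a in S) {
        wnorm <- m$W[, a] / sqrt(sum(m$W[, a]^2))
        num <- num + ss[a] * wnorm[j]^2
        den <- den + ss[a]
      }
      oracle[j] <- sqrt(6 * num / den)
    }
    expect_lt(max(abs(vip(m, components = S) - oracle)), 1e-10)
  }
  # mean mode is the arithmetic mean of single-component VIPs
  single <- vapply(1:4, function(a) vip(m, components = a), numeric(6))
  expect_equal(unname(vip(m, mode = "mean")), unname(rowMeans(single)))
  expect_error(vip(m, components = integer(0)), "empty")
})

test_that("every single-component VIP satisfies sum of squares = p", {
  for (seed in 1:4) {
    prob <- random_pls_problem(n = 15, p = 9, seed = seed)
    m <- fit_pls(prob$X, prob$y, A = 5)
    for (a in seq_len(m$A)) {
      expect_lt(abs(sum(vip(m, components = a)^2) - 9), 1e-8)
    }
  }
  # exchangeable identical columns give VIP = 1 everywhere
  x1 <- stats::rnorm(12)
  X <- matrix(rep(x1, 4), 12, 4, dimnames = list(NULL, paste0("V", 1:4)))
  m1 <- fit_pls(X, x1 + stats::rnorm(12, sd = 0.1), A = 1)
  expect_equal(unname(vip(m1, components = 1)), rep(1, 4), tolerance = 1e-10)
})

test_that("coefficient predictions agree with the factor decomposition", {
  prob <- random_pls_problem(n = 30, p = 10, seed = 10)
  m <- fit_pls(prob$X, prob$y, A = 5)
  # decomposition route: yhat = T q on the standardized scale
  yhat_dec <- drop(m$T_scores %*% m$q) * m$y_scale + m$y_center
  expect_lt(max(abs(predict(m, prob$X) - yhat_dec)), 1e-10)
  # predicting the column-mean row returns the training mean of y
  xbar <- matrix(colMeans(prob$X), 1, dimnames = list(NULL, colnames(prob$X)))
  expect_equal(drop(predict(m, xbar)), mean(prob$y), tolerance = 1e-10)
  # explicit dot-product oracle on new rows
  set.seed(123)
  Xn <- matrix(stats::rnorm(50 * 10), 50, 10,
               dimnames = list(NULL, colnames(prob$X)))
  oracle <- apply(Xn, 1, function(r) sum(r * m$b) + m$b0)
  expect_lt(max(abs(predict(m, Xn) - oracle)), 1e-12)
  expect_error(predict(m, Xn[, 1:5]), "lacks model analyte")
})

test_that("the fit agrees with an independent PLS implementation", {
  prob <- random_pls_problem(n = 30, p = 10, seed = 12)
  m <- fit_pls(prob$X, prob$y, A = 3)
  mo <- mixOmics::pls(prob$X, matrix(prob$y, ncol = 1), ncomp = 3,
                      mode = "regression", scale = TRUE)
  expect_lt(max(abs(predict(m, prob$X) -
                    predict(mo, prob$X)$predict[, 1, 3])), 1e-10)
  v_mo <- mixOmics::vip(mo)
  expect_lt(max(abs(vip(m, components = 1) - v_mo[, 1])), 1e-10)
  expect_lt(max(abs(vip(m) - v_mo[, 3])), 1e-10)
})

test_that("models survive serialization to JSON", {
  prob <- random_pls_problem(n = 20, p = 6, seed = 13)
  m <- fit_pls(prob$X, prob$y, A = 3)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, tmp)
  m2 <- read_pls_model(tmp)
  expect_equal(predict(m2, prob$X), predict(m, prob$X), tolerance = 1e-12)
  expect_equal(vip(m2, mode = "mean"), vip(m, mode = "mean"),
               tolerance = 1e-12)
})
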