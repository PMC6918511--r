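fake_het <- function(bph, ids = sprintf("h%03d", seq_along(bph))) {
  structure(data.frame(hybrid_id = ids, BPH_YPP = bph,
                       stringsAsFactors = FALSE),
            class = c("heterosis_table", "data.frame"))
}

test_that("quantile splitting counts hybrids correctly", {
  het <- fake_het(1:100)
  sg <- split_by_quantiles(het)
  expect_equal(unname(sg$counts), c(25L, 25L))
  expect_true(all(het$BPH_YPP[match(names(sg$labels)[sg$labels == "low"],
                                    het$hybrid_id)] <= sg$cuts["low"]))
  sg2 <- split_by_quantiles(het, n_per_group = 10)
  expect_equal(unname(sg2$counts), c(10L, 10L))
  expect_setequal(names(sg2$labels)[sg2$labels == "high"],
                  sprintf("h%03d", 91:100))
})

test_that("degenerate splits are rejected", {
  expect_error(split_by_quantiles(fake_het(rep(1, 10))), "degenerate")
  expect_error(split_by_quantiles(fake_het(1:10), n_per_group = 6),
               "exceeds population size")
})

test_that("PLS-DA separates a separable signal and respects label symmetry", {
  set.seed(31)
  n <- 40
  labels <- stats::setNames(rep(c("high", "low"), each = n / 2),
                            sprintf("h%03d", 1:n))
  X <- matrix(stats::rnorm(n * 10), n, 10,
              dimnames = list(names(labels), paste0("V", 1:10)))
  X[, 1] <- X[, 1] + ifelse(labels == "high", 3, -3)
  m <- fit_plsda(X, labels, A = 2)
  t1 <- m$T_scores[, 1]
  expect_gt(min(t1[labels == "high"]), max(t1[labels == "low"]))

  flipped <- stats::setNames(ifelse(labels == "high", "low", "high"),
                             names(labels))
  mf <- fit_plsda(X, flipped, A = 2)
  expect_equal(mf$W[, 1], -m$W[, 1], tolerance = 1e-10)
  expect_equal(vip(mf, components = 1), vip(m, components = 1),
               tolerance = 1e-10)
  expect_error(fit_plsda(X, labels[labels == "high"]), "both classes")
})

test_that("top-k VIP selection returns the k largest with threshold", {
  v <- stats::setNames(c(3, 2, 1), c("a", "b", "c"))
  sel <- top_k_by_vip(v, 2)
  expect_equal(sel$ids, c("a", "b"))
  expect_equal(sel$threshold, 2)
  sel_all <- top_k_by_vip(v, 3)
  expect_equal(sel_all$threshold, 1)
  expect_warning(top_k_by_vip(stats::setNames(c(2, 2, 1), c("a", "b", "c")), 1),
                 "ties")
  expect_error(top_k_by_vip(v, 0), "k must lie")
})

test_that("top-k selections are nested as k grows", {
  set.seed(32)
  v <- stats::setNames(stats::runif(50), sprintf("A%02d", 1:50))
  prev <- character(0)
  for (k in c(5, 12, 30, 50)) {
    cur <- top_k_by_vip(v, k)$ids
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("permutation p-values behave at both extremes", {
  set.seed(33)
  n <- 30
  labels <- stats::setNames(rep(c("high", "low"), each = n / 2),
                            sprintf("h%03d", 1:n))
  X_sig <- matrix(stats::rnorm(n * 8), n, 8,
                  dimnames = list(names(labels), paste0("V", 1:8)))
  X_sig[, 1:4] <- X_sig[, 1:4] + ifelse(labels == "high", 4, -4)
  res <- permutation_test_plsda(X_sig, labels, n_perm = 199, seed = 1)
  expect_equal(res$p.value, 1 / 200)  # minimum attainable

  X_null <- matrix(stats::rnorm(n * 8), n, 8,
                   dimnames = list(names(labels), paste0("V", 1:8)))
  res0 <- permutation_test_plsda(X_null, labels, n_perm = 199, seed = 1)
  expect_gt(res0$p.value, 0.05)
  expect_true(res0$p.value <= 1)
  # relabeling classes does not change the statistic
  flipped <- stats::setNames(ifelse(labels == "high", "low", "high"),
                             names(labels))
  res_f <- permutation_test_plsda(X_null, flipped, n_perm = 199, seed = 1)
  expect_equal(res_f$p.value, res0$p.value)
  expect_error(permutation_test_plsda(X_null, labels, n_perm = 50), ">= 100")
})

test_that("null permutation p-values are roughly uniform across seeds", {
  set.seed(34)
  n <- 24
  labels <- stats::setNames(rep(c("high", "low"), each = n / 2),
                            sprintf("h%03d", 1:n))
  ps <- vapply(1:20, function(s) {
    X <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(names(labels), paste0("V", 1:6)))
    permutation_test_plsda(X, labels, n_perm = 199, seed = s)$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("stratified cross-validation scores separable and random labels", {
  set.seed(35)
  n <- 40
  labels <- stats::setNames(rep(c("high", "low"), each = n / 2),
                            sprintf("h%03d", 1:n))
  X <- matrix(stats::rnorm(n * 2), n, 2,
              dimnames = list(names(labels), paste0("V", 1:2)))
  X[, 1] <- X[, 1] + ifelse(labels == "high", 10, -10)
  cv <- cross_validate_plsda(X, labels, folds = 5, A_grid = 1:2, seed = 1)
  expect_equal(cv$accuracy[cv$A == 1], 1)

  # random labels at n = 144: accuracy within binomial range of 0.5
  n2 <- 144
  set.seed(36)
  labels2 <- stats::setNames(sample(rep(c("high", "low"), each = n2 / 2)),
                             sprintf("h%03d", 1:n2))
  X2 <- matrix(stats::rnorm(n2 * 20), n2, 20,
               dimnames = list(names(labels2), paste0("V", 1:20)))
  cv2 <- cross_validate_plsda(X2, labels2, folds = 6, A_grid = 1, seed = 2)
  expect_lt(abs(cv2$accuracy - 0.5), 0.15)
  expect_true(all(cv2$Q2 <= 1))
  expect_error(cross_validate_plsda(X, labels, folds = 30), "class size")
})
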