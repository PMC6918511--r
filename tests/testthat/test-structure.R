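test_that("PCA explains collinear data with one component", {
  t_ <- seq(-2, 2, length.out = 9)
  X <- cbind(A = 2 * t_ + 1, B = -t_ + 3, C = 0.5 * t_)
  rownames(X) <- paste0("s", 1:9)
  pc <- run_pca(X)
  expect_gt(pc$explained[1], 1 - 1e-12)
})

test_that("PCA spectrum is rotation invariant and matches eigenvalues", {
  set.seed(41)
  X <- matrix(stats::rnorm(15 * 8), 15, 8,
              dimnames = list(paste0("s", 1:15), paste0("V", 1:8)))
  pc <- run_pca(X)
  Q <- qr.Q(qr(matrix(stats::rnorm(64), 8, 8)))
  XQ <- X %*% Q
  rownames(XQ) <- rownames(X); colnames(XQ) <- colnames(X)
  pc_rot <- run_pca(XQ)
  expect_equal(pc$explained, pc_rot$explained, tolerance = 1e-10)

  # brute-force eigen oracle for the explained-variance spectrum
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(pc$explained, ev / sum(ev), tolerance = 1e-8)
  # reconstruction of the centered data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(max(abs(tcrossprod(pc$scores, pc$loadings) - Xc)), 1e-8)
  # invariants of the spectrum
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
})

test_that("PCA sign convention orients the dominant loading positive", {
  set.seed(42)
  X <- matrix(stats::rnorm(12 * 5), 12, 5,
              dimnames = list(paste0("s", 1:12), paste0("V", 1:5)))
  pc <- run_pca(X)
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  expect_warning(run_pca(X, n_components = 50), "truncated")
})

test_that("interval core selection walks the PC1 ordering", {
  scores <- matrix(c(6, 5, 4, 3, 2, 1), ncol = 1,
                   dimnames = list(paste0("h", 1:6), NULL))
  pc <- structure(list(scores = scores, sample_ids = rownames(scores)),
                  class = "pca_result")
  cs <- select_core(pc, rownames(scores), k = 2)
  expect_equal(cs$core, c("h1", "h3", "h5"))
  expect_equal(cs$noncore, c("h2", "h4", "h6"))
  cs1 <- select_core(pc, rownames(scores), k = 1)
  expect_equal(cs1$core, cs1$ordering)  # degenerate identity
  cs_off <- select_core(pc, rownames(scores), k = 2, offset = 1)
  expect_equal(cs_off$core, c("h2", "h4", "h6"))
  expect_error(select_core(pc, character(0), k = 2), "empty population")
  expect_error(select_core(pc, rownames(scores), k = 2, offset = 2), "offset")
})

test_that("one of every three of 306 hybrids gives 102 cores", {
  set.seed(43)
  ids <- sprintf("h%03d", 1:306)
  scores <- matrix(stats::rnorm(306), ncol = 1, dimnames = list(ids, NULL))
  pc <- structure(list(scores = scores, sample_ids = ids),
                  class = "pca_result")
  cs <- select_core(pc, ids, k = 3)
  expect_equal(length(cs$core), 102L)
  expect_equal(sort(c(cs$core, cs$noncore)), sort(ids))
  # deterministic: repeated calls return identical sets
  expect_identical(cs$core, select_core(pc, ids, k = 3)$core)
})

test_that("training assembly pools cores and holds out noncores", {
  set.seed(44)
  ids1 <- paste0("a", 1:6); ids2 <- paste0("b", 1:6)
  mk_pc <- function(ids) structure(
    list(scores = matrix(seq_along(ids), ncol = 1,
                         dimnames = list(ids, NULL)),
         sample_ids = ids), class = "pca_result")
  cs1 <- select_core(mk_pc(ids1), ids1, k = 2, population = "p1")
  cs2 <- select_core(mk_pc(ids2), ids2, k = 2, population = "p2")
  all_ids <- c(ids1, ids2)
  pv <- list(values = matrix(stats::rnorm(12 * 4), 12, 4,
                             dimnames = list(all_ids, paste0("A", 1:4))))
  het <- data.frame(hybrid_id = all_ids, BPH_YPP = stats::rnorm(12))
  tr <- assemble_training(list(cs1, cs2), pv, het)
  expect_equal(length(tr$training_ids), 6L)
  expect_length(intersect(tr$training_ids,
                          unlist(lapply(tr$eval, `[[`, "ids"))), 0L)
  expect_equal(tr$y, het$BPH_YPP[match(tr$training_ids, het$hybrid_id)])
  expect_error(assemble_training(list(cs1, cs2), pv, het[1:6, ]),
               "lacking BPH")
  cs2b <- cs2; cs2b$population <- "p1"
  expect_error(assemble_training(list(cs1, cs2b), pv, het), "distinct")
})

test_that("Ward clustering joins coincident parents first and exports Newick", {
  v <- rbind(p1 = c(0, 0), p2 = c(0, 0), p3 = c(5, 5))
  colnames(v) <- c("A1", "A2")
  hc <- cluster_parents(toy_parent_mm(v))
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("p1", "p2"))
  expect_equal(length(hc$labels), 3L)
  expect_error(cluster_parents(toy_parent_mm(v[1:2, ])), "at least 3")

  b <- small_bundle()
  parents <- average_replicates(filter_samples(b$metabolites, roles = "parent"))
  hc2 <- cluster_parents(parents)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  export_newick(hc2, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, rownames(parents$values))
})
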