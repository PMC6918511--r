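test_that("delimited tables parse in both orientations", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,A1,A2", "s1,1,2", "s2,3,4", "s3,5,6"), tmp)
  mm <- read_metabolite_table(tmp)
  expect_s3_class(mm, "metabolite_matrix")
  expect_equal(dim(mm$values), c(3L, 2L))
  expect_equal(mm$state, "raw")
  expect_equal(mm$values["s2", "A2"], 4)

  tmp_t <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,s1,s2,s3", "A1,1,3,5", "A2,2,4,6"), tmp_t)
  mm_t <- read_metabolite_table(tmp_t, orientation = "rows-are-analytes")
  expect_identical(mm_t$values, mm$values)
})

test_that("malformed tables are rejected with coordinates", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,A1", "s1,1", "s1,2"), dup)
  expect_error(read_metabolite_table(dup), "duplicate ids")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,A1,A2", "s1,1,x", "s2,3,4"), bad)
  expect_error(read_metabolite_table(bad), "row 's1', column 'A2'")

  nas <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,A1,A2", "s1,1,", "s2,3,4"), nas)
  expect_error(read_metabolite_table(nas), "missing value")
  imputed <- read_metabolite_table(nas, na_action = "half_min")
  expect_equal(imputed$values["s1", "A2"], 2)  # half the analyte minimum
})

test_that("replicate averaging equals a group-by-mean oracle", {
  mm <- toy_raw_mm()
  avg <- average_replicates(mm)
  expect_equal(avg$state, "replicate_averaged")
  expect_equal(unname(avg$values["g1", ]), c(3, 4, 3))  # mean of [2,4],[6,2],[2,4]
  expect_equal(unname(avg$values["g2", ]), c(1, 3, 6))  # single replicate

  set.seed(11)
  v <- matrix(stats::runif(8 * 5), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("A", 1:5)))
  meta <- data.frame(sample_id = rownames(v),
                     genotype = rep(paste0("g", 1:4), each = 2),
                     role = "parent", population = "pop1",
                     replicate = rep(1:2, 4), stringsAsFactors = FALSE)
  avg2 <- average_replicates(metabolite_matrix(v, meta, state = "raw"))
  for (g in paste0("g", 1:4)) {
    oracle <- colMeans(v[meta$genotype == g, , drop = FALSE])
    expect_equal(unname(avg2$values[g, ]), unname(oracle))
  }
})

test_that("conflicting replicate metadata is an error", {
  mm <- toy_raw_mm()
  mm$sample_meta$population[2] <- "pop2"
  expect_error(average_replicates(mm), "conflicting")
})

test_that("sum normalization and autoscaling satisfy their invariants", {
  v <- rbind(s1 = c(1, 3), s2 = c(2, 2))
  colnames(v) <- c("A1", "A2")
  mm <- toy_parent_mm(v)
  sn <- sum_normalize(mm, row_constant = 1)
  expect_equal(unname(sn$values["s1", ]), c(0.25, 0.75))
  expect_equal(unname(rowSums(sn$values)), c(1, 1))

  as2 <- autoscale(sn)
  # two-sample columns standardize to exactly {-s, +s} with mean 0, sd 1
  expect_equal(unname(colMeans(as2$values)), c(0, 0))
  expect_equal(unname(apply(as2$values, 2, sd)), c(1, 1))

  set.seed(3)
  v10 <- matrix(stats::runif(10 * 5, 1, 5), 10, 5,
                dimnames = list(paste0("s", 1:10), paste0("A", 1:5)))
  out <- normalize_metabolites(toy_parent_mm(v10))
  expect_lt(max(abs(colMeans(out$values))), 1e-9)
  expect_lt(max(abs(apply(out$values, 2, sd) - 1)), 1e-9)
  # scaling parameters retained and consistent with an independent recompute
  sn10 <- sum_normalize(toy_parent_mm(v10))
  expect_equal(out$scaling$center, colMeans(sn10$values))
  expect_equal(out$scaling$scale, apply(sn10$values, 2, sd))
  # standardization is idempotent: re-standardizing changes nothing
  again <- scale(out$values)
  expect_lt(max(abs(again - out$values)), 1e-9)
})

test_that("degenerate rows and columns are handled", {
  v <- rbind(s1 = c(0, 0), s2 = c(1, 1))
  colnames(v) <- c("A1", "A2")
  expect_error(sum_normalize(toy_parent_mm(v)), "summing to zero")

  # A1 is a fixed fraction of every row, so it is constant after sum
  # normalization and must be dropped
  v2 <- rbind(s1 = c(1, 1, 2), s2 = c(2, 3, 3), s3 = c(3, 4, 5))
  colnames(v2) <- c("A1", "A2", "A3")
  sn <- sum_normalize(toy_parent_mm(v2), row_constant = 4)
  expect_warning(as3 <- autoscale(sn), "all-constant")
  expect_false("A1" %in% colnames(as3$values))
  expect_true(all(c("A2", "A3") %in% colnames(as3$values)))
})

test_that("matrices round-trip through write and read", {
  b <- small_bundle()
  tmp <- withr::local_tempfile(fileext = ".csv")
  meta_tmp <- withr::local_tempfile(fileext = ".csv")
  write_metabolite_table(b$metabolites, tmp, meta_path = meta_tmp)
  back <- read_metabolite_table(tmp, meta = meta_tmp)
  expect_equal(back$values, b$metabolites$values, tolerance = 1e-12)
  expect_equal(back$sample_meta$role, b$metabolites$sample_meta$role)
})

test_that("phenotype and design readers validate their contracts", {
  ph <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype_id,ypp", "g1,50", "g1,52", "g2,40"), ph)
  pt <- read_phenotypes(ph)
  expect_equal(unname(genotype_means(pt)["g1"]), 51)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype_id,ypp", "g1,-5"), bad)
  expect_error(read_phenotypes(bad), "positive")

  de <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hybrid_id,female,male,population",
               "h1,g1,g2,pop1", "h2,g2,g1,pop1", "h3,g1,g3,pop1"), de)
  d <- read_design(de)
  expect_equal(nrow(d), 3L)
  expect_error(validate_design(d, c("g1", "g2")), "g3")
})

test_that("QC samples can be excluded before normalization", {
  b <- small_bundle()
  flt <- filter_samples(b$metabolites, roles = "parent")
  expect_true(all(flt$sample_meta$role == "parent"))
  expect_error(filter_samples(b$metabolites, roles = "nonexistent"),
               "no samples left")
})
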