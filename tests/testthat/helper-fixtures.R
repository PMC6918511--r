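# shared fixtures, built in code; the expensive default-scale workflow is
# computed once per test run and memoised

.fixture_cache <- new.env(parent = emptyenv())

default_workflow <- function() {
  if (is.null(.fixture_cache$wf)) {
    b <- generate_synthetic(synthetic_config(seed = 1))
    .fixture_cache$bundle <- b
    .fixture_cache$wf <- run_workflow(b)
  }
  list(bundle = .fixture_cache$bundle, wf = .fixture_cache$wf)
}

# a small, fast study for structural tests
small_bundle <- function(seed = 7, ...) {
  args <- list(n_parents_pop1 = 8L, n_parents_pop2 = 20L, p = 120L, s = 20L,
               d = 4L, n_profiled_hybrid_pairs = 2L, n_qc = 2L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_synthetic(do.call(synthetic_config, args))
}

# toy metabolite matrix with explicit replicate structure
toy_raw_mm <- function() {
  v <- rbind(
    g1_r1 = c(2, 6, 2),
    g1_r2 = c(4, 2, 4),
    g2_r1 = c(1, 3, 6)
  )
  colnames(v) <- c("A1", "A2", "A3")
  meta <- data.frame(
    sample_id = rownames(v),
    genotype = c("g1", "g1", "g2"),
    role = "parent", population = "pop1",
    replicate = c(1L, 2L, 1L), stringsAsFactors = FALSE
  )
  metabolite_matrix(v, sample_meta = meta, state = "raw")
}

# parent matrix in a chosen state for transform tests; rows sum to a common
# constant so the sum_normalized state is valid
toy_parent_mm <- function(values, state = "replicate_averaged") {
  meta <- data.frame(sample_id = rownames(values), genotype = rownames(values),
                     role = "parent", population = "pop1", replicate = 1L,
                     stringsAsFactors = FALSE)
  metabolite_matrix(values, sample_meta = meta, state = state)
}

toy_design <- function(hybrids, females, males, population = "pop1") {
  cross_design(data.frame(hybrid_id = hybrids, female = females, male = males,
                          population = population, stringsAsFactors = FALSE))
}

random_pls_problem <- function(n = 30, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  list(X = X, y = stats::rnorm(n))
}
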