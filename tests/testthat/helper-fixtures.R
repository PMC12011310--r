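# shared fixtures and memoised heavy computations for the suite

bivar_subject <- function(n1 = 6, pmiss = 0, pattern = "dropout", seed = 1L) {
  bt <- build_times_Z(n1, pmiss, pattern, seed)
  subject_design("s1", list(
    marker_design("m1", bt$times, bt$Z1, bt$Z1),
    marker_design("m2", bt$times[bt$keep2], bt$Z2, bt$Z2)))
}

random_psd <- function(n, seed, ridge = 0.1) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    A <- matrix(rnorm(n * n), n)
    A %*% t(A) / n + ridge * diag(n)
  })
}

# full default bivariate grid (both missingness patterns), computed once per
# test run and shared by the grid-level checks
.cache <- new.env(parent = emptyenv())

full_default_grid <- function() {
  if (is.null(.cache$grid)) {
    spec <- rbind(default_grid_spec(pattern = "random"),
                  default_grid_spec(pattern = "dropout"))
    .cache$grid <- run_grid(spec, n_pattern_draws = 20, base_seed = 20260901L)
  }
  .cache$grid
}

# seeded synthetic cohort used by the recovery and case-study-pattern checks
recovery_fixture <- function() {
  if (is.null(.cache$recovery)) {
    cohort <- simulate_cohort(cohort_spec(m = 2000, seed = 20260902L))
    est <- suppressWarnings(estimate_components(cohort))
    .cache$recovery <- list(cohort = cohort, est = est)
  }
  .cache$recovery
}
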