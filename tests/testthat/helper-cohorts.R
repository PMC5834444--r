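# Shared fixtures. The two default-settings phantom cohorts are expensive
# (full pipeline over 60 whole-body scans), so they are computed lazily
# once per test run and reused by every test that needs them.

.fixture_env <- new.env(parent = emptyenv())

# a reduced grid keeps per-scan cost low for unit tests; all other
# generator settings are the defaults
small_spec <- function(...) {
  phantom_spec(grid = c(80, 50, 170), ...)
}

phantom_cohorts <- function() {
  if (is.null(.fixture_env$cohorts)) {
    spec <- phantom_spec()
    a <- generate_cohort(spec, 30, seed = 101)
    b <- generate_cohort(spec, 30, seed = 202)
    .fixture_env$cohorts <- list(
      A = process_cohort(a, feature_set = "full62"),
      B = process_cohort(b, feature_set = "full62"))
  }
  .fixture_env$cohorts
}

cross_experiment <- function(feature_set = "core28", n_trees = 50) {
  key <- paste0("xp_", feature_set, "_", n_trees)
  if (is.null(.fixture_env[[key]])) {
    co <- phantom_cohorts()
    .fixture_env[[key]] <- cross_cohort_experiment(
      co$A, co$B, feature_set = feature_set, n_trees = n_trees, seed = 7)
  }
  .fixture_env[[key]]
}
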