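# Shared fixtures, built in code. The small bundle is generated once per
# test run and reused read-only by several test files.

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 300L, n_variants = 600L, seed = 11L)
      dir <- file.path(tempdir(), "loadscore-bundle-small")
      cache <<- generate_dataset(cfg, dir)
    }
    cache
  }
})

# A clean bundle: reference always ancestral, no mislabeling, hard calls.
clean_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 250L, n_variants = 400L,
                        p_ref_ancestral = 1, ancestral_mislabel_rate = 0,
                        imputation_noise_sd = 0, seed = 21L)
      dir <- file.path(tempdir(), "loadscore-bundle-clean")
      cache <<- generate_dataset(cfg, dir)
    }
    cache
  }
})

read_tsv_for_test <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

with_seed_for_test <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Wrap a plain numeric vector as a load_score for scan-level tests.
as_load_score <- function(values, sample_ids, subset = "all") {
  ls <- loadscore::compute_load(matrix(values, ncol = 1,
                                       dimnames = list(sample_ids, "v1")),
                                weights = 1, subset = subset)
  ls
}
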