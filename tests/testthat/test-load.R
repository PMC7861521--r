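test_that("the weighted load reproduces worked examples", {
  D <- matrix(c(2, 1, 0), nrow = 1,
              dimnames = list("s1", c("v1", "v2", "v3")))
  ls <- compute_load(D, c(1.0, 2.5, 9.9))
  expect_equal(ls$raw, 4.5)
  expect_equal(compute_load(D, c(1, 1, 1), mask = rep(FALSE, 3))$raw, 0)
  expect_equal(compute_burden(D)$raw, 3)
  expect_error(compute_load(D, c(1, 2)), "length")
})

test_that("load, burden and non-reference counts match brute-force oracles", {
  set.seed(42)
  n <- 50; m <- 200
  D <- matrix(stats::runif(n * m, 0, 2), n, m,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("v%03d", 1:m)))
  w <- stats::rnorm(m)
  mask <- stats::runif(m) < 0.8
  # independent elementwise double-loop accumulation
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (mask[j]) oracle[i] <- oracle[i] + D[i, j] * w[j]
    }
  }
  expect_lt(max(abs(compute_load(D, w, mask)$raw - oracle)), 1e-9)
  burden_oracle <- numeric(n)
  for (i in seq_len(n)) burden_oracle[i] <- sum(D[i, mask])
  expect_lt(max(abs(compute_burden(D, mask)$raw - burden_oracle)), 1e-9)
  expect_lt(max(abs(count_non_reference(D, mask) - burden_oracle)), 1e-9)
  expect_equal(count_non_reference(matrix(c(0, 0, 0), 1)), c(0))
  expect_equal(count_non_reference(matrix(c(2, 2), 1)), c(4))
})

test_that("coding and non-coding loads add to the genome-wide load", {
  b <- small_bundle()
  alt <- b$data$alt_dosages
  rec <- b$data$records
  gw <- build_load(alt, rec, subset = "all")
  cod <- build_load(alt, rec, subset = "coding")
  ncod <- build_load(alt, rec, subset = "noncoding")
  expect_lt(max(abs(cod$raw + ncod$raw - gw$raw)), 1e-9)
  expect_identical(attr(cod, "subset"), "coding")
})

test_that("stratified loads partition the total and respect boundaries", {
  set.seed(9)
  n <- 30; m <- 80
  D <- matrix(stats::runif(n * m, 0, 2), n, m)
  daf <- stats::runif(m, 0.001, 0.999)
  daf[1] <- 0.05                      # exact boundary case
  score <- stats::runif(m, 0, 10)
  total <- compute_load(D, score)
  strata <- stratified_loads(D, daf, score,
                             daf_intervals = list(c(0, 0.05), c(0.05, 1)),
                             score_intervals = list(c(0, 5), c(5, 10)))
  expect_identical(length(strata), 4L)
  summed <- Reduce(`+`, lapply(strata, function(s) s$raw))
  expect_lt(max(abs(summed - total$raw)), 1e-9)
  # DAF = 0.05 belongs to the [0.05, ...) stratum
  hi <- strata[["DAF[0.05,1)&score(0,5]"]]
  expect_true(attr(hi, "n_variants") >=
                sum(daf >= 0.05 & daf < 1 & score > 0 & score <= 5))
  lo_names <- grep("DAF\\[0,0.05\\)", names(strata), value = TRUE)
  n_lo <- sum(vapply(strata[lo_names], attr, integer(1), "n_variants"))
  expect_identical(n_lo, sum(daf < 0.05))
  # a single all-covering stratum equals the plain load
  one <- stratified_loads(D, daf, score,
                          daf_intervals = list(c(0, 1)),
                          score_intervals = list(c(0, 10)))
  expect_lt(max(abs(one[[1]]$raw - total$raw)), 1e-9)
  expect_error(stratified_loads(D, daf, score,
                                daf_intervals = list(c(0, 0.5), c(0.4, 1))),
               "overlap")
  expect_error(stratified_loads(D, daf, score), "at least one")
})

test_that("load scores scale with the weights and survive REF/ALT swaps", {
  b <- small_bundle()
  alt <- b$data$alt_dosages
  rec <- b$data$records
  base <- build_load(alt, rec)
  # scale equivariance
  rec2 <- rec
  rec2$phyloP3 <- rec$phyloP * 3
  # positivity mask is unchanged by a positive scale factor
  tripled <- build_load(alt, rec2, weight_column = "phyloP3")
  expect_equal(tripled$raw, base$raw * 3, tolerance = 1e-9)
  # swap REF/ALT at a random subset, keeping the ancestral base consistent
  set.seed(5)
  swap <- stats::runif(nrow(rec)) < 0.5
  rec_sw <- rec
  rec_sw$ref[swap] <- rec$alt[swap]
  rec_sw$alt[swap] <- rec$ref[swap]
  alt_sw <- alt
  alt_sw[, swap] <- 2 - alt[, swap]
  swapped <- build_load(alt_sw, rec_sw)
  expect_lt(max(abs(swapped$raw - base$raw)), 1e-9)
})

test_that("computed loads equal the truth when orientations are clean", {
  b <- clean_bundle()
  ls <- build_load(b$data$alt_dosages, b$data$records, subset = "all")
  expect_lt(max(abs(ls$raw - b$data$truth_samples$true_load)), 1e-9)
  # with mislabeling, agreement degrades but stays strongly correlated
  bm <- small_bundle()
  lsm <- build_load(bm$data$alt_dosages, bm$data$records, subset = "all")
  r <- stats::cor(lsm$raw, bm$data$truth_samples$true_load)
  expect_gt(r, 0.9)
  expect_lt(r, 1)
})

test_that("missing dosages are mean-imputed or rejected on request", {
  set.seed(6)
  D <- matrix(stats::runif(40, 0, 2), 8, 5)
  D[1, 2] <- NA; D[5, 4] <- NA
  w <- stats::runif(5)
  Di <- D
  for (j in 1:5) Di[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  expect_equal(compute_load(D, w)$raw, as.numeric(Di %*% w),
               tolerance = 1e-12)
  expect_error(compute_load(D, w, na_action = "error"), "missing")
})

test_that("the KS normality check behaves on normal and bimodal loads", {
  ok <- 0L
  for (r in 1:20) {
    x <- with_seed_for_test(300 + r, stats::rnorm(1e4, mean = 50, sd = 4))
    if (normality_check(x)$p_value > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
  mixture <- with_seed_for_test(7, c(stats::rnorm(5e3, 0), stats::rnorm(5e3, 6)))
  expect_lt(normality_check(mixture)$p_value, 1e-6)
  nc <- normality_check(with_seed_for_test(8, stats::rnorm(500, 3, 2)))
  z <- (with_seed_for_test(8, stats::rnorm(500, 3, 2)) - nc$mean) / nc$sd
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  expect_error(normality_check(rep(1, 100)), "zero-variance")
  expect_error(normality_check(stats::rnorm(10)), "n >= 30")
})
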