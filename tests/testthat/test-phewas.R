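make_pheno <- function(name, values) {
  data.frame(sample_id = sprintf("S%05d", seq_along(values)),
             stats::setNames(list(values), name), check.names = FALSE,
             stringsAsFactors = FALSE)
}

test_that("phenotype retention rules hit every stated boundary", {
  n <- 6000
  phecode_500 <- c(rep(1L, 500), rep(0L, n - 500))
  phecode_501 <- c(rep(1L, 501), rep(0L, n - 501))
  cont_4999 <- c(stats::rnorm(4999), rep(NA, n - 4999))
  cont_5000 <- c(stats::rnorm(5000), rep(NA, n - 5000))
  bin_ok <- c(rep(1L, 600), rep(0L, 700), rep(NA, n - 1300))
  bin_ok2 <- c(rep(1L, 600), rep(0L, n - 600))
  phen <- data.frame(sample_id = sprintf("S%05d", 1:n),
                     phecode_500, phecode_501, cont_4999, cont_5000,
                     bin_ok, bin_ok2, stringsAsFactors = FALSE)
  types <- c(phecode_500 = "phecode", phecode_501 = "phecode",
             cont_4999 = "continuous", cont_5000 = "continuous",
             bin_ok = "binary", bin_ok2 = "binary")
  kept <- filter_phenotypes(phen, types)
  expect_false("phecode_500" %in% kept)  # cases must exceed 500 strictly
  expect_true("phecode_501" %in% kept)
  expect_false("cont_4999" %in% kept)    # n = 4,999 < 5,000
  expect_true("cont_5000" %in% kept)
  expect_false("bin_ok" %in% kept)       # n = 1,300 < 5,000
  expect_true("bin_ok2" %in% kept)       # 600 cases, 5,400 controls, n ok
  sm <- attr(kept, "summary")
  expect_identical(sm$n_cases[sm$name == "phecode_500"], 500L)
})

test_that("a noiseless linear phenotype is recovered exactly", {
  n <- 400L
  load <- stats::rnorm(n)
  y <- 2 + 0.5 * load
  res <- run_association(load, y, "continuous", inverse_normal = FALSE)
  expect_true(res$converged)
  expect_equal(res$beta, 0.5, tolerance = 1e-6)
  expect_lt(res$p_value, 1e-12)
  expect_identical(res$n, n)
})

test_that("binary, ordinal and multinomial fits recover injected effects", {
  set.seed(21)
  n <- 2e4
  load <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 - 0.1 * load))
  res <- run_association(load, y, "binary")
  se_expected <- 1 / sqrt(n * mean(y) * (1 - mean(y)))
  expect_lt(abs(res$beta - (-0.1)), 3 * se_expected)
  expect_true(res$converged)

  lat <- -0.4 * load + stats::rnorm(n)
  yo <- findInterval(lat, c(-1, 0, 1)) + 1L
  ro <- run_association(load, yo, "ordered_categorical")
  expect_lt(ro$beta, 0)
  expect_lt(ro$p_value, 1e-6)

  yn <- sample(c("a", "b", "c"), n, TRUE)
  rn <- run_association(load, yn, "unordered_categorical")
  expect_true(is.na(rn$beta))          # multinomial reports an LRT p only
  expect_gt(rn$p_value, 1e-4)          # null phenotype: no tiny p expected
  yn2 <- ifelse(load > 1, sample(c("a", "b"), n, TRUE, c(0.8, 0.2)),
                sample(c("a", "b", "c"), n, TRUE))
  rn2 <- run_association(load, yn2, "unordered_categorical")
  expect_lt(rn2$p_value, 1e-6)
})

test_that("complete-case n and missingness handling are correct", {
  set.seed(3)
  n <- 600L
  load <- stats::rnorm(n)
  y <- 0.2 * load + stats::rnorm(n)
  y[1:50] <- NA
  covar <- data.frame(age = stats::rnorm(n))
  covar$age[51:60] <- NA
  res <- run_association(load, y, "continuous", covar)
  expect_identical(res$n, n - 60L)
})

test_that("the scan crosses scores with phenotypes deterministically", {
  set.seed(31)
  n <- 800
  cov <- simulate_covariates(n, seed = 1)
  load <- stats::rnorm(n)
  specs <- c(list(pheno_spec("cont_a", "continuous", -0.2)),
             phecode_specs(4, n_affected = 1, effect_of_load = -0.4,
                           prevalence = 0.3))
  ph <- simulate_phenotypes(load, cov, specs, seed = 2)
  ls1 <- as_load_score(load, cov$sample_id, subset = "all")
  ls2 <- as_load_score(stats::rnorm(n), cov$sample_id, subset = "coding")
  res <- phewas_scan(list(all = ls1, coding = ls2), ph$phenotypes, ph$types,
                     cov, min_cases = 50L, min_n = 500L)
  expect_identical(nrow(res), 10L)                  # 2 scores x 5 phenotypes
  expect_identical(res$score_kind, rep(c("all", "coding"), each = 5))
  expect_identical(res$phenotype[1:5], sort(res$phenotype[1:5]))
  res2 <- phewas_scan(list(all = ls1, coding = ls2), ph$phenotypes, ph$types,
                      cov, min_cases = 50L, min_n = 500L)
  expect_identical(res, res2)                       # deterministic rerun
  # the truly associated score attains the smaller p on its phenotype
  p_all <- res$p_value[res$score_kind == "all" & res$phenotype == "phecode_001"]
  p_cod <- res$p_value[res$score_kind == "coding" & res$phenotype == "phecode_001"]
  expect_lt(p_all, p_cod)
  bad <- data.frame(sample_id = "nope", x = 1)
  expect_error(phewas_scan(list(all = ls1), bad, c(x = "continuous")),
               "overlap")
})

test_that("Bonferroni thresholds follow alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 539), 0.05 / 539)
  expect_equal(signif(bonferroni_threshold(0.05, 539), 3), 9.28e-5)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("sensitivity modes reproduce their degenerate identities", {
  b <- clean_bundle()                    # every REF is ancestral
  d <- b$data
  types <- as.data.frame(d$types)
  out <- sensitivity_scan(d$alt_dosages, d$records, d$phenotypes, types,
                          d$covariates, subset = "all",
                          modes = c("default", "ref_ancestral"),
                          min_cases = 10L, min_n = 100L)
  # restriction to ref == ancestral is vacuous here
  expect_identical(out$default, out$ref_ancestral)
  # identical weight columns give bitwise-identical scans
  rec2 <- d$records
  rec2$phyloPNH <- rec2$phyloP
  out2 <- sensitivity_scan(d$alt_dosages, rec2, d$phenotypes, types,
                           d$covariates, subset = "all",
                           modes = c("default", "alt_weight"),
                           min_cases = 10L, min_n = 100L)
  expect_identical(out2$default, out2$alt_weight)
  expect_error(sensitivity_scan(d$alt_dosages, d$records[
    setdiff(names(d$records), "phyloPNH")], d$phenotypes, types,
    d$covariates, modes = "alt_weight"), "phyloPNH")
  # an extra covariate uncorrelated with load and phenotype barely moves betas
  set.seed(12)
  cov2 <- d$covariates
  cov2$noise_cov <- stats::rnorm(nrow(cov2))
  ls <- build_load(d$alt_dosages, d$records, subset = "all")
  r1 <- phewas_scan(list(all = ls), d$phenotypes, types, d$covariates,
                    min_cases = 10L, min_n = 100L)
  r2 <- phewas_scan(list(all = ls), d$phenotypes, types, cov2,
                    min_cases = 10L, min_n = 100L)
  ok <- !is.na(r1$beta)
  expect_true(all(abs(r1$beta[ok] - r2$beta[ok]) <= r1$se[ok]))
})

test_that("nonref-covariate mode runs and labels its table", {
  b <- clean_bundle()
  d <- b$data
  out <- sensitivity_scan(d$alt_dosages, d$records, d$phenotypes,
                          as.data.frame(d$types), d$covariates,
                          subset = "all", modes = "nonref_covar",
                          min_cases = 10L, min_n = 100L)
  expect_true(all(out$nonref_covar$converged |
                    is.na(out$nonref_covar$beta)))
  expect_identical(sort(unique(out$nonref_covar$score_kind)), "all")
})
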