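test_that("neutral site frequencies match the analytic 1/x CDF", {
  n_ind <- 1000
  x_min <- 1 / (2 * n_ind)
  f <- sample_site_frequencies(rep(0, 1e5), n_ind, seed = 42)
  expect_true(all(f >= x_min & f <= 1 - x_min))
  # independent oracle: CDF of the truncated 1/x density in closed form
  xs <- exp(seq(log(x_min), log(1 - x_min), length.out = 500))
  analytic <- log(xs / x_min) / log((1 - x_min) / x_min)
  sup_dist <- max(abs(stats::ecdf(f)(xs) - analytic))
  expect_lt(sup_dist, 0.02)
})

test_that("stronger purifying selection shifts frequencies toward rare", {
  f0 <- sample_site_frequencies(rep(0, 1e4), 1000, seed = 1)
  f50 <- sample_site_frequencies(rep(50, 1e4), 1000, seed = 2)
  expect_lt(mean(f50), mean(f0))
  # mean DAF non-increasing across the default mixture components
  mix <- default_gamma_mixture()
  means <- vapply(seq_len(nrow(mix)), function(i) {
    mean(sample_site_frequencies(rep(mix$gamma[i], 5e3), 1000, seed = 100 + i))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_error(sample_site_frequencies(c(0.1, -1), 1000), "non-negative")
  expect_error(sample_site_frequencies(rep(0, 10), 1000, grid_points = 50),
               "grid_points")
})

test_that("frequency sampling is deterministic under a fixed seed", {
  g <- c(rep(0, 50), rep(5, 50))
  expect_identical(sample_site_frequencies(g, 500, seed = 9),
                   sample_site_frequencies(g, 500, seed = 9))
})

test_that("conservation-like scores track selection strength", {
  g <- c(0, 1, 5, 20, 80)
  s <- assign_scores(g, noise_sd = 0)
  expect_true(all(diff(s) >= 0))
  expect_true(all(assign_scores(rep(0, 10), noise_sd = 0) == 0))
  expect_true(all(s >= -5 & s <= 10))
  mix <- default_gamma_mixture()
  gam <- with_seed_for_test(2, {
    comp <- sample.int(nrow(mix), 1e4, TRUE, prob = mix$weight)
    mix$gamma[comp]
  })
  sc <- assign_scores(gam, noise_sd = 1, seed = 3)
  expect_gt(stats::cor(sc, gam, method = "spearman"), 0.5)
  expect_error(assign_scores(c(1, 2), noise_sd = -1), "noise_sd")
})

test_that("genotype simulation respects HWE and reports INFO", {
  n <- 1e4
  g <- simulate_genotypes(0.5, n, seed = 5)
  se_mean <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(g$dosage) - 1.0), 3 * se_mean)
  props <- tabulate(g$hard + 1L, nbins = 3) / n
  for (k in 1:3) {
    p <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(props[k] - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_equal(simulate_genotypes(c(0.1, 0.4), 200, seed = 1)$info, c(1, 1))
  gn <- simulate_genotypes(c(0.3, 0.4), 500, imputation_noise_sd = 0.1, seed = 2)
  expect_true(all(gn$info > 0 & gn$info < 1))
  expect_true(all(gn$dosage >= 0 & gn$dosage <= 2))
  expect_error(simulate_genotypes(c(0.5, 1), 10), "inside")
})

test_that("allele labelling honours ancestral probabilities", {
  a1 <- assign_alleles(200, p_ref_ancestral = 1, mislabel_rate = 0, seed = 1)
  expect_true(all(a1$ancestral == a1$ref))
  expect_true(all(a1$ref != a1$alt))
  a0 <- assign_alleles(200, p_ref_ancestral = 0, mislabel_rate = 0, seed = 2)
  expect_true(all(a0$ancestral == a0$alt))
  n <- 1e4
  am <- assign_alleles(n, p_ref_ancestral = 0.5, mislabel_rate = 0.1, seed = 3)
  frac <- mean(am$ancestral != am$ancestral_true)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("phenotype simulation produces the configured structure", {
  n <- 1e5
  load <- stats::rnorm(n)
  specs <- list(
    pheno_spec("null_c", "continuous", effect_of_load = 0),
    pheno_spec("eff_c", "continuous", effect_of_load = -0.1,
               noise_sd = sqrt(1 - 0.01)),
    pheno_spec("rare_b", "binary", effect_of_load = 0, prevalence = 0.02))
  ph <- simulate_phenotypes(load, covariates = NULL, specs = specs, seed = 7)
  # independence by construction when effect_of_load = 0
  expect_lt(abs(stats::cor(ph$phenotypes$null_c, load)), 3 / sqrt(n))
  # realized R^2 of the load term within 20% relative error of 0.01
  r2 <- stats::cor(ph$phenotypes$eff_c, load)^2
  expect_lt(abs(r2 - 0.01) / 0.01, 0.20)
  prev <- mean(ph$phenotypes$rare_b)
  expect_lt(abs(prev - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  expect_error(pheno_spec("bad", "binary", prevalence = 1.2), "prevalence")
  # ordinal and nominal types produce the declared domains
  specs2 <- list(pheno_spec("o", "ordered_categorical", -0.2,
                            cutpoints = c(-1, 0, 1)),
                 pheno_spec("u", "unordered_categorical", 0, n_classes = 3))
  ph2 <- simulate_phenotypes(stats::rnorm(500), specs = specs2, seed = 8)
  expect_true(all(ph2$phenotypes$o %in% 1:4))
  expect_true(all(ph2$phenotypes$u %in% paste0("class_", 1:3)))
})

test_that("dataset bundles are deterministic and round-trip exactly", {
  cfg <- sim_config(n_individuals = 120L, n_variants = 200L, seed = 33L)
  d1 <- file.path(tempdir(), "det-a")
  d2 <- file.path(tempdir(), "det-b")
  b1 <- generate_dataset(cfg, d1)
  b2 <- generate_dataset(cfg, d2)
  for (nm in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[nm]])),
                     unname(tools::md5sum(b2$paths[[nm]])), label = nm)
  }
  # the dosage TSV round-trips bit-exactly
  mat <- read_dosage_tsv(b1$paths$genotypes)
  expect_identical(mat, b1$data$alt_dosages)
})

test_that("an empty panel still yields schema-valid files", {
  cfg <- sim_config(n_individuals = 50L, n_variants = 0L, seed = 3L)
  b <- generate_dataset(cfg, file.path(tempdir(), "empty-panel"))
  ann <- read_tsv_for_test(b$paths$annotations)
  expect_identical(nrow(ann), 0L)
  expect_true(all(c("chrom", "pos", "ref", "alt", "ancestral", "phyloP") %in%
                    names(ann)))
  truth <- read_tsv_for_test(b$paths$truth_samples)
  expect_identical(nrow(truth), 50L)
  expect_true(all(truth$true_load == 0))
})

test_that("the truth file load equals compute_load under true orientations", {
  b <- small_bundle()
  ann <- read_annotations(b$paths$annotations)
  alt <- read_dosage_tsv(b$paths$genotypes)
  tv <- read_tsv_for_test(b$paths$truth_variants)
  ts <- read_tsv_for_test(b$paths$truth_samples)
  ori <- ifelse(tv$alt_is_derived_true, "alt_is_derived", "ref_is_derived")
  D <- derived_dosage(alt, ori)
  ls <- compute_load(D, ann$phyloP, mask = tv$in_truth_mask)
  expect_lt(max(abs(ls$raw - ts$true_load)), 1e-9)
})

test_that("VCF bundles are read back consistently", {
  cfg <- sim_config(n_individuals = 40L, n_variants = 60L, seed = 13L)
  b <- generate_dataset(cfg, file.path(tempdir(), "vcf-bundle"),
                        format = "vcf")
  mat <- read_vcf_dosages(b$paths$genotypes)
  expect_equal(dim(mat), dim(b$data$alt_dosages))
  expect_equal(unname(mat), unname(b$data$alt_dosages), tolerance = 1e-12)
  expect_identical(rownames(mat), rownames(b$data$alt_dosages))
})
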