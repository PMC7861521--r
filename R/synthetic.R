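#' Default mixture of population-scaled selection coefficients
#'
#' The synthetic cohort draws each variant's scaled purifying-selection
#' strength gamma from a small point-mass mixture. The default places half
#' the variants in an effectively neutral class and spreads the remainder
#' over weak to strong purifying selection, which is the regime in which a
#' conservation-score-weighted load is informative while an unweighted
#' burden is dominated by neutral alleles.
#'
#' @return A data.frame with columns `weight` and `gamma`.
#' @export
default_gamma_mixture <- function() {
  data.frame(weight = c(0.50, 0.25, 0.15, 0.08, 0.02),
             gamma  = c(0, 1, 5, 20, 80))
}

#' Draw derived allele frequencies from the stationary density under selection
#'
#' Frequencies are sampled by inverse-CDF interpolation on a log-spaced grid
#' from the stationary (sojourn) density of the diffusion approximation for
#' an additive deleterious variant with scaled selection strength gamma,
#' f(x) proportional to
#' exp(-gamma x) (1 - exp(-gamma (1 - x))) / (x (1 - x) (1 - exp(-gamma)))
#' for gamma > 0, with the neutral limit f(x) proportional to 1/x as
#' gamma -> 0; larger gamma shifts mass toward rare alleles. The support
#' is truncated to [x_min, 1 - x_min] with x_min = 1 / (2 n_individuals),
#' i.e. frequencies resolvable in a diploid sample of that size.
#'
#' @param gamma Non-negative scaled selection coefficient, one per variant.
#' @param n_individuals Diploid sample size; sets the truncation x_min.
#' @param grid_points Number of grid points for the inverse-CDF (>= 100).
#' @param seed Integer seed or NULL to use the current RNG stream.
#' @return Numeric vector of derived allele frequencies in (0, 1).
#' @export
sample_site_frequencies <- function(gamma, n_individuals,
                                    grid_points = 2048L, seed = NULL) {
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  if (grid_points < 100) stop("`grid_points` must be >= 100", call. = FALSE)
  if (length(gamma) == 0L) return(numeric(0))
  x_min <- 1 / (2 * n_individuals)
  grid <- exp(seq(log(x_min), log(1 - x_min), length.out = grid_points))
  with_seed(seed, {
    out <- numeric(length(gamma))
    for (g in unique(gamma)) {
      idx <- which(gamma == g)
      dens <- if (g < 1e-12) {
        1 / grid
      } else {
        exp(-g * grid) * -expm1(-g * (1 - grid)) /
          (grid * (1 - grid) * (-expm1(-g)))
      }
      area <- diff(grid) * (dens[-1] + dens[-grid_points]) / 2
      cdf <- c(0, cumsum(area))
      cdf <- cdf / cdf[grid_points]
      u <- stats::runif(length(idx))
      out[idx] <- stats::approx(cdf, grid, xout = u, rule = 2,
                                ties = "ordered")$y
    }
    out
  })
}

#' Assign conservation-like scores tracking selection strength
#'
#' Scores are an affine transform of log1p(gamma) plus Gaussian noise,
#' clipped to a phyloP-like range (default [-5, 10]). With the default
#' scale, neutral variants sit near zero (half of them negative, as for
#' phyloP) and strongly selected variants approach the upper bound, so score
#' rank tracks selection strength in expectation.
#'
#' @param gamma Non-negative scaled selection coefficients.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed or NULL.
#' @param scale Slope of the affine map from log1p(gamma) to score units.
#' @param range Length-2 clipping range of the score.
#' @return Numeric score vector, same length as `gamma`.
#' @export
assign_scores <- function(gamma, noise_sd = 1, seed = NULL,
                          scale = 2.5, range = c(-5, 10)) {
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  with_seed(seed, {
    raw <- scale * log1p(gamma)
    if (noise_sd > 0) raw <- raw + stats::rnorm(length(gamma), 0, noise_sd)
    pmin(pmax(raw, range[1]), range[2])
  })
}

#' Draw a selection architecture: classes and per-variant gamma
#'
#' Variants are labelled coding with probability `coding_fraction`; coding
#' variants receive a functional class (synonymous/missense/lof), non-coding
#' variants are "other". Every variant draws a base gamma from the mixture;
#' missense and loss-of-function variants get an additive gamma shift so the
#' class ordering of selection strength (lof > missense > synonymous) holds.
#'
#' @param n_variants Number of variants.
#' @param coding_fraction Proportion of variants labelled coding, in [0, 1].
#' @param gamma_mixture data.frame(weight, gamma); weights must sum to 1.
#' @param coding_class_probs Named probabilities for synonymous/missense/lof.
#' @param gamma_shift Named additive gamma shifts for missense and lof.
#' @param seed Integer seed or NULL.
#' @return data.frame(gamma, region_class, functional_class).
#' @export
selection_architecture <- function(n_variants,
                                   coding_fraction = 0.015,
                                   gamma_mixture = default_gamma_mixture(),
                                   coding_class_probs = c(synonymous = 0.50,
                                                          missense = 0.45,
                                                          lof = 0.05),
                                   gamma_shift = c(missense = 5, lof = 30),
                                   seed = NULL) {
  check_prob(coding_fraction, "coding_fraction")
  if (abs(sum(gamma_mixture$weight) - 1) > 1e-8) {
    stop("gamma mixture weights must sum to 1", call. = FALSE)
  }
  if (any(gamma_mixture$gamma < 0)) {
    stop("gamma mixture components must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    coding <- stats::runif(n_variants) < coding_fraction
    fclass <- rep("other", n_variants)
    if (any(coding)) {
      fclass[coding] <- sample(names(coding_class_probs), sum(coding),
                               replace = TRUE, prob = coding_class_probs)
    }
    comp <- sample.int(nrow(gamma_mixture), n_variants, replace = TRUE,
                       prob = gamma_mixture$weight)
    gamma <- gamma_mixture$gamma[comp]
    gamma[fclass == "missense"] <- gamma[fclass == "missense"] +
      gamma_shift[["missense"]]
    gamma[fclass == "lof"] <- gamma[fclass == "lof"] + gamma_shift[["lof"]]
    data.frame(gamma = gamma,
               region_class = ifelse(coding, "coding", "noncoding"),
               functional_class = fclass)
  })
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Hard genotypes are Binomial(2, freq) per individual and variant; optional
#' additive Gaussian noise clipped to [0, 2] produces fractional dosages that
#' mimic imputation. The per-variant INFO score is reported as the squared
#' correlation between hard and noisy dosage (1 when the noisy dosage equals
#' the hard genotype, 0 when the hard genotype column is monomorphic so no
#' correlation is defined).
#'
#' @param freqs Derived (or ALT) allele frequencies, strictly inside (0, 1).
#' @param n_individuals Number of diploid individuals.
#' @param imputation_noise_sd SD of the additive dosage noise (0 = hard calls).
#' @param seed Integer seed or NULL.
#' @return list(dosage = n x m matrix, hard = integer matrix, info = vector).
#' @export
simulate_genotypes <- function(freqs, n_individuals,
                               imputation_noise_sd = 0, seed = NULL) {
  if (length(freqs) && (any(freqs <= 0) || any(freqs >= 1))) {
    stop("`freqs` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (imputation_noise_sd < 0) {
    stop("`imputation_noise_sd` must be >= 0", call. = FALSE)
  }
  m <- length(freqs)
  n <- n_individuals
  with_seed(seed, {
    hard <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)),
                   nrow = n, ncol = m)
    if (imputation_noise_sd > 0 && m > 0) {
      dosage <- pmin(pmax(hard + stats::rnorm(n * m, 0, imputation_noise_sd),
                          0), 2)
      info <- vapply(seq_len(m), function(j) {
        if (stats::sd(hard[, j]) == 0 || stats::sd(dosage[, j]) == 0) {
          return(0)
        }
        stats::cor(hard[, j], dosage[, j])^2
      }, numeric(1))
    } else {
      dosage <- hard * 1.0
      info <- rep(1, m)
    }
    list(dosage = dosage, hard = hard, info = info)
  })
}

#' Assign REF/ALT/ancestral allele labels
#'
#' With probability `p_ref_ancestral` the reference allele is the ancestral
#' allele (so the derived allele is ALT); otherwise the derived allele is REF.
#' With probability `mislabel_rate` the recorded ancestral label is swapped
#' relative to truth; the true orientation is retained in separate columns so
#' downstream polarization can be validated against ground truth.
#'
#' @param n_variants Number of variants (a frequency vector may be passed; its
#'   length is used).
#' @param p_ref_ancestral Probability that REF is the ancestral allele.
#' @param mislabel_rate Probability the recorded ancestral label is wrong.
#' @param seed Integer seed or NULL.
#' @return data.frame(ref, alt, ancestral, ancestral_true,
#'   alt_is_derived_true, mislabeled).
#' @export
assign_alleles <- function(n_variants, p_ref_ancestral = 0.9,
                           mislabel_rate = 0, seed = NULL) {
  check_prob(p_ref_ancestral, "p_ref_ancestral")
  check_prob(mislabel_rate, "mislabel_rate")
  n <- if (length(n_variants) > 1L) length(n_variants) else as.integer(n_variants)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    ref_anc <- stats::runif(n) < p_ref_ancestral
    ancestral_true <- ifelse(ref_anc, ref, alt)
    mislab <- stats::runif(n) < mislabel_rate
    ancestral <- ifelse(mislab, ifelse(ref_anc, alt, ref), ancestral_true)
    data.frame(ref = ref, alt = alt, ancestral = ancestral,
               ancestral_true = ancestral_true,
               alt_is_derived_true = ref_anc,
               mislabeled = mislab)
  })
}

#' Declare one phenotype for the synthetic cohort
#'
#' @param name Phenotype name (column name in the phenotype table).
#' @param type One of continuous, ordered_categorical, unordered_categorical,
#'   binary, phecode.
#' @param effect_of_load Effect of the standardized true load on the
#'   phenotype (continuous scale) or on the liability/latent scale.
#' @param prevalence Target case prevalence in (0, 1), binary/phecode only.
#' @param cutpoints Latent-scale cutpoints, ordered_categorical only.
#' @param n_classes Number of classes (>= 2), unordered_categorical only.
#' @param noise_sd SD of the phenotype/latent Gaussian noise.
#' @return A `pheno_spec` list.
#' @export
pheno_spec <- function(name, type = PHENOTYPE_TYPES, effect_of_load = 0,
                       prevalence = NULL, cutpoints = NULL, n_classes = NULL,
                       noise_sd = 1) {
  type <- match.arg(type)
  if (type %in% c("binary", "phecode")) {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1) {
      stop("binary/phecode specs need `prevalence` strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  if (type == "ordered_categorical" && (is.null(cutpoints) || length(cutpoints) < 1)) {
    stop("ordered_categorical specs need `cutpoints`", call. = FALSE)
  }
  if (type == "unordered_categorical" && (is.null(n_classes) || n_classes < 2)) {
    stop("unordered_categorical specs need `n_classes` >= 2", call. = FALSE)
  }
  structure(list(name = name, type = type, effect_of_load = effect_of_load,
                 prevalence = prevalence, cutpoints = cutpoints,
                 n_classes = n_classes, noise_sd = noise_sd),
            class = "pheno_spec")
}

#' Batch of phecode-like binary phenotype specs
#'
#' @param n Number of phecode-like phenotypes.
#' @param n_affected How many (the first `n_affected`) carry a load effect.
#' @param effect_of_load Liability-scale load effect for affected phenotypes.
#' @param prevalence Case prevalence shared by all phecodes.
#' @param noise_sd Liability noise SD.
#' @param prefix Name prefix.
#' @return List of `pheno_spec`.
#' @export
phecode_specs <- function(n, n_affected = 0, effect_of_load = -0.1,
                          prevalence = 0.15, noise_sd = 1,
                          prefix = "phecode_") {
  lapply(seq_len(n), function(i) {
    pheno_spec(sprintf("%s%03d", prefix, i), "phecode",
               effect_of_load = if (i <= n_affected) effect_of_load else 0,
               prevalence = prevalence, noise_sd = noise_sd)
  })
}

#' Default phenotype panel for the synthetic cohort
#'
#' A small panel covering all five phenotype types: two continuous traits
#' (one load-associated, one null), an ordinal and a nominal trait, one
#' common binary trait, and ten phecode-like phenotypes of which two carry a
#' weak negative load effect — the direction the deleterious-load model
#' predicts for fitness-related traits.
#'
#' @return List of `pheno_spec`.
#' @export
default_phenotype_specs <- function() {
  c(list(
    pheno_spec("body_mass_like", "continuous", effect_of_load = -0.10,
               noise_sd = sqrt(1 - 0.10^2)),
    pheno_spec("null_continuous", "continuous", effect_of_load = 0),
    pheno_spec("activity_ordinal", "ordered_categorical",
               effect_of_load = -0.05, cutpoints = c(-1, 0, 1)),
    pheno_spec("diet_nominal", "unordered_categorical",
               effect_of_load = 0, n_classes = 3),
    pheno_spec("binary_trait", "binary", effect_of_load = -0.10,
               prevalence = 0.30)),
    phecode_specs(10, n_affected = 2, effect_of_load = -0.10,
                  prevalence = 0.15))
}

#' Simulate stand-in cohort covariates
#'
#' Emits columns with the roles of the usual PheWAS covariates: age, sex,
#' genotyping chip, assessment centre (categorical) and four principal
#' component stand-ins. All are independent of the genotypes.
#'
#' @param n_individuals Number of individuals.
#' @param seed Integer seed or NULL.
#' @return data.frame with a `sample_id` column.
#' @export
simulate_covariates <- function(n_individuals, seed = NULL) {
  n <- n_individuals
  with_seed(seed, data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    age = sample(40:69, n, replace = TRUE),
    sex = stats::rbinom(n, 1, 0.5),
    chip = stats::rbinom(n, 1, 0.9),
    centre = sample(sprintf("centre_%d", 1:5), n, replace = TRUE),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n)
  ))
}

#' Simulate typed phenotypes with a configurable dependence on true load
#'
#' Continuous phenotypes are effect * z(load) + covariate effects + noise.
#' Binary and phecode phenotypes use a liability threshold placed at the
#' empirical quantile that achieves the target prevalence. Ordinal
#' phenotypes cut the same latent variable at fixed cutpoints; nominal
#' phenotypes choose the class with the largest Gumbel-perturbed utility
#' (multinomial logit), with the load and covariate effects on the last
#' class. With effect_of_load = 0 a phenotype is independent of load given
#' the covariates.
#'
#' @param true_load Per-individual true deleterious load.
#' @param covariates Covariate table (or NULL); numeric columns named in
#'   `covariate_effects` contribute linearly after standardization.
#' @param specs List of `pheno_spec`.
#' @param covariate_effects Named numeric vector of covariate effects.
#' @param seed Integer seed or NULL.
#' @return list(phenotypes = data.frame with sample_id, types = data.frame).
#' @export
simulate_phenotypes <- function(true_load, covariates = NULL,
                                specs = default_phenotype_specs(),
                                covariate_effects = c(age = 0.1, sex = 0.2),
                                seed = NULL) {
  n <- length(true_load)
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("`covariates` must have one row per individual", call. = FALSE)
  }
  z <- z_standardize(true_load)
  eta_c <- rep(0, n)
  if (!is.null(covariates)) {
    for (nm in names(covariate_effects)) {
      if (nm %in% names(covariates)) {
        eta_c <- eta_c +
          covariate_effects[[nm]] * z_standardize(as.numeric(covariates[[nm]]))
      }
    }
  }
  sample_id <- if (!is.null(covariates) && "sample_id" %in% names(covariates)) {
    as.character(covariates$sample_id)
  } else {
    sprintf("S%05d", seq_len(n))
  }
  with_seed(seed, {
    vals <- list()
    types <- character(0)
    for (sp in specs) {
      base <- sp$effect_of_load * z + eta_c
      y <- switch(sp$type,
        continuous = base + stats::rnorm(n, 0, sp$noise_sd),
        binary = ,
        phecode = {
          lat <- base + stats::rnorm(n, 0, sp$noise_sd)
          thr <- stats::quantile(lat, 1 - sp$prevalence, names = FALSE)
          as.integer(lat > thr)
        },
        ordered_categorical = {
          lat <- base + stats::rnorm(n, 0, sp$noise_sd)
          findInterval(lat, sort(sp$cutpoints)) + 1L
        },
        unordered_categorical = {
          K <- sp$n_classes
          u <- matrix(-log(-log(stats::runif(n * K))), n, K)
          u[, K] <- u[, K] + base
          paste0("class_", max.col(u))
        })
      vals[[sp$name]] <- y
      types[sp$name] <- sp$type
    }
    phenotypes <- data.frame(sample_id = sample_id, vals,
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    list(phenotypes = phenotypes,
         types = data.frame(name = names(types), type = unname(types),
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for a full synthetic dataset
#'
#' @param n_individuals,n_variants Cohort and panel sizes.
#' @param gamma_mixture data.frame(weight, gamma) of selection strengths.
#' @param coding_fraction Proportion of coding variants.
#' @param score_noise_sd Noise SD of the conservation-like score.
#' @param p_ref_ancestral Probability the reference allele is ancestral.
#' @param ancestral_mislabel_rate Probability the recorded ancestral label is
#'   swapped relative to truth.
#' @param imputation_noise_sd Dosage noise SD (0 gives hard calls).
#' @param phenotype_specs List of `pheno_spec`.
#' @param seed Master integer seed; fully determines the bundle.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1000L, n_variants = 2000L,
                       gamma_mixture = default_gamma_mixture(),
                       coding_fraction = 0.015,
                       score_noise_sd = 1,
                       p_ref_ancestral = 0.9,
                       ancestral_mislabel_rate = 0.02,
                       imputation_noise_sd = 0.05,
                       phenotype_specs = default_phenotype_specs(),
                       seed = 1L) {
  check_prob(coding_fraction, "coding_fraction")
  check_prob(p_ref_ancestral, "p_ref_ancestral")
  check_prob(ancestral_mislabel_rate, "ancestral_mislabel_rate")
  if (abs(sum(gamma_mixture$weight) - 1) > 1e-8) {
    stop("gamma mixture weights must sum to 1", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 gamma_mixture = gamma_mixture,
                 coding_fraction = coding_fraction,
                 score_noise_sd = score_noise_sd,
                 p_ref_ancestral = p_ref_ancestral,
                 ancestral_mislabel_rate = ancestral_mislabel_rate,
                 imputation_noise_sd = imputation_noise_sd,
                 phenotype_specs = phenotype_specs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a complete synthetic dataset bundle on disk
#'
#' Produces a self-consistent bundle readable by every downstream stage:
#' genotype dosages (TSV or VCF 4.2 with a DS FORMAT field), a variant
#' annotation table, phenotype and phenotype-type tables, covariates, truth
#' tables (per-variant gamma and true orientation; per-individual true
#' loads), and the configuration as YAML. The truth load is the genome-wide
#' sum of derived dosages weighted by the assigned score over variants with
#' score > 0 and INFO >= 0.9, using the true (not the possibly mislabeled)
#' orientation — the same variant set the load-score filter profile selects.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @param format "tsv" for a dosage matrix or "vcf" for a VCF 4.2 file.
#' @return Invisibly, list(paths = named file paths, data = in-memory pieces).
#' @export
generate_dataset <- function(config, dir, format = c("tsv", "vcf")) {
  stopifnot(inherits(config, "sim_config"))
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  }
  n <- config$n_individuals
  m <- config$n_variants
  s <- function(k) sub_seed(config$seed, k)

  arch <- selection_architecture(m, config$coding_fraction,
                                 config$gamma_mixture, seed = s(1))
  freqs <- sample_site_frequencies(arch$gamma, n, seed = s(2))
  score <- assign_scores(arch$gamma, config$score_noise_sd, seed = s(3))
  score_nh <- assign_scores(arch$gamma, config$score_noise_sd * 1.5, seed = s(8))
  alleles <- assign_alleles(m, config$p_ref_ancestral,
                            config$ancestral_mislabel_rate, seed = s(4))
  geno <- simulate_genotypes(freqs, n, config$imputation_noise_sd, seed = s(5))
  covariates <- simulate_covariates(n, seed = s(6))

  derived <- geno$dosage                       # derived-allele dosage
  alt_dosages <- derived
  flip <- !alleles$alt_is_derived_true
  if (any(flip)) alt_dosages[, flip] <- 2 - alt_dosages[, flip]
  rownames(alt_dosages) <- covariates$sample_id
  variant_id <- if (m > 0) {
    sprintf("1:%d:%s:%s", seq_len(m), alleles$ref, alleles$alt)
  } else character(0)
  colnames(alt_dosages) <- variant_id

  records <- data.frame(variant_id = variant_id,
                        chrom = rep("1", m),
                        pos = seq_len(m),
                        ref = alleles$ref, alt = alleles$alt,
                        ancestral = alleles$ancestral,
                        phyloP = score, phyloPNH = score_nh,
                        region_class = arch$region_class,
                        functional_class = arch$functional_class,
                        info = geno$info,
                        missing_fraction = rep(0, m),
                        stringsAsFactors = FALSE)

  truth_mask <- score > 0 & geno$info >= 0.9
  load_of <- function(extra) {
    mk <- truth_mask & extra
    as.numeric(derived[, mk, drop = FALSE] %*% score[mk])
  }
  true_load <- load_of(rep(TRUE, m))
  true_load_coding <- load_of(arch$region_class == "coding")
  true_load_noncoding <- load_of(arch$region_class == "noncoding")

  phen <- simulate_phenotypes(true_load, covariates,
                              config$phenotype_specs, seed = s(7))

  truth_variants <- data.frame(variant_id = variant_id,
                               gamma = arch$gamma,
                               daf_true = freqs,
                               daf_sample = if (m > 0) colMeans(derived) / 2 else numeric(0),
                               ancestral_true = alleles$ancestral_true,
                               alt_is_derived_true = alleles$alt_is_derived_true,
                               mislabeled = alleles$mislabeled,
                               in_truth_mask = truth_mask,
                               stringsAsFactors = FALSE)
  truth_samples <- data.frame(sample_id = covariates$sample_id,
                              true_load = true_load,
                              true_load_coding = true_load_coding,
                              true_load_noncoding = true_load_noncoding,
                              stringsAsFactors = FALSE)

  paths <- list(
    annotations = file.path(dir, "annotations.tsv"),
    genotypes = file.path(dir, if (format == "tsv") "dosages.tsv" else "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    phenotype_types = file.path(dir, "phenotype_types.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_tsv_full(records, paths$annotations)
  if (format == "tsv") {
    write_dosage_tsv(alt_dosages, paths$genotypes)
  } else {
    write_vcf_dosages(alt_dosages, records, paths$genotypes, hard = {
      h <- geno$hard
      if (any(flip)) h[, flip] <- 2L - h[, flip]
      h
    })
  }
  write_tsv_full(phen$phenotypes, paths$phenotypes)
  write_tsv_full(phen$types, paths$phenotype_types)
  write_tsv_full(covariates, paths$covariates)
  write_tsv_full(truth_variants, paths$truth_variants)
  write_tsv_full(truth_samples, paths$truth_samples)
  cfg <- config
  cfg$phenotype_specs <- lapply(cfg$phenotype_specs, unclass)
  yaml::write_yaml(unclass(cfg), paths$config)

  invisible(list(paths = paths,
                 data = list(records = records,
                             alt_dosages = alt_dosages,
                             derived_dosages = derived,
                             truth_variants = truth_variants,
                             truth_samples = truth_samples,
                             phenotypes = phen$phenotypes,
                             types = phen$types,
                             covariates = covariates,
                             config = config)))
}
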