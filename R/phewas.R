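# Phenotype filtering and the phenome-wide association scan of load scores
# against typed phenotypes with covariate adjustment.

#' Filter phenotypes by case/control and sample-size rules
#'
#' Phecode phenotypes are kept iff the case count is strictly greater than
#' `min_cases`. Binary phenotypes are kept iff both cases and controls are
#' at least `min_cases` and the non-missing sample size is at least
#' `min_n`. Continuous, ordered and unordered phenotypes are kept iff the
#' non-missing sample size is at least `min_n`. Counts are computed over
#' non-missing values; binary/phecode columns are expected coded 0/1.
#'
#' @param phenotypes data.frame with `sample_id` plus phenotype columns.
#' @param types data.frame(name, type) or named character vector.
#' @param min_cases Case/control threshold (default 500).
#' @param min_n Minimum individuals for non-phecode phenotypes (default 5000).
#' @return Character vector of retained phenotype names, with a `summary`
#'   attribute (per-phenotype counts and decisions).
#' @export
filter_phenotypes <- function(phenotypes, types, min_cases = 500L,
                              min_n = 5000L) {
  types <- as_type_map(types)
  nm <- intersect(names(types), setdiff(names(phenotypes), "sample_id"))
  rows <- lapply(nm, function(p) {
    y <- phenotypes[[p]]
    n <- sum(!is.na(y))
    tp <- types[[p]]
    cases <- controls <- NA_integer_
    if (tp %in% c("binary", "phecode")) {
      cases <- sum(y == 1, na.rm = TRUE)
      controls <- sum(y == 0, na.rm = TRUE)
    }
    kept <- switch(tp,
      phecode = cases > min_cases,
      binary = cases >= min_cases && controls >= min_cases && n >= min_n,
      n >= min_n)
    data.frame(name = p, type = tp, n = n, n_cases = cases,
               n_controls = controls, kept = kept,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  out <- summary$name[summary$kept]
  attr(out, "summary") <- summary
  out
}

prep_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  cv <- covariates[setdiff(names(covariates), "sample_id")]
  chr <- vapply(cv, function(x) is.character(x) || is.logical(x), logical(1))
  cv[chr] <- lapply(cv[chr], factor)
  cv
}

#' Association test between a load score and one phenotype
#'
#' Fits the regression family implied by the phenotype type: linear model
#' for continuous (with an optional rank-based inverse-normal transform of
#' the response), proportional-odds cumulative logit for ordered
#' categorical, multinomial logit for unordered categorical (p-value from a
#' likelihood-ratio test of the load term; no single coefficient is
#' reported), and binomial logistic regression for binary and phecode
#' phenotypes. Rows with any missing phenotype, load or covariate value are
#' excluded (complete-case analysis), and the reported n is the size of the
#' analysis set. Non-convergence or separation yields a flagged result with
#' NA estimates rather than an error.
#'
#' @param load Numeric load values aligned with `phenotype` (typically the
#'   z-standardized score).
#' @param phenotype Phenotype values (missing allowed).
#' @param ptype One of continuous, ordered_categorical,
#'   unordered_categorical, binary, phecode.
#' @param covariates Optional covariate data.frame aligned by row (a
#'   `sample_id` column is ignored; character columns become factors).
#' @param inverse_normal Apply the rank-based inverse-normal transform to
#'   continuous responses (default TRUE).
#' @return One-row data.frame: ptype, n, beta, se, p_value, converged.
#' @export
run_association <- function(load, phenotype, ptype, covariates = NULL,
                            inverse_normal = TRUE) {
  stopifnot(ptype %in% PHENOTYPE_TYPES,
            length(load) == length(phenotype))
  d <- data.frame(.y = phenotype, .load = as.numeric(load))
  cv <- prep_covariates(covariates)
  if (!is.null(cv)) {
    stopifnot(nrow(cv) == length(load))
    d <- cbind(d, cv)
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d <- droplevels(d)
  n <- nrow(d)
  bad <- data.frame(ptype = ptype, n = n, beta = NA_real_, se = NA_real_,
                    p_value = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    if (ptype == "continuous") {
      if (inverse_normal) d$.y <- rank_inverse_normal(d$.y)
      fit <- stats::lm(.y ~ ., data = d)
      sm <- suppressWarnings(summary(fit))$coefficients
      data.frame(ptype = ptype, n = n,
                 beta = sm[".load", 1], se = sm[".load", 2],
                 p_value = sm[".load", 4], converged = TRUE,
                 stringsAsFactors = FALSE)
    } else if (ptype %in% c("binary", "phecode")) {
      d$.y <- as.integer(d$.y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                         family = stats::binomial()))
      sm <- summary(fit)$coefficients
      data.frame(ptype = ptype, n = n,
                 beta = sm[".load", 1], se = sm[".load", 2],
                 p_value = sm[".load", 4], converged = fit$converged,
                 stringsAsFactors = FALSE)
    } else if (ptype == "ordered_categorical") {
      d$.y <- factor(d$.y, ordered = TRUE)
      fit <- suppressWarnings(MASS::polr(.y ~ ., data = d, Hess = TRUE))
      sm <- summary(fit)$coefficients
      tval <- sm[".load", 3]
      data.frame(ptype = ptype, n = n,
                 beta = sm[".load", 1], se = sm[".load", 2],
                 p_value = 2 * stats::pnorm(-abs(tval)), converged = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      d$.y <- factor(d$.y)
      full <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 500)
      null <- nnet::multinom(.y ~ . - .load, data = d, trace = FALSE,
                             maxit = 500)
      df <- nlevels(d$.y) - 1L
      p <- stats::pchisq(null$deviance - full$deviance, df = df,
                         lower.tail = FALSE)
      data.frame(ptype = ptype, n = n, beta = NA_real_, se = NA_real_,
                 p_value = p, converged = full$convergence == 0,
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) bad)
  res
}

#' Phenome-wide association scan
#'
#' Tests every load score against every retained phenotype with covariate
#' adjustment, returning one row per (score, phenotype) pair in
#' deterministic order (score kind, then phenotype name).
#'
#' @param loads A `load_score` or a named list of them (names become the
#'   `score_kind` column).
#' @param phenotypes data.frame with `sample_id` plus phenotype columns.
#' @param types data.frame(name, type) or named character vector.
#' @param covariates Optional covariate data.frame with `sample_id`.
#' @param filter Apply [filter_phenotypes()] first (default TRUE).
#' @param inverse_normal Passed to [run_association()].
#' @param standardized Use the z-standardized load values (default TRUE).
#' @param min_cases,min_n Passed to [filter_phenotypes()].
#' @return data.frame: score_kind, phenotype, ptype, n, beta, se, p_value,
#'   converged.
#' @export
phewas_scan <- function(loads, phenotypes, types, covariates = NULL,
                        filter = TRUE, inverse_normal = TRUE,
                        standardized = TRUE, min_cases = 500L,
                        min_n = 5000L) {
  if (inherits(loads, "load_score")) {
    loads <- stats::setNames(list(loads), attr(loads, "subset"))
  }
  stopifnot(is.list(loads), length(loads) >= 1, !is.null(names(loads)))
  types <- as_type_map(types)
  ids <- as.character(phenotypes$sample_id)
  for (ls in loads) ids <- intersect(ids, ls$sample_id)
  if (!is.null(covariates)) {
    ids <- intersect(ids, as.character(covariates$sample_id))
  }
  if (!length(ids)) stop("no overlapping samples", call. = FALSE)
  phen <- phenotypes[match(ids, as.character(phenotypes$sample_id)), ,
                     drop = FALSE]
  cova <- if (is.null(covariates)) NULL else
    covariates[match(ids, as.character(covariates$sample_id)), , drop = FALSE]
  retained <- if (filter) {
    filter_phenotypes(phen, types, min_cases = min_cases, min_n = min_n)
  } else {
    intersect(names(types), setdiff(names(phen), "sample_id"))
  }
  out <- list()
  for (kind in sort(names(loads))) {
    ls <- loads[[kind]]
    lv <- (if (standardized) ls$z else ls$raw)[match(ids, ls$sample_id)]
    for (p in sort(retained)) {
      row <- run_association(lv, phen[[p]], types[[p]], cova,
                             inverse_normal = inverse_normal)
      out[[length(out) + 1L]] <- cbind(
        data.frame(score_kind = kind, phenotype = p,
                   stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, out)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (>= 1).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("`n_tests` must be a positive count", call. = FALSE)
  }
  alpha / n_tests
}

#' Reference-bias and weighting sensitivity scans
#'
#' Reruns the scan under the requested sensitivity modes:
#' \describe{
#'   \item{default}{the standard scan.}
#'   \item{nonref_covar}{adds the per-individual count of non-reference
#'     alleles over the load variants as an extra covariate.}
#'   \item{ref_ancestral}{recomputes the load restricted to sites where the
#'     reference allele equals the recorded ancestral allele.}
#'   \item{alt_weight}{recomputes the load using an alternative weight
#'     column (e.g. phyloPNH, the human-reference-free conservation score).}
#' }
#'
#' @param alt_dosages Sample-by-variant ALT dosage matrix.
#' @param records Annotation data.frame.
#' @param phenotypes,types,covariates As in [phewas_scan()].
#' @param weight_column Primary weight column.
#' @param alt_weight_column Weight column for mode "alt_weight".
#' @param subset Genomic subset of the load score.
#' @param modes Subset of the four mode names.
#' @param ... Passed to [phewas_scan()].
#' @return Named list of scan tables, one per mode.
#' @export
sensitivity_scan <- function(alt_dosages, records, phenotypes, types,
                             covariates = NULL, weight_column = "phyloP",
                             alt_weight_column = "phyloPNH",
                             subset = "coding",
                             modes = c("default", "nonref_covar",
                                       "ref_ancestral", "alt_weight"),
                             ...) {
  modes <- match.arg(modes, several.ok = TRUE)
  base <- build_load(alt_dosages, records, weight_column, subset)
  out <- list()
  for (mode in modes) {
    if (mode == "default") {
      out[[mode]] <- phewas_scan(stats::setNames(list(base), subset),
                                 phenotypes, types, covariates, ...)
    } else if (mode == "nonref_covar") {
      mask <- filter_variants(records, min_info = 0.9, max_missing = NULL,
                              positive_score = weight_column)
      if (subset != "all") mask <- mask & records$region_class == subset
      nonref <- count_non_reference(alt_dosages, mask)
      cv <- if (is.null(covariates)) {
        data.frame(sample_id = rownames(alt_dosages),
                   stringsAsFactors = FALSE)
      } else {
        covariates
      }
      cv$nonref_count <- nonref[match(as.character(cv$sample_id),
                                      rownames(alt_dosages))]
      out[[mode]] <- phewas_scan(stats::setNames(list(base), subset),
                                 phenotypes, types, cv, ...)
    } else if (mode == "ref_ancestral") {
      ls <- build_load(alt_dosages, records, weight_column, subset,
                       extra_mask = !is.na(records$ancestral) &
                         records$ancestral == records$ref)
      out[[mode]] <- phewas_scan(stats::setNames(list(ls), subset),
                                 phenotypes, types, covariates, ...)
    } else {
      if (!alt_weight_column %in% names(records)) {
        stop(sprintf("weight column `%s` absent from annotations",
                     alt_weight_column), call. = FALSE)
      }
      ls <- build_load(alt_dosages, records, alt_weight_column, subset)
      out[[mode]] <- phewas_scan(stats::setNames(list(ls), subset),
                                 phenotypes, types, covariates, ...)
    }
  }
  out
}
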