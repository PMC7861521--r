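# Per-individual deleterious load scores: weighted and unweighted sums of
# derived-allele dosages, frequency/score strata, non-reference counts, and
# the normality diagnostic of the load distribution.

new_load_score <- function(sample_id, raw, weight_scheme = "custom",
                           subset = "all", stratum = NULL) {
  out <- data.frame(sample_id = as.character(sample_id), raw = raw,
                    z = z_standardize(raw), stringsAsFactors = FALSE)
  attr(out, "weight_scheme") <- weight_scheme
  attr(out, "subset") <- subset
  attr(out, "stratum") <- stratum
  class(out) <- c("load_score", "data.frame")
  out
}

#' @export
print.load_score <- function(x, ...) {
  cat(sprintf("load score: %d individuals, subset=%s, weights=%s%s\n",
              nrow(x), attr(x, "subset"), attr(x, "weight_scheme"),
              if (!is.null(attr(x, "stratum"))) paste0(", stratum=", attr(x, "stratum")) else ""))
  cat(sprintf("  raw: mean %.4g, sd %.4g\n", mean(x$raw), stats::sd(x$raw)))
  invisible(x)
}

#' Weighted deleterious load score
#'
#' For each individual, the sum over selected variants of the derived-allele
#' dosage times the per-variant weight (an additive model with no
#' normalization by variant count). Raw sums are retained and a z-standardized
#' copy is provided for association testing, where the per-SD scale makes
#' effect sizes comparable across variant subsets.
#'
#' @param derived_dosages Sample-by-variant matrix of derived-allele dosages
#'   in [0, 2] (see [derived_dosage()]).
#' @param weights Finite per-variant weights.
#' @param mask Logical or integer variant selector (NULL = all).
#' @param na_action "impute_mean" replaces missing dosages by the variant's
#'   mean derived dosage (unbiased for the sum); "error" raises instead.
#' @param sample_ids Sample identifiers (default: rownames).
#' @param weight_scheme,subset Metadata recorded on the result.
#' @return A `load_score` data.frame: sample_id, raw, z.
#' @export
compute_load <- function(derived_dosages, weights, mask = NULL,
                         na_action = c("impute_mean", "error"),
                         sample_ids = rownames(derived_dosages),
                         weight_scheme = "custom", subset = "all") {
  na_action <- match.arg(na_action)
  stopifnot(is.matrix(derived_dosages))
  m <- ncol(derived_dosages)
  if (length(weights) != m) {
    stop("`weights` length must equal the number of variants", call. = FALSE)
  }
  if (any(!is.finite(weights))) stop("`weights` must be finite", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, m)
  if (is.logical(mask) && length(mask) != m) {
    stop("logical `mask` length must equal the number of variants",
         call. = FALSE)
  }
  D <- derived_dosages[, mask, drop = FALSE]
  w <- weights[mask]
  if (anyNA(D)) {
    if (na_action == "error") {
      stop("missing dosages present and na_action = \"error\"", call. = FALSE)
    }
    mu <- colMeans(D, na.rm = TRUE)
    if (anyNA(mu)) stop("variant with all dosages missing", call. = FALSE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(D)))
  raw <- as.numeric(D %*% w)
  new_load_score(sample_ids, raw, weight_scheme = weight_scheme,
                 subset = subset)
}

#' Unweighted mutation burden
#'
#' The per-individual count of derived alleles: identical to
#' [compute_load()] with unit weights.
#'
#' @inheritParams compute_load
#' @return A `load_score` with weight_scheme "unit".
#' @export
compute_burden <- function(derived_dosages, mask = NULL,
                           na_action = c("impute_mean", "error"),
                           sample_ids = rownames(derived_dosages),
                           subset = "all") {
  compute_load(derived_dosages, rep(1, ncol(derived_dosages)), mask = mask,
               na_action = na_action, sample_ids = sample_ids,
               weight_scheme = "unit", subset = subset)
}

as_interval_matrix <- function(x, name, probs = FALSE) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(x), ncol = 2)
  if (any(x[, 1] >= x[, 2])) stop(sprintf("`%s`: need low < high", name), call. = FALSE)
  if (probs && (any(x < 0) || any(x > 1))) {
    stop(sprintf("`%s` must lie within [0, 1]", name), call. = FALSE)
  }
  o <- order(x[, 1])
  x <- x[o, , drop = FALSE]
  if (nrow(x) > 1 && any(x[-1, 1] < x[-nrow(x), 2] - 1e-12)) {
    stop(sprintf("`%s` intervals overlap", name), call. = FALSE)
  }
  x
}

#' Load scores stratified by DAF and/or deleteriousness score
#'
#' Builds one load score per stratum of the cross of DAF intervals (closed
#' on the left, [low, high)) and score intervals (closed on the right,
#' (low, high]). Strata are disjoint by construction; a variant falling in
#' no stratum contributes to none, and strata forming a partition of the
#' masked variants sum elementwise to the unstratified load.
#'
#' @param derived_dosages Sample-by-variant derived dosage matrix.
#' @param daf Per-variant derived allele frequency.
#' @param score Per-variant deleteriousness score (weights by default).
#' @param weights Per-variant weights (defaults to `score`).
#' @param daf_intervals,score_intervals Two-column matrices or lists of
#'   (low, high) pairs; NULL spans the whole range of that dimension.
#' @param mask Optional additional variant mask.
#' @param ... Passed to [compute_load()].
#' @return Named list of `load_score`, one per stratum.
#' @export
stratified_loads <- function(derived_dosages, daf, score, weights = score,
                             daf_intervals = NULL, score_intervals = NULL,
                             mask = NULL, ...) {
  m <- ncol(derived_dosages)
  stopifnot(length(daf) == m, length(score) == m, length(weights) == m)
  if (is.null(daf_intervals) && is.null(score_intervals)) {
    stop("supply at least one of `daf_intervals`, `score_intervals`",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, m)
  dm <- if (is.null(daf_intervals)) NULL else
    as_interval_matrix(daf_intervals, "daf_intervals", probs = TRUE)
  sm <- if (is.null(score_intervals)) NULL else
    as_interval_matrix(score_intervals, "score_intervals")
  daf_masks <- if (is.null(dm)) list(`DAF[0,1]` = rep(TRUE, m)) else {
    stats::setNames(
      lapply(seq_len(nrow(dm)), function(i) daf >= dm[i, 1] & daf < dm[i, 2]),
      sprintf("DAF[%g,%g)", dm[, 1], dm[, 2]))
  }
  score_masks <- if (is.null(sm)) list(score_all = rep(TRUE, m)) else {
    stats::setNames(
      lapply(seq_len(nrow(sm)), function(i) score > sm[i, 1] & score <= sm[i, 2]),
      sprintf("score(%g,%g]", sm[, 1], sm[, 2]))
  }
  out <- list()
  for (dn in names(daf_masks)) {
    for (sn in names(score_masks)) {
      label <- if (is.null(sm)) dn else if (is.null(dm)) sn else paste(dn, sn, sep = "&")
      mk <- mask & daf_masks[[dn]] & score_masks[[sn]] & !is.na(daf) & !is.na(score)
      ls <- compute_load(derived_dosages, weights, mask = mk, ...)
      attr(ls, "stratum") <- label
      attr(ls, "n_variants") <- sum(mk)
      out[[label]] <- ls
    }
  }
  out
}

#' Per-individual count of non-reference alleles
#'
#' Sum of ALT-allele dosages (not derived-polarized) over the masked
#' variants; used as a sensitivity covariate for reference bias.
#'
#' @param alt_dosages Sample-by-variant ALT dosage matrix.
#' @param mask Variant selector (NULL = all).
#' @return Named numeric vector, one count per individual.
#' @export
count_non_reference <- function(alt_dosages, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, ncol(alt_dosages))
  rowSums(alt_dosages[, mask, drop = FALSE], na.rm = TRUE)
}

#' Kolmogorov-Smirnov normality check of a load score distribution
#'
#' Standardizes the scores and runs a one-sample KS test against the
#' standard normal. Because the mean and SD are estimated from the data
#' (the Lilliefors situation) the p-value is conservative; it is reported
#' with that caveat for descriptive use, mirroring how near-normality of
#' load distributions is assessed.
#'
#' @param load A `load_score` or numeric vector (n >= 30).
#' @return list(statistic, p_value, mean, sd, note).
#' @export
normality_check <- function(load) {
  x <- if (inherits(load, "load_score")) load$raw else as.numeric(load)
  if (length(x) < 30) stop("need n >= 30 for the KS check", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("undefined test: zero-variance load distribution", call. = FALSE)
  }
  z <- (x - mean(x)) / s
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(ks$statistic),
       p_value = ks$p.value,
       mean = mean(x), sd = s,
       note = paste("location and scale estimated from the data",
                    "(Lilliefors caveat): p-value is conservative"))
}

#' Build a load score from ALT dosages and annotations
#'
#' Pipeline convenience: polarizes alleles, applies the load-score filter
#' profile (INFO >= 0.9, strictly positive weight score, biallelic SNVs,
#' resolvable ancestral allele), optionally restricts to a genomic subset,
#' and computes the weighted load.
#'
#' @param alt_dosages Sample-by-variant ALT dosage matrix (rownames = IDs).
#' @param records Annotation data.frame aligned with the columns.
#' @param weight_column Score column used as weights (must be positive to be
#'   included).
#' @param subset "all", "coding" or "noncoding" (uses `region_class`).
#' @param min_info INFO threshold for the filter profile.
#' @param extra_mask Optional additional logical mask (e.g. ref == ancestral
#'   for reference-bias sensitivity).
#' @param na_action Passed to [compute_load()].
#' @return A `load_score`.
#' @export
build_load <- function(alt_dosages, records,
                       weight_column = "phyloP",
                       subset = c("all", "coding", "noncoding"),
                       min_info = 0.9, extra_mask = NULL,
                       na_action = "impute_mean") {
  subset <- match.arg(subset)
  stopifnot(nrow(records) == ncol(alt_dosages))
  mask <- filter_variants(records, min_info = min_info, max_missing = NULL,
                          positive_score = weight_column)
  if (subset != "all") mask <- mask & records$region_class == subset
  if (!is.null(extra_mask)) mask <- mask & extra_mask
  ori <- polarize(records$ref, records$alt, records$ancestral)
  D <- derived_dosage(alt_dosages[, mask, drop = FALSE], ori[mask])
  compute_load(D, records[[weight_column]][mask], na_action = na_action,
               sample_ids = rownames(alt_dosages),
               weight_scheme = weight_column, subset = subset)
}
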