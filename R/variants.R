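# Polarization of REF/ALT genotypes into derived-allele dosages, derived
# allele frequencies, and the variant-level inclusion filters.

#' Polarize REF/ALT alleles against an ancestral allele
#'
#' @param ref,alt Single-base alleles.
#' @param ancestral Ancestral allele, possibly NA.
#' @return Character vector with values `alt_is_derived` (ancestral equals
#'   REF), `ref_is_derived` (ancestral equals ALT) or `unresolved` (ancestral
#'   missing or matching neither allele).
#' @export
polarize <- function(ref, alt, ancestral) {
  stopifnot(length(ref) == length(alt), length(alt) == length(ancestral))
  out <- rep("unresolved", length(ref))
  ok <- !is.na(ancestral)
  out[ok & ancestral == ref] <- "alt_is_derived"
  out[ok & ancestral == alt] <- "ref_is_derived"
  out
}

#' Convert ALT-allele dosage to derived-allele dosage
#'
#' Returns the ALT dosage unchanged where ALT is derived and its complement
#' to 2 where REF is derived. Unresolved orientations are a contract
#' violation: callers must filter first.
#'
#' @param alt_dosage Numeric vector, or a sample-by-variant matrix with one
#'   orientation per column.
#' @param orientation Output of [polarize()] (scalar, per-entry, or
#'   per-column for a matrix).
#' @return Derived-allele dosage with the same shape as `alt_dosage`.
#' @export
derived_dosage <- function(alt_dosage, orientation) {
  if (any(orientation == "unresolved")) {
    stop("unresolved orientation: filter unpolarizable variants first",
         call. = FALSE)
  }
  if (is.matrix(alt_dosage)) {
    stopifnot(length(orientation) == ncol(alt_dosage))
    flip <- orientation == "ref_is_derived"
    out <- alt_dosage
    out[, flip] <- 2 - out[, flip]
    return(out)
  }
  if (length(orientation) == 1L) {
    orientation <- rep(orientation, length(alt_dosage))
  }
  stopifnot(length(orientation) == length(alt_dosage))
  ifelse(orientation == "ref_is_derived", 2 - alt_dosage, alt_dosage)
}

#' Derived allele frequency from a dosage column or matrix
#'
#' The DAF is the mean of non-missing derived dosages divided by 2.
#'
#' @param alt_dosage Numeric vector (one variant) or sample-by-variant
#'   matrix.
#' @param orientation Orientation(s) from [polarize()].
#' @return DAF in [0, 1] (vector of per-variant DAFs for a matrix input).
#' @export
derived_frequency <- function(alt_dosage, orientation) {
  d <- derived_dosage(alt_dosage, orientation)
  if (is.matrix(d)) {
    nn <- colSums(!is.na(d))
    if (any(nn == 0)) {
      stop("derived frequency undefined: all-missing dosage column",
           call. = FALSE)
    }
    return(colMeans(d, na.rm = TRUE) / 2)
  }
  if (all(is.na(d))) {
    stop("derived frequency undefined: all-missing dosage column",
         call. = FALSE)
  }
  mean(d, na.rm = TRUE) / 2
}

#' Variant inclusion mask
#'
#' Applies the study's variant filters; each criterion can be disabled by
#' passing NULL. Defaults follow the load-score profile: imputation INFO
#' >= 0.9, missing fraction strictly below 1\%, strictly positive
#' deleteriousness score, biallelic SNVs only, and a resolvable ancestral
#' allele. Masks for different criteria combine by logical conjunction, so
#' filtering is order-independent.
#'
#' @param records Annotation data.frame (see [read_annotations()]).
#' @param min_info Minimum INFO score (kept when info >= min_info), or NULL.
#' @param max_missing Missingness bound (kept when strictly below), or NULL.
#' @param positive_score Name of a score column that must be strictly
#'   positive, or NULL.
#' @param biallelic_snv_only Require single-base REF and ALT, REF != ALT.
#' @param require_polarized Require the ancestral allele to match REF or ALT.
#' @return Logical inclusion mask, one entry per record.
#' @export
filter_variants <- function(records, min_info = 0.9, max_missing = 0.01,
                            positive_score = "phyloP",
                            biallelic_snv_only = TRUE,
                            require_polarized = TRUE) {
  n <- nrow(records)
  mask <- rep(TRUE, n)
  if (!is.null(min_info)) {
    if (!"info" %in% names(records)) {
      stop("INFO filter requested but `info` column absent", call. = FALSE)
    }
    mask <- mask & !is.na(records$info) & records$info >= min_info
  }
  if (!is.null(max_missing)) {
    if (!"missing_fraction" %in% names(records)) {
      stop("missingness filter requested but `missing_fraction` column absent",
           call. = FALSE)
    }
    mask <- mask & !is.na(records$missing_fraction) &
      records$missing_fraction < max_missing
  }
  if (!is.null(positive_score)) {
    if (!positive_score %in% names(records)) {
      stop(sprintf("score column `%s` absent from annotations", positive_score),
           call. = FALSE)
    }
    sc <- records[[positive_score]]
    mask <- mask & !is.na(sc) & sc > 0
  }
  if (isTRUE(biallelic_snv_only)) {
    bases <- c("A", "C", "G", "T")
    mask <- mask & nchar(records$ref) == 1L & nchar(records$alt) == 1L &
      records$ref %in% bases & records$alt %in% bases &
      records$ref != records$alt
  }
  if (isTRUE(require_polarized)) {
    ori <- polarize(records$ref, records$alt, records$ancestral)
    mask <- mask & ori != "unresolved"
  }
  mask
}

#' Load-score filter profile
#'
#' INFO >= 0.9, strictly positive weight score, biallelic SNVs, resolvable
#' orientation; no missingness criterion (imputed dosages have none).
#'
#' @param records Annotation data.frame.
#' @param weight_column Score column required to be positive.
#' @return Logical mask.
#' @export
load_score_filter <- function(records, weight_column = "phyloP") {
  filter_variants(records, min_info = 0.9, max_missing = NULL,
                  positive_score = weight_column)
}

#' DAF-spectrum calibration filter profile
#'
#' Missingness strictly below 1\% and resolvable orientation; no INFO and no
#' score-positivity criterion (spectra are built across the full score
#' range).
#'
#' @param records Annotation data.frame.
#' @return Logical mask.
#' @export
afs_filter <- function(records) {
  filter_variants(records, min_info = NULL, max_missing = 0.01,
                  positive_score = NULL)
}

#' Add an in-sample DAF column to an annotation table
#'
#' Computes the derived allele frequency from the dosage matrix using the
#' recorded ancestral annotation; unresolved variants get NA.
#'
#' @param records Annotation data.frame.
#' @param alt_dosages Sample-by-variant ALT dosage matrix.
#' @return `records` with a `daf` column.
#' @export
annotate_daf <- function(records, alt_dosages) {
  stopifnot(nrow(records) == ncol(alt_dosages))
  ori <- polarize(records$ref, records$alt, records$ancestral)
  daf <- rep(NA_real_, nrow(records))
  ok <- ori != "unresolved"
  if (any(ok)) {
    daf[ok] <- derived_frequency(alt_dosages[, ok, drop = FALSE], ori[ok])
  }
  records$daf <- daf
  records
}
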