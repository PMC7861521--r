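# Derived-allele-frequency spectrum calibration of deleteriousness scores:
# score-interval binning, non-normalized DAF spectra, log-log slope fits,
# and the slope-vs-rank regression with synonymous/missense/LOF controls.

# Log-spaced frequency bin edges on [lo, 1]; the first edge is pinned to lo
# exactly so the minimum observed DAF is never lost to rounding.
log_freq_edges <- function(lo, n_bins) {
  e <- exp(seq(log(lo), 0, length.out = n_bins + 1))
  e[1] <- lo
  e[n_bins + 1] <- 1
  e
}

#' Score interval specification
#'
#' Intervals use the (low, high] convention and must be ascending and
#' non-overlapping (contiguous intervals sharing an endpoint are allowed).
#'
#' @param method Score method name (e.g. "phyloP").
#' @param intervals Two-column matrix (low, high) or list of length-2
#'   vectors.
#' @return A `score_bin_spec`.
#' @export
score_bin_spec <- function(method, intervals) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2,
                      dimnames = list(NULL, c("low", "high")))
  if (nrow(intervals) == 0) stop("empty score bin specification", call. = FALSE)
  if (any(intervals[, 1] >= intervals[, 2])) {
    stop("each interval needs low < high", call. = FALSE)
  }
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2] - 1e-12)) {
    stop("score intervals must be non-overlapping and ascending", call. = FALSE)
  }
  structure(list(method = method, intervals = intervals,
                 labels = sprintf("(%g,%g]", intervals[, 1], intervals[, 2])),
            class = "score_bin_spec")
}

#' Published score interval lists for the four candidate methods
#'
#' The interval lists conventionally used to stratify each score:
#' fitCons in steps of 0.2 on (0, 0.8], GERP++ and phyloP in steps of 2.5
#' over their score ranges, CADD in steps of 5 on (0, 35].
#'
#' @return Named list of `score_bin_spec`.
#' @export
default_score_intervals <- function() {
  list(
    fitCons = score_bin_spec("fitCons",
                             cbind(seq(0, 0.6, by = 0.2), seq(0.2, 0.8, by = 0.2))),
    GERP = score_bin_spec("GERP",
                          cbind(seq(-10, 7.5, by = 2.5), seq(-7.5, 10, by = 2.5))),
    CADD = score_bin_spec("CADD",
                          cbind(seq(0, 30, by = 5), seq(5, 35, by = 5))),
    phyloP = score_bin_spec("phyloP",
                            cbind(seq(-5, 7.5, by = 2.5), seq(-2.5, 10, by = 2.5)))
  )
}

#' Assign variants to score intervals
#'
#' @param scores Numeric score vector.
#' @param spec A `score_bin_spec`.
#' @return Factor with one level per interval; variants outside every
#'   interval get NA (dropped from spectra).
#' @export
bin_by_score <- function(scores, spec) {
  stopifnot(inherits(spec, "score_bin_spec"))
  lab <- rep(NA_character_, length(scores))
  for (i in seq_len(nrow(spec$intervals))) {
    lo <- spec$intervals[i, 1]; hi <- spec$intervals[i, 2]
    lab[!is.na(scores) & scores > lo & scores <= hi] <- spec$labels[i]
  }
  factor(lab, levels = spec$labels)
}

#' Non-normalized derived allele frequency spectrum
#'
#' Counts variants per logarithmically spaced frequency bin spanning
#' [min observed DAF, 1). Counts are raw, i.e. not normalized by the total
#' number of variants or the bin width.
#'
#' @param dafs Derived allele frequencies in (0, 1); NAs dropped.
#' @param n_freq_bins Number of bins (>= 5) when `edges` is NULL.
#' @param edges Optional explicit ascending bin edges (shared edges make
#'   spectra comparable across score bins).
#' @param label Optional label (score interval or control class).
#' @return An `afs_spectrum`: list(edges, counts, label, n).
#' @export
daf_spectrum <- function(dafs, n_freq_bins = 20L, edges = NULL, label = NULL) {
  dafs <- dafs[!is.na(dafs)]
  if (length(dafs) && (any(dafs <= 0) || any(dafs >= 1))) {
    stop("DAFs must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(edges)) {
    if (n_freq_bins < 5) stop("`n_freq_bins` must be >= 5", call. = FALSE)
    if (!length(dafs)) {
      return(structure(list(edges = numeric(0),
                            counts = integer(0), label = label, n = 0L),
                       class = "afs_spectrum"))
    }
    edges <- log_freq_edges(min(dafs), n_freq_bins)
  }
  edges <- sort(edges)
  k <- length(edges) - 1L
  idx <- findInterval(dafs, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1L & idx <= k], nbins = k)
  structure(list(edges = edges, counts = as.integer(counts), label = label,
                 n = sum(counts)),
            class = "afs_spectrum")
}

#' @export
print.afs_spectrum <- function(x, ...) {
  cat("DAF spectrum", if (!is.null(x$label)) paste0("[", x$label, "]"), "-",
      x$n, "variants in", length(x$counts), "bins\n")
  invisible(x)
}

#' Log-log slope of a DAF spectrum
#'
#' Ordinary least squares of log10(count / bin width) on log10(geometric bin
#' midpoint), dropping empty bins. Normalizing counts by bin width makes the
#' fitted slope independent of the binning: the neutral 1/x spectrum has
#' slope -1 exactly, and stronger purifying selection gives more negative
#' slopes.
#'
#' @param spectrum An `afs_spectrum`.
#' @return A `slope_fit`: list(slope, intercept, r_squared, n_bins_used).
#' @export
fit_spectrum_slope <- function(spectrum) {
  stopifnot(inherits(spectrum, "afs_spectrum"))
  k <- length(spectrum$counts)
  if (k == 0) stop("insufficient data: empty spectrum", call. = FALSE)
  lo <- spectrum$edges[-(k + 1)]
  hi <- spectrum$edges[-1]
  keep <- spectrum$counts > 0
  if (sum(keep) < 2) {
    stop("insufficient data: need >= 2 non-empty frequency bins",
         call. = FALSE)
  }
  x <- log10(sqrt(lo * hi))[keep]
  y <- log10(spectrum$counts[keep] / (hi - lo)[keep])
  fit <- stats::lm(y ~ x)
  # exact power laws are a designed input; silence the perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 1  # zero-variance response: fit is exact
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_bins_used = sum(keep)),
            class = "slope_fit")
}

#' Regression of spectrum slopes on score-category rank
#'
#' Score categories ordered from low to high are coded as integers starting
#' from 1 and the fitted slopes are regressed on the rank by ordinary least
#' squares. A negative rank coefficient means higher score categories have
#' steeper (more negative) spectra, i.e. the score tracks purifying
#' selection.
#'
#' @param slopes Numeric slopes ordered by ascending score category (or a
#'   list of `slope_fit`).
#' @return list(coefficient, p_value, r_squared).
#' @export
slope_vs_rank <- function(slopes) {
  if (is.list(slopes)) {
    slopes <- vapply(slopes, function(s) {
      if (inherits(s, "slope_fit")) s$slope else as.numeric(s)
    }, numeric(1))
  }
  K <- length(slopes)
  if (K < 3) stop("insufficient data: need >= 3 score categories", call. = FALSE)
  rank <- seq_len(K)
  fit <- stats::lm(slopes ~ rank)
  sm <- suppressWarnings(summary(fit)$coefficients)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(coefficient = unname(stats::coef(fit)[2]),
       p_value = if (nrow(sm) >= 2) unname(sm[2, 4]) else NA_real_,
       r_squared = if (is.finite(r2)) r2 else 1)
}

#' Control spectra for synonymous, missense and loss-of-function variants
#'
#' Builds one spectrum per functional control class using the same frequency
#' binning as the score-bin spectra (pass shared `edges`). An absent class
#' yields an all-zero spectrum with a warning.
#'
#' @param dafs Derived allele frequencies.
#' @param functional_class Per-variant class labels.
#' @param edges Shared bin edges (recommended); computed from the pooled
#'   control DAFs when NULL.
#' @param n_freq_bins Bin count when `edges` is NULL.
#' @param classes Control classes to report.
#' @return Named list of `afs_spectrum`.
#' @export
control_spectra <- function(dafs, functional_class, edges = NULL,
                            n_freq_bins = 20L,
                            classes = c("synonymous", "missense", "lof")) {
  stopifnot(length(dafs) == length(functional_class))
  pool <- dafs[functional_class %in% classes & !is.na(dafs)]
  if (is.null(edges)) {
    if (!length(pool)) stop("no variants in any control class", call. = FALSE)
    edges <- log_freq_edges(min(pool), n_freq_bins)
  }
  out <- lapply(classes, function(cl) {
    d <- dafs[functional_class == cl]
    if (!length(d)) {
      warning(sprintf("control class `%s` absent: empty spectrum", cl),
              call. = FALSE)
    }
    daf_spectrum(d, edges = edges, label = cl)
  })
  stats::setNames(out, classes)
}

#' Spectrum slopes across the intervals of a score bin specification
#'
#' Convenience wrapper: assigns variants to score intervals, builds spectra
#' on shared log-spaced edges, and fits one slope per non-empty interval.
#'
#' @param dafs Derived allele frequencies.
#' @param scores Score values (same length).
#' @param spec A `score_bin_spec`.
#' @param n_freq_bins Number of shared frequency bins.
#' @return list(spectra, slopes, labels) with one entry per interval that
#'   contains variants.
#' @export
afs_slopes <- function(dafs, scores, spec, n_freq_bins = 20L) {
  stopifnot(length(dafs) == length(scores))
  bins <- bin_by_score(scores, spec)
  keep <- !is.na(bins) & !is.na(dafs)
  if (!any(keep)) stop("no variants fall inside the score intervals", call. = FALSE)
  edges <- log_freq_edges(min(dafs[keep]), n_freq_bins)
  labels <- levels(bins)[tabulate(bins[keep], nbins = nlevels(bins)) > 0]
  spectra <- lapply(labels, function(lb) {
    daf_spectrum(dafs[keep & bins == lb], edges = edges, label = lb)
  })
  slopes <- lapply(spectra, fit_spectrum_slope)
  list(spectra = stats::setNames(spectra, labels),
       slopes = stats::setNames(slopes, labels),
       labels = labels)
}
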