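# Permutation-null enrichment test: is the number of phenotypes nominally
# associated with a load score larger than expected by chance?

#' Count nominally significant association results
#'
#' Number of rows with p-value strictly below `alpha`; rows flagged as
#' non-converged are excluded.
#'
#' @param results data.frame with `p_value` and `converged` columns (a
#'   [phewas_scan()] table).
#' @param alpha Nominal significance level (default 0.05).
#' @return Integer count.
#' @export
count_nominal <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("empty results table", call. = FALSE)
  sum(results$p_value < alpha & results$converged, na.rm = TRUE)
}

#' Assemble a permutation result
#'
#' The permutation p-value is the fraction of permutations whose nominal
#' count is at least as large (ties count toward significance) as the
#' observed count. The plain fraction can be exactly zero; the add-one
#' variant (r + 1) / (n + 1) is available behind `add_one`.
#'
#' @param observed_count Observed nominal count.
#' @param null_counts Integer vector of per-permutation nominal counts.
#' @param alpha_nominal Nominal level used for the counts.
#' @param add_one Use the (r + 1) / (n + 1) p-value variant.
#' @param n_dropped Number of non-converged fits dropped from the counts.
#' @return A `permutation_result`.
#' @export
permutation_result <- function(observed_count, null_counts,
                               alpha_nominal = 0.05, add_one = FALSE,
                               n_dropped = 0L) {
  B <- length(null_counts)
  if (B < 1) stop("need at least one permutation", call. = FALSE)
  r <- sum(null_counts >= observed_count)
  p <- if (add_one) (r + 1) / (B + 1) else r / B
  structure(list(observed_count = as.integer(observed_count),
                 null_counts = as.integer(null_counts),
                 n_permutations = B,
                 p_value = p,
                 alpha_nominal = alpha_nominal,
                 add_one = add_one,
                 n_dropped = as.integer(n_dropped)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation enrichment test: observed %d nominal ",
                     "associations (alpha = %g)\n"),
              x$observed_count, x$alpha_nominal))
  cat(sprintf("  null: mean %.2f over %d permutations; p = %.4g%s\n",
              mean(x$null_counts), x$n_permutations, x$p_value,
              if (x$n_dropped > 0) sprintf(" (%d fits dropped)", x$n_dropped) else ""))
  invisible(x)
}

# Rao score test p-values for adding each column of `cand` to the null
# logistic model y ~ X. One null fit serves every candidate, which is what
# makes large permutation studies affordable.
score_test_pvals <- function(X, y, cand) {
  nf <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu <- nf$fitted.values
  w <- mu * (1 - mu)
  r <- y - mu
  WX <- X * w
  M <- tryCatch(chol2inv(chol(crossprod(X, WX))), error = function(e) NULL)
  if (is.null(M) || !nf$converged) return(rep(NA_real_, ncol(cand)))
  U <- as.numeric(crossprod(cand, r))
  C <- crossprod(cand, WX)
  q <- rowSums((C %*% M) * C)
  xwx <- as.numeric(crossprod(cand^2, w))
  V <- xwx - q
  stat <- ifelse(V > 1e-12, U^2 / V, NA_real_)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Wald p-value for the last column of X in a logistic fit.
logistic_wald_p <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged) return(NA_real_)
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  pos <- match(ncol(X), piv)
  if (is.na(pos)) return(NA_real_)
  covm <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(covm[pos, pos])
  b <- fit$coefficients[ncol(X)]
  2 * stats::pnorm(-abs(b / se))
}

#' Permutation enrichment test for nominal load-phenotype associations
#'
#' Computes the observed number of phecode-type phenotypes nominally
#' associated with the load score, then repeatedly shuffles the load values
#' across sample IDs (phenotypes and covariates untouched, so their joint
#' structure is preserved), reruns the scan, and records the nominal count
#' for each permutation. Shuffling preserves the multiset of load values
#' exactly. Two engines fit the per-phenotype logistic models: "glm" refits
#' the full model for the observed and every permuted load; "score" fits the
#' covariate-only null model once per phenotype and evaluates the Rao score
#' test for each candidate load, which is orders of magnitude faster. The
#' observed and permuted counts always use the same engine, so the
#' permutation p-value compares exchangeable quantities either way.
#' Non-converged fits are dropped from the counts and tallied in
#' `n_dropped`.
#'
#' @param load A `load_score` (z values are used).
#' @param phenotypes data.frame with `sample_id` plus phenotype columns.
#' @param types data.frame(name, type) or named character vector; only
#'   phenotypes of the types in `phenotype_types` enter the test.
#' @param covariates Optional covariate data.frame with `sample_id`.
#' @param n_permutations Number of permutations (>= 1; 2000 gives a p-value
#'   resolution of 5e-4).
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Integer seed for the shuffles, or NULL.
#' @param engine "glm" (full refits) or "score" (cached-null score test).
#' @param add_one Use the (r + 1)/(n + 1) p-value variant.
#' @param phenotype_types Which declared types enter the test.
#' @return A `permutation_result`.
#' @export
permute_and_count <- function(load, phenotypes, types, covariates = NULL,
                              n_permutations = 2000L, alpha = 0.05,
                              seed = NULL, engine = c("glm", "score"),
                              add_one = FALSE,
                              phenotype_types = "phecode") {
  engine <- match.arg(engine)
  if (n_permutations < 1) {
    stop("`n_permutations` must be >= 1", call. = FALSE)
  }
  types <- as_type_map(types)
  keep <- intersect(names(types)[types %in% phenotype_types],
                    setdiff(names(phenotypes), "sample_id"))
  if (!length(keep)) {
    stop("no phenotypes of the requested type(s)", call. = FALSE)
  }
  ids <- intersect(as.character(phenotypes$sample_id), load$sample_id)
  if (!is.null(covariates)) {
    ids <- intersect(ids, as.character(covariates$sample_id))
  }
  if (!length(ids)) stop("no overlapping samples", call. = FALSE)
  n <- length(ids)
  lz <- load$z[match(ids, load$sample_id)]
  Y <- as.matrix(phenotypes[match(ids, as.character(phenotypes$sample_id)),
                            keep, drop = FALSE])
  storage.mode(Y) <- "double"
  Xbase <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    cv <- prep_covariates(
      covariates[match(ids, as.character(covariates$sample_id)), ,
                 drop = FALSE])
    stats::model.matrix(~ ., data = cv)
  }
  B <- as.integer(n_permutations)
  perms <- with_seed(seed, {
    vapply(seq_len(B), function(b) lz[sample.int(n)], numeric(n))
  })
  cand <- cbind(lz, perms)  # column 1 = observed, then one per permutation

  pv <- matrix(NA_real_, nrow = B + 1L, ncol = length(keep))
  for (j in seq_along(keep)) {
    cc <- !is.na(Y[, j])
    yj <- Y[cc, j]
    Xj <- Xbase[cc, , drop = FALSE]
    if (engine == "score") {
      pv[, j] <- score_test_pvals(Xj, yj, cand[cc, , drop = FALSE])
    } else {
      for (b in seq_len(B + 1L)) {
        pv[b, j] <- logistic_wald_p(cbind(Xj, cand[cc, b]), yj)
      }
    }
  }
  hits <- pv < alpha
  observed <- sum(hits[1, ], na.rm = TRUE)
  null_counts <- rowSums(hits[-1, , drop = FALSE], na.rm = TRUE)
  permutation_result(observed, null_counts, alpha_nominal = alpha,
                     add_one = add_one, n_dropped = sum(is.na(pv)))
}

#' Summary of a permutation null distribution
#'
#' @param result A `permutation_result` with at least two permutations.
#' @return list(mean, sd, histogram = data.frame(count, n_permutations),
#'   observed_count).
#' @export
null_summary <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  if (result$n_permutations < 2) {
    stop("need >= 2 permutations to summarize", call. = FALSE)
  }
  tab <- table(result$null_counts)
  hist <- data.frame(count = as.integer(names(tab)),
                     n_permutations = as.integer(tab))
  list(mean = mean(result$null_counts),
       sd = stats::sd(result$null_counts),
       histogram = hist,
       observed_count = result$observed_count)
}

#' Plot the permutation null with the observed count marked
#'
#' @param x A `permutation_result`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$null_counts,
                 main = "Permutation null of nominal association counts",
                 xlab = sprintf("phenotypes with p < %g", x$alpha_nominal),
                 xlim = range(c(x$null_counts, x$observed_count)), ...)
  graphics::abline(v = x$observed_count, col = "red", lty = 2, lwd = 2)
  invisible(x)
}
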