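# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 97L * k) %% 2147483646 + 1)
}

z_standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Rank-based inverse-normal transform (Blom offsets); NAs preserved.
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.375) / (sum(ok) + 0.25))
  out
}

# TSV writers format doubles with 17 significant digits so that files
# round-trip bit-exactly through read.delim.
format_full <- function(x) {
  s <- formatC(x, digits = 17, format = "g")
  s[is.na(x)] <- "NA"
  trimws(s)
}

write_tsv_full <- function(df, path) {
  out <- as.data.frame(df)
  isd <- vapply(out, is.double, logical(1))
  out[isd] <- lapply(out[isd], format_full)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Normalise a types argument (data.frame with name/type or named character)
# to a named character vector.
as_type_map <- function(types) {
  if (is.data.frame(types)) {
    stopifnot(all(c("name", "type") %in% names(types)))
    return(stats::setNames(as.character(types$type), as.character(types$name)))
  }
  if (is.character(types) && !is.null(names(types))) return(types)
  stop("`types` must be a data.frame(name, type) or a named character vector",
       call. = FALSE)
}

PHENOTYPE_TYPES <- c("continuous", "ordered_categorical",
                     "unordered_categorical", "binary", "phecode")
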