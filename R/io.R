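# Readers and writers for the bundle's plain-text formats.

#' Read a variant annotation table
#'
#' @param path TSV with header; expected columns include chrom, pos, ref,
#'   alt, ancestral, at least one score column (e.g. phyloP), region_class,
#'   functional_class, info, missing_fraction.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  rec <- read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "ancestral")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rec
}

#' Write a sample-by-variant dosage matrix as TSV
#'
#' First column `sample_id`, one column per variant, full-precision doubles.
#'
#' @param dosages Numeric matrix with sample IDs as rownames.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(sample_id = rownames(dosages),
                   as.data.frame(dosages, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(df, path)
}

#' Read a sample-by-variant dosage matrix from TSV
#'
#' @param path TSV written by [write_dosage_tsv()].
#' @return Numeric matrix, rownames = sample IDs, colnames = variant IDs.
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  stopifnot("sample_id" %in% names(df))
  ids <- as.character(df$sample_id)
  mat <- as.matrix(df[setdiff(names(df), "sample_id")])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Write dosages as a VCF 4.2 file with DS (and optional GT) FORMAT fields
#'
#' @param alt_dosages Sample-by-variant ALT dosage matrix (rownames = IDs).
#' @param records Annotation data.frame with chrom, pos, ref, alt.
#' @param path Output path.
#' @param hard Optional integer hard-genotype matrix for the GT field.
#' @export
write_vcf_dosages <- function(alt_dosages, records, path, hard = NULL) {
  n <- nrow(alt_dosages)
  m <- ncol(alt_dosages)
  stopifnot(nrow(records) == m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(alt_dosages)), collapse = "\t")
  ), con)
  if (m > 0) {
    gt_of <- function(g) c("0/0", "0/1", "1/1")[g + 1L]
    rows <- vapply(seq_len(m), function(j) {
      ds <- format_full(alt_dosages[, j])
      gt <- if (is.null(hard)) rep("./.", n) else gt_of(hard[, j])
      paste(c(records$chrom[j], records$pos[j],
              if ("variant_id" %in% names(records)) records$variant_id[j] else ".",
              records$ref[j], records$alt[j], ".", "PASS", ".", "GT:DS",
              paste(gt, ds, sep = ":")), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Uses the per-sample DS FORMAT field when present, otherwise falls back to
#' summing GT alleles as a hard dosage.
#'
#' @param path VCF 4.2 file (plain text or gzipped).
#' @return Sample-by-variant dosage matrix; column names are
#'   chrom:pos:ref:alt keys.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keys <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
  }
  out <- t(ds)
  colnames(out) <- keys
  storage.mode(out) <- "double"
  out
}

#' Read a phenotype table and its declared types
#'
#' @param path Phenotype TSV (sample_id plus one column per phenotype).
#' @param types_path TSV with columns name, type.
#' @return list(phenotypes = data.frame, types = named character vector).
#' @export
read_phenotypes <- function(path, types_path) {
  phen <- read_tsv(path)
  stopifnot("sample_id" %in% names(phen))
  phen$sample_id <- as.character(phen$sample_id)
  types <- as_type_map(read_tsv(types_path))
  bad <- setdiff(names(types), names(phen))
  if (length(bad)) {
    stop("declared types for absent phenotype columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(phenotypes = phen, types = types)
}
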