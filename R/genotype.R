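#' Construct a genotype matrix
#'
#' The central container for additively coded biallelic SNP genotypes: an
#' \code{n x m} numeric matrix with entries in \{0, 1, 2\} (count of the
#' alternate / A2 allele) or \code{NA} for missing calls, with unique sample
#' IDs as rownames and unique marker IDs as colnames.
#'
#' @param values numeric matrix, entries in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample IDs (default taken
#'   from rownames, or generated).
#' @param marker_ids character vector of unique marker IDs (default taken
#'   from colnames, or generated).
#' @return a \code{genotype_matrix}: a numeric matrix with class attribute.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, marker_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("ind_", seq_len(nrow(values)))
  marker_ids <- marker_ids %||% colnames(values) %||% paste0("snp_", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values)) stop("sample_ids length must equal nrow(values)")
  if (length(marker_ids) != ncol(values)) stop("marker_ids length must equal ncol(values)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(marker_ids)) stop("marker_ids must be unique")
  bad <- !(values %in% c(0, 1, 2)) & !is.na(values)
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA; found ",
                     paste(unique(values[bad])[1:min(3, sum(bad))], collapse = ", "))
  dimnames(values) <- list(as.character(sample_ids), as.character(marker_ids))
  class(values) <- c("genotype_matrix", class(values))
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

sample_ids <- function(g) rownames(g)
marker_ids <- function(g) colnames(g)

#' Read genotypes from file
#'
#' Supported dialects:
#' \describe{
#'   \item{raw}{PLINK \code{--recode A} style whitespace-separated text:
#'     columns FID IID PAT MAT SEX PHENOTYPE then one 0/1/2 column per
#'     marker; \code{NA} for missing.}
#'   \item{vcf}{VCF v4.x; only the GT field is used, mapped
#'     0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA. Multi-allelic
#'     records are rejected.}
#'   \item{csv}{comma-separated, first column sample ID, header row of
#'     marker IDs, entries 0/1/2/NA.}
#' }
#'
#' @param path file path.
#' @param format one of \code{"raw"}, \code{"vcf"}, \code{"csv"} (default
#'   guessed from the file extension).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "raw", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", csv = "csv", raw = "raw",
                     stop("cannot guess format from extension of ", path,
                          "; pass format= explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         raw = read_genotypes_raw(path),
         csv = read_genotypes_csv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "-9"))
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(dt)[1:6]))
    stop("parse error in ", path, " line 1: expected PLINK .raw header ",
         "FID IID PAT MAT SEX PHENOTYPE ...")
  ids <- as.character(dt[["IID"]])
  vals <- as.matrix(dt[, -(1:6), drop = FALSE])
  check_coded_entries(vals, path)
  genotype_matrix(vals, sample_ids = ids, marker_ids = colnames(vals))
}

read_genotypes_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""))
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  check_coded_entries(vals, path)
  genotype_matrix(vals, sample_ids = ids, marker_ids = colnames(vals))
}

check_coded_entries <- function(vals, path) {
  suppressWarnings(storage.mode(vals) <- "double")
  bad_row <- which(apply(vals, 1, function(r) any(!(r %in% c(0, 1, 2)) & !is.na(r))))
  if (length(bad_row))
    stop("parse error in ", path, ": non-0/1/2 genotype on data line ", bad_row[1])
  vals
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    off <- which(multi)[1]
    stop("unsupported multi-allelic record at ", vcf@fix[off, "CHROM"], ":",
         vcf@fix[off, "POS"], " (ALT = ", alt[off], ")")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")   # markers x samples, character
  vals <- t(apply(gt, c(1, 2), parse_gt, path = path))
  mids <- rownames(gt)
  if (is.null(mids)) mids <- paste0(vcf@fix[, "CHROM"], "_", vcf@fix[, "POS"])
  if (anyDuplicated(mids)) mids <- make.unique(mids)
  genotype_matrix(vals, sample_ids = colnames(gt), marker_ids = mids)
}

parse_gt <- function(gt, path) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  a <- suppressWarnings(as.integer(alleles))
  if (length(a) != 2 || anyNA(a) || any(a > 1))
    stop("parse error in ", path, ": unsupported GT '", gt, "'")
  sum(a)
}

#' Write genotypes to file
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param format \code{"raw"} (PLINK-additive text) or \code{"csv"}.
#' @export
write_genotypes <- function(g, path, format = c("raw", "csv")) {
  format <- match.arg(format)
  if (format == "raw") {
    dt <- data.table::data.table(FID = rownames(g), IID = rownames(g),
                                 PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
    dt <- cbind(dt, data.table::as.data.table(unclass(g)))
    data.table::fwrite(dt, path, sep = " ", na = "NA", quote = FALSE)
  } else {
    dt <- data.table::data.table(id = rownames(g))
    dt <- cbind(dt, data.table::as.data.table(unclass(g)))
    data.table::fwrite(dt, path, sep = ",", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Tab-separated two-column table \code{id <TAB> y}; values are continuous
#' phenotypes already corrected for fixed effects.
#'
#' @param path file path.
#' @return named numeric vector of phenotypes.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2) stop("phenotype file needs two columns (id, y): ", path)
  y <- as.numeric(dt[[2]])
  names(y) <- as.character(dt[[1]])
  if (anyDuplicated(names(y))) stop("duplicate sample IDs in ", path)
  y
}

#' @rdname read_phenotypes
#' @param y named numeric phenotype vector.
#' @export
write_phenotypes <- function(y, path) {
  data.table::fwrite(data.table::data.table(id = names(y), y = as.numeric(y)),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
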