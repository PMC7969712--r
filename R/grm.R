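#' VanRaden genomic relationship matrix
#'
#' Computes G = M M' / sum_j 2 p_j q_j, where M is the n x m genotype matrix
#' with 2 p_j subtracted from column j (so genotypes 0/1/2 become
#' -2p_j, 1-2p_j, 2-2p_j), p_j is the in-sample alternate-allele (A2)
#' frequency and q_j = 1 - p_j. Because columns of M are mean-zero, every
#' row of G sums to zero and G is positive semi-definite up to round-off.
#'
#' Allele frequencies are always estimated from the matrix passed in; when
#' training and test individuals are to share one relationship space (the
#' usual genomic-prediction protocol), build G once from the combined matrix
#' and slice it with [grm_submatrix()].
#'
#' @param g a complete [genotype_matrix()] (run [impute_missing()] first).
#' @return a \code{grm}: n x n symmetric numeric matrix with sample IDs as
#'   dimnames and attribute \code{"denominator"} = sum_j 2 p_j q_j.
#' @export
vanraden_grm <- function(g) {
  if (anyNA(g)) stop("genotypes contain missing values; run impute_missing() first")
  if (ncol(g) < 1) stop("need at least one marker")
  x <- unclass(g)
  p <- colMeans(x) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0)
    stop("degenerate input: all markers monomorphic (sum 2 p q = 0)")
  M <- sweep(x, 2, 2 * p)
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(x), rownames(x))
  attr(G, "denominator") <- denom
  class(G) <- c("grm", class(G))
  G
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d, mean diagonal %.3f, denominator %.3f\n",
              nrow(x), ncol(x), mean(diag(x)), attr(x, "denominator")))
  invisible(x)
}

#' Extract a block of a GRM by sample ID
#'
#' @param G a [vanraden_grm()] result (or any matrix with sample-ID dimnames).
#' @param rows,cols character vectors of sample IDs; \code{cols} defaults to
#'   \code{rows}.
#' @return the requested block, in the requested order, as a plain matrix.
#' @export
grm_submatrix <- function(G, rows, cols = rows) {
  ri <- match(rows, rownames(G))
  ci <- match(cols, colnames(G))
  if (anyNA(ri)) stop("unknown sample ID(s): ",
                      paste(rows[is.na(ri)][1:min(3, sum(is.na(ri)))], collapse = ", "))
  if (anyNA(ci)) stop("unknown sample ID(s): ",
                      paste(cols[is.na(ci)][1:min(3, sum(is.na(ci)))], collapse = ", "))
  out <- unclass(G)[ri, ci, drop = FALSE]
  attr(out, "denominator") <- NULL
  out
}

#' Read / write a GRM as square TSV
#'
#' Text round-trip format: header row of sample IDs, first column of sample
#' IDs, full square matrix.
#'
#' @param G a \code{grm}.
#' @param path file path.
#' @export
write_grm <- function(G, path) {
  dt <- data.table::data.table(id = rownames(G))
  dt <- cbind(dt, data.table::as.data.table(unclass(G)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1]])
  G <- as.matrix(dt[, -1, drop = FALSE])
  if (nrow(G) != ncol(G)) stop("GRM file is not square: ", path)
  dimnames(G) <- list(ids, ids)
  class(G) <- c("grm", class(G))
  G
}

# Feature construction shared by all learners: rows of G for the requested
# individuals, restricted to training-individual columns.
grm_features <- function(G, train_ids, test_ids = NULL) {
  X_train <- grm_submatrix(G, train_ids, train_ids)
  X_test <- if (length(test_ids)) grm_submatrix(G, test_ids, train_ids) else NULL
  list(X_train = X_train, X_test = X_test)
}
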