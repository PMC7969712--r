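#' Marker quality-control thresholds
#'
#' Filters are strict: a marker is kept only if MAF > \code{maf_min},
#' call rate > \code{call_rate_min} and HWE p-value > \code{hwe_p_min}.
#' Two named presets mirror common chip-QC protocols:
#' \code{"beef"} = (0.05, 0.95, 1e-5), \code{"dairy"} = (0.01, 0.95, 1e-4).
#'
#' @param maf_min minimum minor allele frequency, in [0, 1].
#' @param call_rate_min minimum non-missing fraction, in [0, 1].
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value, in [0, 1].
#' @return a \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.95, hwe_p_min = 1e-5) {
  v <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(v < 0 | v > 1)) stop("QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param preset \code{"beef"} or \code{"dairy"}.
#' @export
qc_preset <- function(preset = c("beef", "dairy")) {
  switch(match.arg(preset),
         beef = qc_thresholds(0.05, 0.95, 1e-5),
         dairy = qc_thresholds(0.01, 0.95, 1e-4))
}

#' Per-marker QC statistics
#'
#' For each marker: call rate (non-missing fraction), minor allele frequency
#' from non-missing genotypes, and the 1-df chi-square Hardy-Weinberg
#' goodness-of-fit p-value of observed genotype counts (nAA, nAa, naa)
#' against expectations (n p^2, 2 n p q, n q^2), with the allele frequency
#' estimated from the same samples. A marker with all genotypes missing
#' gets NA maf/hwe_p and call rate 0.
#'
#' @param g a [genotype_matrix()] with at least 2 samples.
#' @return data.frame with columns marker_id, maf, call_rate, hwe_p.
#' @export
marker_stats <- function(g) {
  if (nrow(g) < 2) stop("marker_stats needs at least 2 samples")
  x <- unclass(g)
  n_obs <- colSums(!is.na(x))
  call_rate <- n_obs / nrow(x)
  p <- colMeans(x, na.rm = TRUE) / 2      # alternate (A2) allele frequency
  p[n_obs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  n0 <- colSums(x == 0, na.rm = TRUE)
  n1 <- colSums(x == 1, na.rm = TRUE)
  n2 <- colSums(x == 2, na.rm = TRUE)
  hwe_p <- hwe_chisq_p(n0, n1, n2)
  data.frame(marker_id = colnames(x), maf = maf, call_rate = call_rate,
             hwe_p = hwe_p, row.names = NULL, stringsAsFactors = FALSE)
}

# 1-df chi-square HWE test from genotype counts (vectorized).
# Counts are (ref hom, het, alt hom); expectations use p = alt frequency.
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  out <- pchisq(chi2, df = 1, lower.tail = FALSE)
  out[n == 0] <- NA_real_
  out
}

#' Apply marker QC filters
#'
#' Retains markers that pass all three filters (strict inequalities),
#' preserving the original marker order, and reports per-reason failure
#' counts (a marker may fail several filters and is counted in each).
#' Markers with undefined statistics (all-missing) fail the call-rate
#' filter.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with \code{genotypes} (the filtered matrix) and
#'   \code{report}, a \code{qc_report} with fields n_markers_in,
#'   n_failed_maf, n_failed_cr, n_failed_hwe, n_markers_out and the
#'   per-marker \code{stats} table.
#' @export
apply_qc <- function(g, thresholds = qc_preset("beef")) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  st <- marker_stats(g)
  pass_maf <- !is.na(st$maf) & st$maf > thresholds$maf_min
  pass_cr <- st$call_rate > thresholds$call_rate_min
  pass_hwe <- !is.na(st$hwe_p) & st$hwe_p > thresholds$hwe_p_min
  keep <- pass_maf & pass_cr & pass_hwe
  if (!any(keep))
    stop("no markers survive QC; review thresholds (maf_min = ",
         thresholds$maf_min, ", call_rate_min = ", thresholds$call_rate_min,
         ", hwe_p_min = ", thresholds$hwe_p_min, ")")
  out <- genotype_matrix(unclass(g)[, keep, drop = FALSE])
  report <- structure(list(n_markers_in = ncol(g),
                           n_failed_maf = sum(!pass_maf),
                           n_failed_cr = sum(!pass_cr),
                           n_failed_hwe = sum(!pass_hwe),
                           n_markers_out = sum(keep),
                           thresholds = thresholds, stats = st),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("marker QC: %d in -> %d out (failed MAF: %d, call rate: %d, HWE: %d)\n",
              x$n_markers_in, x$n_markers_out, x$n_failed_maf, x$n_failed_cr,
              x$n_failed_hwe))
  invisible(x)
}

#' @rdname apply_qc
#' @param report a \code{qc_report}.
#' @param path output path for the per-marker statistics TSV.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  data.table::fwrite(report$stats, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Missing entries of marker j are replaced by its mean genotype
#' \code{2 p_j} computed from the non-missing samples, so imputation leaves
#' allele frequencies unchanged. Output is a complete matrix.
#'
#' @param g a [genotype_matrix()].
#' @return a complete \code{genotype_matrix} (entries no longer restricted
#'   to integers; downstream use is numeric).
#' @export
impute_missing <- function(g) {
  if (!anyNA(g)) return(g)
  x <- unclass(g)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0))
    stop("marker(s) with all genotypes missing (should have failed QC): ",
         paste(colnames(x)[n_obs == 0][1:min(3, sum(n_obs == 0))], collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  out <- x
  class(out) <- c("genotype_matrix", class(matrix()))
  out
}
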