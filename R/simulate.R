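#' Simulation configuration for genotypes and quantitative phenotypes
#'
#' Defines the population and trait simulated by [simulate_genotypes()] and
#' [simulate_phenotypes()]. Three additive genetic architectures are
#' supported, mirroring the classic dairy-trait trichotomy:
#' \describe{
#'   \item{major_gene}{one QTL carrying \code{major_gene_var_share} of the
#'     additive genetic variance plus \code{n_qtl - 1} small-effect loci
#'     (milk-fat-percentage-like).}
#'   \item{few_moderate}{a handful (\code{n_moderate}, default 10) of
#'     moderate-effect loci plus many small-effect loci
#'     (milk-yield-like).}
#'   \item{polygenic}{\code{n_qtl} loci with i.i.d. Normal small effects
#'     (somatic-cell-score-like).}
#' }
#'
#' @param n_individuals number of individuals (n > 0).
#' @param n_markers number of biallelic SNPs (m > 0), unlinked.
#' @param maf_range length-2 numeric in (0, 0.5]; per-marker allele
#'   frequencies are drawn uniformly on this interval.
#' @param architecture one of \code{"major_gene"}, \code{"few_moderate"},
#'   \code{"polygenic"}.
#' @param h2 target narrow-sense heritability in (0, 1).
#' @param n_qtl number of causal loci; defaults: 101 (major_gene),
#'   500 (few_moderate: 10 moderate + 490 small), 500 (polygenic).
#' @param major_gene_var_share share of genetic variance carried by the
#'   major QTL (major_gene only), in (0, 1).
#' @param n_moderate number of moderate-effect loci (few_moderate only).
#' @param moderate_var_share total genetic-variance share of the moderate
#'   loci (few_moderate only).
#' @param standardize if TRUE, phenotypes are scaled to mean 0 / sd 1
#'   (the convention of pre-standardized dairy datasets).
#' @param seed integer RNG seed; all simulation is deterministic given it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_individuals, n_markers,
                       maf_range = c(0.05, 0.5),
                       architecture = c("polygenic", "major_gene", "few_moderate"),
                       h2 = 0.5,
                       n_qtl = NULL,
                       major_gene_var_share = 0.5,
                       n_moderate = 10,
                       moderate_var_share = 0.5,
                       standardize = TRUE,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_individuals < 1 || n_markers < 1)
    stop("invalid config: n_individuals and n_markers must be positive")
  if (!(h2 > 0 && h2 < 1)) stop("invalid config: h2 must be in (0, 1)")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("invalid config: maf_range must lie within (0, 0.5]")
  n_qtl <- n_qtl %||% switch(architecture,
                             major_gene = 101L, few_moderate = 500L, polygenic = 500L)
  n_qtl <- min(as.integer(n_qtl), as.integer(n_markers))
  if (n_qtl < 1) stop("invalid config: n_qtl must be positive")
  if (!(major_gene_var_share > 0 && major_gene_var_share < 1))
    stop("invalid config: major_gene_var_share must be in (0, 1)")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 maf_range = as.numeric(maf_range),
                 architecture = architecture, h2 = h2, n_qtl = n_qtl,
                 major_gene_var_share = major_gene_var_share,
                 n_moderate = as.integer(min(n_moderate, n_qtl)),
                 moderate_var_share = moderate_var_share,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate unlinked biallelic SNP genotypes
#'
#' Marker j gets an alternate-allele frequency p_j drawn uniformly on
#' \code{maf_range}; genotypes are i.i.d. Binomial(2, p_j) counts
#' (Hardy-Weinberg proportions, no linkage disequilibrium, no missingness).
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with attribute \code{"allele_freq"} holding
#'   the drawn p_j.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_markers
  set.seed(derive_seed(config$seed, 1L))
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  vals <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  g <- genotype_matrix(vals,
                       sample_ids = sprintf("ind_%04d", seq_len(n)),
                       marker_ids = sprintf("snp_%05d", seq_len(m)))
  attr(g, "allele_freq") <- p
  g
}

#' Simulate additive phenotypes under a chosen genetic architecture
#'
#' True genetic values are \code{g = Mc \%*\% effects} with \code{Mc} the
#' column-centered QTL genotypes; residuals are
#' \code{e ~ N(0, var(g) (1 - h2) / h2)} so that the realized heritability
#' var(g)/var(y) targets \code{h2}; \code{y = g + e}, optionally
#' standardized to mean 0 / sd 1.
#'
#' @param genotypes a complete [genotype_matrix()].
#' @param config the [sim_config()] used (or compatible with) the genotypes.
#' @return list with \code{phenotypes} (named numeric vector) and
#'   \code{truth}, a \code{sim_truth} list: \code{qtl_indices},
#'   \code{qtl_effects}, \code{genetic_values}, \code{realized_h2}.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(genotypes)) stop("genotypes must be complete (impute first)")
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (config$n_qtl > m) stop("invalid config: n_qtl exceeds marker count")
  set.seed(derive_seed(config$seed, 2L))

  # QTL positions: resample any candidate that is monomorphic in this sample
  variances <- apply(genotypes, 2, var)
  poly <- which(variances > 0)
  if (length(poly) < 2) stop("fewer than 2 polymorphic markers; cannot simulate")
  n_qtl <- min(config$n_qtl, length(poly))
  qtl <- sort(sample(poly, n_qtl))

  k <- n_qtl
  effects <- switch(config$architecture,
    polygenic = rnorm(k),
    major_gene = {
      eff <- rnorm(k, sd = 0.1)
      if (k > 1) {
        # inflate the first QTL until it carries the requested variance share
        Mq <- scale(genotypes[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
        v_small <- var(as.vector(Mq[, -1, drop = FALSE] %*% eff[-1]))
        s <- config$major_gene_var_share
        # var(major) = s/(1-s) * var(small) when QTL are unlinked
        target <- s / (1 - s) * v_small
        eff[1] <- sign(eff[1]) * sqrt(target / var(Mq[, 1]))
      }
      eff
    },
    few_moderate = {
      n_mod <- min(config$n_moderate, k - 1L)
      eff <- rnorm(k, sd = 0.1)
      if (n_mod >= 1) {
        Mq <- scale(genotypes[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
        idx_mod <- seq_len(n_mod)
        v_small <- var(as.vector(Mq[, -idx_mod, drop = FALSE] %*% eff[-idx_mod]))
        s <- config$moderate_var_share
        v_mod_marker <- (s / (1 - s)) * v_small / n_mod
        eff[idx_mod] <- rnorm(n_mod) * sqrt(v_mod_marker /
                                              pmax(variances[qtl[idx_mod]], 1e-12))
      }
      eff
    })

  Mq <- scale(genotypes[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  g <- as.vector(Mq %*% effects)
  vg <- var(g)
  if (vg <= 0) stop("degenerate simulation: zero genetic variance")
  e <- rnorm(n, sd = sqrt(vg * (1 - config$h2) / config$h2))
  y <- g + e
  realized_h2 <- vg / var(y)
  if (config$standardize) y <- as.vector(scale(y))
  names(y) <- rownames(genotypes)
  truth <- structure(list(qtl_indices = qtl, qtl_effects = effects,
                          genetic_values = stats::setNames(g, rownames(genotypes)),
                          realized_h2 = realized_h2),
                     class = "sim_truth")
  list(phenotypes = y, truth = truth)
}

#' One-call simulation of a genotype + phenotype dataset
#'
#' @param config a [sim_config()].
#' @return list with \code{genotypes}, \code{phenotypes}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  list(genotypes = g, phenotypes = ph$phenotypes, truth = ph$truth)
}
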