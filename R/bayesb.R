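#' BayesB sampler configuration
#'
#' Priors and chain settings of the BayesB marker-effect model
#' y = 1 mu + sum_j m_j alpha_j delta_j + e, where delta_j is a Bernoulli
#' inclusion indicator with P(delta_j = 0) = pi, alpha_j | included ~
#' N(0, sigma2_alpha_j), sigma2_alpha_j ~ scaled-inv-chi2(df_prior,
#' scale_prior) and sigma_e^2 ~ scaled-inv-chi2(df_e, scale_e).
#'
#' When \code{scale_prior} is NULL it is set so the prior mean effect
#' variance matches \code{var(y) h2_prior / ((1 - pi) sum_j 2 p_j q_j)} --
#' i.e. the included markers jointly account for h2_prior of the
#' phenotypic variance a priori.
#'
#' @param pi prior exclusion probability in [0, 1).
#' @param n_iter chain length; \code{burn_in} iterations are discarded and
#'   every \code{thin}-th retained thereafter.
#' @param burn_in,thin chain management, burn_in < n_iter.
#' @param df_prior nu of the effect-variance prior (> 2 for a finite mean).
#' @param scale_prior S of the effect-variance prior (NULL = auto).
#' @param h2_prior prior heritability used by the auto scale rule.
#' @param fixed_effect_var if non-NULL, a single common effect variance
#'   used for all markers and never updated (with pi = 0 this collapses
#'   BayesB onto ridge-regression / rrBLUP-like behavior).
#' @param seed integer RNG seed; the chain is deterministic given it.
#' @export
bayesb_config <- function(pi = 0.95, n_iter = 10000, burn_in = 2000, thin = 5,
                          df_prior = 4.2, scale_prior = NULL, h2_prior = 0.5,
                          fixed_effect_var = NULL, seed = 1L) {
  if (pi < 0 || pi >= 1) stop("pi must be in [0, 1)")
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (n_iter < burn_in + 100) stop("need n_iter >= burn_in + 100")
  structure(list(pi = pi, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 df_prior = df_prior, scale_prior = scale_prior,
                 h2_prior = h2_prior, fixed_effect_var = fixed_effect_var,
                 seed = as.integer(seed)), class = "bayesb_config")
}

#' Fit BayesB by Markov chain Monte Carlo
#'
#' Marginalized Gibbs sampler: for each marker the inclusion indicator is
#' drawn from its full conditional with the effect integrated out
#' (a likelihood-ratio step), the effect is then drawn from its normal full
#' conditional when included; per-marker effect variances and the residual
#' variance are drawn from scaled-inverse-chi-square full conditionals and
#' the intercept from its normal full conditional.
#'
#' @param genotypes training [genotype_matrix()] (complete); markers are
#'   centered internally with training-set allele frequencies, which are
#'   stored for [bayesb_predict()].
#' @param y named training phenotype vector aligned with the genotype rows.
#' @param config a [bayesb_config()].
#' @return a \code{bayesb_posterior}: \code{effect_mean} (posterior mean of
#'   alpha_j delta_j), \code{inclusion_prob}, \code{mu_mean},
#'   \code{sigma_e2_mean}, retained-sample vectors \code{mu_samples} /
#'   \code{sigma_e2_samples}, \code{allele_freq}, \code{marker_ids}.
#' @export
bayesb_fit <- function(genotypes, y, config = bayesb_config()) {
  stopifnot(inherits(config, "bayesb_config"))
  X <- as.matrix(unclass(genotypes))
  if (anyNA(X)) stop("genotypes must be complete (impute first)")
  if (nrow(X) != length(y)) stop("genotype rows and y must be aligned")
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, 2 * p)
  sum2pq <- sum(2 * p * (1 - p))
  nu <- config$df_prior
  S <- config$scale_prior
  if (is.null(S)) {
    v_target <- var(y) * config$h2_prior /
      max((1 - config$pi) * sum2pq, .Machine$double.eps)
    S <- v_target * (nu - 2) / nu
  }
  vy <- var(y)
  nu_e <- 4
  Se <- vy / 2 * (nu_e - 2) / nu_e
  fixed <- !is.null(config$fixed_effect_var)
  set.seed(config$seed)
  res <- bayesb_mcmc(Xc, as.numeric(y), config$pi, config$n_iter,
                     config$burn_in, config$thin, nu, S, nu_e, Se,
                     !fixed, if (fixed) config$fixed_effect_var else 0)
  structure(list(effect_mean = stats::setNames(res$effect_mean, colnames(X)),
                 inclusion_prob = stats::setNames(res$inclusion_prob, colnames(X)),
                 mu_mean = res$mu_mean, sigma_e2_mean = res$sigma_e2_mean,
                 mu_samples = res$mu_samples,
                 sigma_e2_samples = res$sigma_e2_samples,
                 n_retained = res$n_retained,
                 allele_freq = stats::setNames(p, colnames(X)),
                 marker_ids = colnames(X), config = config),
            class = "bayesb_posterior")
}

#' Predict GEBVs from a BayesB posterior
#'
#' GEBV_i = sum_j m_ij alpha_hat_j with test genotypes centered by the
#' training-set allele frequencies.
#'
#' @param posterior a [bayesb_fit()] result.
#' @param genotypes test [genotype_matrix()] with the training markers, in
#'   any order (matched by marker ID).
#' @return named numeric vector of test GEBVs.
#' @export
bayesb_predict <- function(posterior, genotypes) {
  stopifnot(inherits(posterior, "bayesb_posterior"))
  X <- as.matrix(unclass(genotypes))
  if (anyNA(X)) stop("genotypes must be complete (impute first)")
  idx <- match(posterior$marker_ids, colnames(X))
  if (anyNA(idx))
    stop("test genotypes lack training marker(s): ",
         paste(head(posterior$marker_ids[is.na(idx)], 3), collapse = ", "))
  X <- X[, idx, drop = FALSE]
  Xc <- sweep(X, 2, 2 * posterior$allele_freq)
  gebv <- as.numeric(Xc %*% posterior$effect_mean)
  names(gebv) <- rownames(X)
  gebv
}

#' @rdname bayesb_fit
#' @param path output path for the posterior marker summary TSV
#'   (marker_id, effect_mean, inclusion_prob).
#' @export
write_bayesb_summary <- function(posterior, path) {
  data.table::fwrite(data.table::data.table(marker_id = posterior$marker_ids,
                                            effect_mean = posterior$effect_mean,
                                            inclusion_prob = posterior$inclusion_prob),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
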