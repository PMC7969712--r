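#' REML variance components for the single-GRM mixed model
#'
#' Model: y = 1 mu + g + e with g ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2).
#' The restricted likelihood is profiled over the variance ratio
#' delta = sigma_e^2 / sigma_g^2 using the spectral decomposition
#' G = U D U': after rotating y and the intercept by U', the profiled
#' -2 log REML is
#' (n-1) log(sigma_g_hat^2) + sum log(d_i + delta) + log(sum w_i x_i^2) + c,
#' minimized in 1-D over log(delta). Exact for a single random effect.
#'
#' @param y numeric phenotype vector.
#' @param G matching genomic relationship matrix (PSD).
#' @return a \code{variance_components} list: \code{sigma_g2},
#'   \code{sigma_e2}, \code{h2}, \code{delta}, \code{boundary} (TRUE when
#'   the estimate sits at h2 ~ 0 or 1), \code{reml_loglik}.
#' @export
reml_variance_components <- function(y, G) {
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals for REML")
  if (nrow(G) != n) stop("G dimension does not match y")
  eg <- eigen(unclass(G)[seq_len(n), seq_len(n)], symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("G is not positive semi-definite (min eigenvalue ",
         signif(min(eg$values), 3), ")")
  d <- pmax(eg$values, 0)
  ty <- crossprod(eg$vectors, y)
  tx <- crossprod(eg$vectors, rep(1, n))

  neg2_profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    xwx <- sum(w * tx^2)
    beta <- sum(w * tx * ty) / xwx
    r <- ty - tx * beta
    q <- sum(w * r^2)
    sg2 <- q / (n - 1)
    (n - 1) * log(sg2) + sum(log(d + delta)) + log(xwx)
  }
  opt <- optimize(neg2_profile, interval = c(-12, 12), tol = 1e-9)
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  xwx <- sum(w * tx^2)
  beta <- sum(w * tx * ty) / xwx
  q <- sum(w * (ty - tx * beta)^2)
  sigma_g2 <- q / (n - 1)
  sigma_e2 <- delta * sigma_g2
  h2 <- sigma_g2 / (sigma_g2 + sigma_e2)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 delta = delta, boundary = (h2 < 1e-3 || h2 > 1 - 1e-3),
                 reml_loglik = -0.5 * opt$objective),
            class = "variance_components")
}

# Restricted -2 log-likelihood (profiled over sigma_g2) at an arbitrary
# ratio delta; used for optimizer sanity checks.
reml_neg2_profile <- function(y, G, delta) {
  n <- length(y)
  eg <- eigen(unclass(G), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ty <- crossprod(eg$vectors, y); tx <- crossprod(eg$vectors, rep(1, n))
  w <- 1 / (d + delta)
  xwx <- sum(w * tx^2)
  beta <- sum(w * tx * ty) / xwx
  q <- sum(w * (ty - tx * beta)^2)
  (n - 1) * log(q / (n - 1)) + sum(log(d + delta)) + log(xwx)
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

#' GBLUP prediction of test-set breeding values
#'
#' Solves the mixed model for the training individuals and projects onto
#' the test block of G:
#' \code{g_test = G[test, train] (G[train, train] + delta I)^{-1} (y - mu)}
#' with \code{delta = sigma_e^2 / sigma_g^2} and \code{mu} the GLS estimate
#' of the overall mean.
#'
#' @param y_train named training phenotypes.
#' @param G full GRM covering training and test individuals.
#' @param train_ids,test_ids sample-ID character vectors.
#' @param vc a [reml_variance_components()] result (estimated on the
#'   training data when NULL).
#' @return list: \code{gebv} (named test GEBVs), \code{mu},
#'   \code{gebv_train}, \code{vc}.
#' @export
gblup_predict <- function(y_train, G, train_ids, test_ids, vc = NULL) {
  if (is.null(names(y_train))) names(y_train) <- train_ids
  y <- y_train[train_ids]
  if (anyNA(y)) stop("y_train missing entries for some train_ids")
  Gtt <- grm_submatrix(G, train_ids, train_ids)
  vc <- vc %||% reml_variance_components(y, Gtt)
  if (vc$sigma_g2 <= 0) {
    mu <- mean(y)
    z <- rep(0, length(test_ids)); names(z) <- test_ids
    return(list(gebv = z, mu = mu,
                gebv_train = stats::setNames(rep(0, length(train_ids)), train_ids),
                vc = vc))
  }
  delta <- vc$sigma_e2 / vc$sigma_g2
  A <- Gtt + diag(delta, length(train_ids))
  sol <- tryCatch(solve_sym(A, cbind(y, 1)),
                  error = function(e) solve_sym(A + diag(1e-8 * mean(diag(A)),
                                                          nrow(A)), cbind(y, 1)))
  mu <- sum(sol[, 2] * y) / sum(sol[, 2])     # GLS mean: (1'A^-1 y)/(1'A^-1 1)
  alpha <- sol[, 1] - sol[, 2] * mu           # A^{-1} (y - mu)
  gebv_train <- as.numeric(Gtt %*% alpha)
  names(gebv_train) <- train_ids
  gebv <- as.numeric(grm_submatrix(G, test_ids, train_ids) %*% alpha)
  names(gebv) <- test_ids
  list(gebv = gebv, mu = mu, gebv_train = gebv_train, vc = vc)
}

solve_sym <- function(A, B) {
  R <- chol((A + t(A)) / 2)
  backsolve(R, forwardsolve(t(R), B))
}
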