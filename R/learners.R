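#' Base-learner parameter constructors
#'
#' Hyperparameters of the three level-0 learners. SVR uses the
#' epsilon-insensitive loss with a Gaussian kernel
#' k(x, x') = exp(-gamma ||x - x'||^2); KRR is the closed-form kernel ridge
#' predictor f(x) = k' (K + lambda I)^{-1} y; ENET is the elastic-net linear
#' model with penalty alpha * (rho |w|_1 + (1 - rho)/2 |w|_2^2) on the
#' mean-squared-error scale (the scikit-learn / glmnet convention).
#'
#' @param C positive regularization constant.
#' @param epsilon nonnegative tube half-width.
#' @param gamma positive Gaussian-kernel bandwidth; NULL = 1 / n_features.
#' @return a parameter list of class \code{svr_params} / \code{krr_params} /
#'   \code{enet_params}.
#' @export
svr_params <- function(C = 1, epsilon = 0.1, gamma = NULL) {
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be > 0")
  structure(list(C = C, epsilon = epsilon, gamma = gamma), class = "svr_params")
}

#' @rdname svr_params
#' @param lambda nonnegative ridge penalty.
#' @param kernel \code{"linear"}, \code{"gaussian"} or \code{"polynomial"}.
#' @param degree,coef0 polynomial-kernel parameters: (x.y + coef0)^degree.
#' @export
krr_params <- function(lambda = 1, kernel = c("linear", "gaussian", "polynomial"),
                       gamma = NULL, degree = 2, coef0 = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(lambda = lambda, kernel = match.arg(kernel), gamma = gamma,
                 degree = degree, coef0 = coef0), class = "krr_params")
}

#' @rdname svr_params
#' @param alpha nonnegative overall penalty strength.
#' @param rho l1-ratio in [0, 1] (0 = ridge, 1 = lasso).
#' @export
enet_params <- function(alpha = 0.01, rho = 0.5) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(alpha = alpha, rho = rho), class = "enet_params")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X and y must be aligned")
  if (nrow(X) < 2) stop("need at least 2 training samples")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (any(!is.finite(y))) stop("non-finite target values")
  X
}

kernel_matrix <- function(params, X, X2 = X) {
  switch(params$kernel,
         linear = X %*% t(X2),
         gaussian = {
           gamma <- params$gamma %||% (1 / ncol(X))
           d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * X %*% t(X2)
           exp(-gamma * pmax(d2, 0))
         },
         polynomial = (X %*% t(X2) + params$coef0)^params$degree)
}

#' Fit a support vector regression base learner
#'
#' Epsilon-insensitive SVR with Gaussian kernel, solved by libsvm (via
#' e1071). Prediction uses the dual kernel expansion
#' f(x) = sum_i beta_i k(x, x_i) + b.
#'
#' @param X numeric feature matrix (typically rows of a GRM over training
#'   columns); rownames are preserved for bookkeeping.
#' @param y numeric response aligned with rows of X.
#' @param params an [svr_params()].
#' @return a \code{gs_learner} with a \code{predict} method.
#' @export
fit_svr <- function(X, y, params = svr_params()) {
  X <- check_xy(X, y)
  gamma <- params$gamma %||% (1 / ncol(X))
  model <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                      cost = params$C, epsilon = params$epsilon, gamma = gamma,
                      scale = FALSE, tolerance = 1e-4, fitted = FALSE)
  structure(list(kind = "svr", params = params, gamma = gamma, model = model,
                 empty = model$tot.nSV == 0), class = "gs_learner")
}

#' Fit a kernel ridge regression base learner
#'
#' Closed-form dual solution \code{d = (K + lambda I)^{-1} y} computed by a
#' Cholesky factorization of the (symmetrized, jittered if needed) kernel
#' matrix; prediction is \code{f(x) = k(x, .) d}.
#'
#' @inheritParams fit_svr
#' @param params a [krr_params()].
#' @export
fit_krr <- function(X, y, params = krr_params()) {
  X <- check_xy(X, y)
  K <- kernel_matrix(params, X)
  A <- (K + t(K)) / 2 + diag(params$lambda, nrow(X))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    if (params$lambda == 0)
      stop("singular kernel matrix with lambda = 0; use lambda > 0")
    R <- chol(A + diag(1e-10 * mean(diag(A)), nrow(A)))
  }
  dual <- backsolve(R, forwardsolve(t(R), y))
  structure(list(kind = "krr", params = params, X_train = X, dual = dual),
            class = "gs_learner")
}

#' Fit an elastic-net base learner
#'
#' Coordinate-descent elastic net (glmnet) with intercept, on the objective
#' \code{(1/2n) ||y - b - X w||^2 + alpha (rho |w|_1 + (1-rho)/2 |w|_2^2)}.
#' Features are not internally standardized: rows of a GRM are already on a
#' common scale.
#'
#' @inheritParams fit_svr
#' @param params an [enet_params()].
#' @export
fit_enet <- function(X, y, params = enet_params()) {
  X <- check_xy(X, y)
  # glmnet standardizes y internally, which rescales its lambda by
  # 1 / sd_n(y); compensate so the objective above holds exactly
  sdy <- sqrt(mean((y - mean(y))^2))
  lam <- params$alpha * if (sdy > 0) sdy else 1
  # descend a short path onto the target lambda for stable convergence
  lambda_path <- if (lam > 0) lam * c(64, 16, 4, 1) else {
    lmax <- max(abs(crossprod(X, y - mean(y)))) / nrow(X) / max(params$rho, 1e-3)
    c(lmax * c(1, 0.1, 0.01), 0)
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = params$rho,
                        lambda = lambda_path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e6)
  cf <- coef(fit, s = lam, exact = FALSE)
  structure(list(kind = "enet", params = params,
                 intercept = as.numeric(cf[1]), w = as.numeric(cf[-1])),
            class = "gs_learner")
}

#' @export
predict.gs_learner <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- switch(object$kind,
                svr = if (isTRUE(object$empty))
                  # no support vectors: all residuals inside the tube and
                  # f(x) = -rho everywhere
                  rep(-object$model$rho, nrow(X))
                else as.numeric(predict(object$model, X)),
                krr = as.numeric(kernel_matrix(object$params, X, object$X_train) %*%
                                   object$dual),
                enet = as.numeric(object$intercept + X %*% object$w),
                custom = object$predict_fun(object$model, X))
  names(out) <- rownames(X)
  out
}

#' Fit any registered learner kind
#'
#' @param kind \code{"svr"}, \code{"krr"} or \code{"enet"}.
#' @param X,y training data.
#' @param params matching parameter object (defaults used when NULL).
#' @export
fit_learner <- function(kind, X, y, params = NULL) {
  switch(kind,
         svr = fit_svr(X, y, params %||% svr_params()),
         krr = fit_krr(X, y, params %||% krr_params()),
         enet = fit_enet(X, y, params %||% enet_params()),
         stop("unknown learner kind: ", kind))
}

#' Default hyperparameter grids
#'
#' Grid-search lattices used when a learner spec carries no explicit grid.
#' \code{n_features} scales the Gaussian bandwidth candidates.
#'
#' @param kind learner kind.
#' @param n_features number of feature columns.
#' @return data.frame, one row per lattice point.
#' @export
default_grid <- function(kind, n_features) {
  switch(kind,
         svr = expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5),
                           gamma = c(1, 0.5, 10) / n_features),
         krr = expand.grid(lambda = c(1e-3, 1e-2, 0.1, 1, 10),
                           kernel = c("linear", "gaussian"),
                           stringsAsFactors = FALSE),
         enet = expand.grid(alpha = 10^seq(-4, 0, length.out = 5),
                            rho = c(0.1, 0.5, 0.9)),
         stop("unknown learner kind: ", kind))
}

grid_row_params <- function(kind, row, n_features) {
  row <- as.list(row)
  switch(kind,
         svr = svr_params(C = row$C, epsilon = row$epsilon, gamma = row$gamma),
         krr = krr_params(lambda = row$lambda,
                          kernel = as.character(row$kernel %||% "linear"),
                          gamma = row$gamma %||% (1 / n_features)),
         enet = enet_params(alpha = row$alpha, rho = row$rho))
}

#' Inner-CV grid search over a hyperparameter lattice
#'
#' Scores every lattice point by mean inner-k-fold Pearson accuracy on
#' (X, y) and returns the best row (ties broken by lattice order; a point
#' whose fit fails scores -Inf and the search continues). A singleton grid
#' is returned directly without any inner fitting.
#'
#' @param kind learner kind (\code{"svr"}, \code{"krr"}, \code{"enet"}).
#' @param X,y training data.
#' @param grid data.frame lattice (default [default_grid()]).
#' @param k_inner inner fold count (default 5).
#' @param seed RNG seed for the inner fold plan.
#' @return list: \code{params} (best parameter object), \code{scores}
#'   (lattice with a \code{score} column), \code{best_index}.
#' @export
grid_search <- function(kind, X, y, grid = NULL, k_inner = 5, seed = 1L) {
  X <- as.matrix(X)
  grid <- grid %||% default_grid(kind, ncol(X))
  if (!nrow(grid)) stop("empty grid")
  if (nrow(grid) == 1)
    return(list(params = grid_row_params(kind, grid[1, , drop = FALSE], ncol(X)),
                scores = cbind(grid, score = NA_real_), best_index = 1L))
  n <- nrow(X)
  plan <- make_fold_plan(n, min(k_inner, n), seed = seed)
  scores <- rep(-Inf, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- grid_row_params(kind, grid[i, , drop = FALSE], ncol(X))
    r <- try({
      accs <- vapply(seq_len(plan$k), function(f) {
        hold <- which(plan$assignment == f)
        fit <- fit_learner(kind, X[-hold, , drop = FALSE], y[-hold], params)
        pred <- predict(fit, X[hold, , drop = FALSE])
        if (sd(pred) == 0 || sd(y[hold]) == 0) return(NA_real_)
        pearson_accuracy(y[hold], pred)
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, silent = TRUE)
    if (!inherits(r, "try-error") && is.finite(r)) scores[i] <- r
  }
  best <- which.max(scores)
  list(params = grid_row_params(kind, grid[best, , drop = FALSE], ncol(X)),
       scores = cbind(grid, score = scores), best_index = best)
}
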