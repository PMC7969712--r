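#' Balanced random fold plan
#'
#' Partitions n individuals into k folds of sizes differing by at most one,
#' uniformly at random, deterministically given the seed.
#'
#' @param n number of individuals.
#' @param k number of folds, 2 <= k <= n.
#' @param seed integer RNG seed.
#' @return a \code{fold_plan}: list(n, k, assignment, seed) where
#'   \code{assignment[i]} is the fold label of individual i.
#' @export
make_fold_plan <- function(n, k, seed = 1L) {
  if (k > n) stop("invalid fold plan: k (", k, ") exceeds n (", n, ")")
  if (k < 2) stop("invalid fold plan: need k >= 2")
  set.seed(as.integer(seed))
  assignment <- sample(rep(seq_len(k), length.out = n))
  structure(list(n = as.integer(n), k = as.integer(k),
                 assignment = assignment, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Base-learner specification for stacking
#'
#' Describes one level-0 learner: a registered kind with either fixed
#' \code{params} or a \code{grid} to be tuned by inner cross-validation, or
#' a fully custom learner given by \code{fit}/\code{predict} functions
#' (used e.g. for mock learners in tests).
#'
#' @param kind \code{"svr"}, \code{"krr"}, \code{"enet"} or \code{"custom"}.
#' @param params fixed parameter object (skips tuning when given).
#' @param grid data.frame hyperparameter lattice (NULL = [default_grid()]
#'   when \code{params} is also NULL).
#' @param fit,predict functions \code{fit(X, y) -> model} and
#'   \code{predict(model, X) -> numeric} for \code{kind = "custom"}.
#' @param label column label in the metadata matrix.
#' @export
learner_spec <- function(kind, params = NULL, grid = NULL,
                         fit = NULL, predict = NULL, label = kind) {
  if (kind == "custom" && (is.null(fit) || is.null(predict)))
    stop("custom learner spec needs fit and predict functions")
  structure(list(kind = kind, params = params, grid = grid,
                 fit = fit, predict = predict, label = label),
            class = "learner_spec")
}

#' @rdname learner_spec
#' @export
default_learners <- function() {
  list(learner_spec("svr"), learner_spec("krr"), learner_spec("enet"))
}

# Fit one spec on (X, y): tune if a grid (or nothing) was supplied.
fit_spec <- function(spec, X, y, k_inner = 5, seed = 1L) {
  if (spec$kind == "custom") {
    model <- spec$fit(X, y)
    return(structure(list(kind = "custom", model = model,
                          predict_fun = spec$predict), class = "gs_learner"))
  }
  params <- spec$params
  if (is.null(params)) {
    gs <- grid_search(spec$kind, X, y, grid = spec$grid, k_inner = k_inner,
                      seed = seed)
    params <- gs$params
  }
  fit_learner(spec$kind, X, y, params)
}

#' Generate stacking metadata by out-of-fold prediction
#'
#' For each base learner and each fold f of the plan, the learner is fitted
#' on the training individuals outside f (with inner grid search when the
#' spec carries no fixed params) and predicts fold f, filling the
#' corresponding rows of \code{train_meta}; the out-of-fold prediction for
#' individual i therefore never uses y_i. Test metadata comes from learners
#' refit on the full training set (default) or from averaging the k fold
#' models (\code{test_mode = "average"}).
#'
#' @param learners list of [learner_spec()]s.
#' @param X_train,y_train training features (rows of G over training
#'   columns) and phenotypes.
#' @param X_test test features over the same columns (or NULL).
#' @param plan a [make_fold_plan()] covering exactly the training rows.
#' @param test_mode \code{"refit"} or \code{"average"}.
#' @param k_inner inner fold count for per-fold grid search.
#' @param seed RNG seed for inner tuning.
#' @return list of class \code{stacking_metadata}: \code{train_meta}
#'   (n_train x L), \code{test_meta} (n_test x L or NULL), \code{learners}
#'   (labels), \code{plan}, \code{fitted} (the refit learners).
#' @export
generate_metadata <- function(learners, X_train, y_train, X_test = NULL,
                              plan = NULL, test_mode = c("refit", "average"),
                              k_inner = 5, seed = 1L) {
  test_mode <- match.arg(test_mode)
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n != length(y_train)) stop("X_train rows and y_train must be aligned")
  plan <- plan %||% make_fold_plan(n, 5, seed = seed)
  if (plan$n != n) stop("fold plan covers ", plan$n,
                        " individuals, training set has ", n)
  L <- length(learners)
  labels <- vapply(learners, function(s) s$label, "")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  train_meta <- matrix(NA_real_, n, L, dimnames = list(rownames(X_train), labels))
  test_meta <- if (!is.null(X_test))
    matrix(0, nrow(as.matrix(X_test)), L,
           dimnames = list(rownames(X_test), labels)) else NULL
  fitted <- vector("list", L)

  for (j in seq_len(L)) {
    spec <- learners[[j]]
    for (f in seq_len(plan$k)) {
      hold <- which(plan$assignment == f)
      fit <- tryCatch(
        fit_spec(spec, X_train[-hold, , drop = FALSE], y_train[-hold],
                 k_inner = k_inner, seed = derive_seed(seed, j * 100L + f)),
        error = function(e) stop("base learner '", labels[j], "' failed on fold ",
                                 f, ": ", conditionMessage(e)))
      train_meta[hold, j] <- predict(fit, X_train[hold, , drop = FALSE])
      if (!is.null(test_meta) && test_mode == "average")
        test_meta[, j] <- test_meta[, j] +
          predict(fit, as.matrix(X_test)) / plan$k
    }
    full_fit <- fit_spec(spec, X_train, y_train, k_inner = k_inner,
                         seed = derive_seed(seed, j * 100L))
    fitted[[j]] <- full_fit
    if (!is.null(test_meta) && test_mode == "refit")
      test_meta[, j] <- predict(full_fit, as.matrix(X_test))
  }
  structure(list(train_meta = train_meta, test_meta = test_meta,
                 learners = labels, plan = plan, fitted = fitted),
            class = "stacking_metadata")
}

#' Ordinary least-squares meta-learner
#'
#' Exact OLS of y_train on the out-of-fold metadata (with intercept by
#' default), solved by SVD; if the metadata is rank-deficient (e.g. two
#' identical base learners) the minimum-norm solution is returned with a
#' warning.
#'
#' @param meta a [generate_metadata()] result or a plain matrix.
#' @param y_train training phenotypes.
#' @param intercept include an intercept (default TRUE).
#' @return list: \code{intercept}, \code{weights} (length L, named).
#' @export
fit_meta_ols <- function(meta, y_train, intercept = TRUE) {
  M <- if (inherits(meta, "stacking_metadata")) meta$train_meta else as.matrix(meta)
  if (nrow(M) != length(y_train)) stop("metadata rows and y_train must be aligned")
  if (nrow(M) <= ncol(M) + 1) stop("need n_train > L + 1 for the meta-learner")
  Z <- if (intercept) cbind(`(Intercept)` = 1, M) else M
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(Z))
    warning("rank-deficient metadata (rank ", sum(pos), " < ", ncol(Z),
            "); returning the minimum-norm OLS solution")
  coefs <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y_train)) / sv$d[pos])
  coefs <- as.numeric(coefs)
  if (intercept) list(intercept = coefs[1],
                      weights = stats::setNames(coefs[-1], colnames(M)))
  else list(intercept = 0, weights = stats::setNames(coefs, colnames(M)))
}

#' Fit the stacking ensemble and predict test GEBVs
#'
#' The two-step stacking flow: (1) out-of-fold metadata generation from the
#' base learners over a k_meta-fold plan of the training set; (2) an OLS
#' meta-learner fitted on the metadata; test predictions are
#' \code{intercept + test_meta \%*\% weights}.
#'
#' @param X_train,y_train,X_test features and phenotypes as in
#'   [generate_metadata()].
#' @param learners list of [learner_spec()]s (default: SVR + KRR + ENET).
#' @param k_meta metadata fold count (default 5).
#' @param seed RNG seed (fold plan + inner tuning).
#' @param intercept meta-learner intercept flag.
#' @param test_mode see [generate_metadata()].
#' @param k_inner inner grid-search fold count.
#' @return list of class \code{stacking_model}: \code{predictions} (named
#'   numeric, test GEBVs), \code{meta} (coefficients), \code{metadata},
#'   \code{plan}.
#' @export
self_fit_predict <- function(X_train, y_train, X_test,
                             learners = default_learners(), k_meta = 5,
                             seed = 1L, intercept = TRUE,
                             test_mode = c("refit", "average"), k_inner = 5) {
  plan <- make_fold_plan(nrow(as.matrix(X_train)), k_meta,
                         seed = derive_seed(seed, 7L))
  md <- generate_metadata(learners, X_train, y_train, X_test, plan = plan,
                          test_mode = match.arg(test_mode),
                          k_inner = k_inner, seed = seed)
  meta_fit <- fit_meta_ols(md, y_train, intercept = intercept)
  preds <- as.numeric(meta_fit$intercept + md$test_meta %*% meta_fit$weights)
  names(preds) <- rownames(md$test_meta)
  structure(list(predictions = preds, meta = meta_fit, metadata = md,
                 plan = plan), class = "stacking_model")
}
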