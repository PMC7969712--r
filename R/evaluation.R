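#' Pearson prediction accuracy
#'
#' r = cov(y, y_pre) / sqrt(var(y) var(y_pre)), the correlation between
#' corrected phenotypes and predicted GEBVs -- the standard genomic
#' prediction accuracy. A constant vector makes r undefined and raises an
#' error rather than silently returning 0.
#'
#' @param y corrected phenotypes.
#' @param y_pre predicted GEBVs, same length (>= 3).
#' @return scalar r in [-1, 1].
#' @export
pearson_accuracy <- function(y, y_pre) {
  if (length(y) != length(y_pre)) stop("y and y_pre must have equal length")
  if (length(y) < 3) stop("need at least 3 pairs for Pearson accuracy")
  if (any(!is.finite(y)) || any(!is.finite(y_pre))) stop("non-finite values")
  vy <- var(y); vp <- var(y_pre)
  if (vy == 0 || vp == 0)
    stop("undefined correlation: constant ", if (vy == 0) "y" else "y_pre")
  r <- cov(y, y_pre) / sqrt(vy * vp)
  min(max(r, -1), 1)
}

new_cv_result <- function(method, fold_acc, seed, extra = NULL) {
  ok <- !is.na(fold_acc)
  structure(list(method = method,
                 fold_accuracy = fold_acc,
                 mean = mean(fold_acc[ok]),
                 sd = sd(fold_acc[ok]),
                 n_folds = length(fold_acc),
                 n_used = sum(ok),
                 seed = seed,
                 extra = extra),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: %d-fold CV accuracy %.3f +/- %.3f%s\n", x$method,
              x$n_folds, x$mean, x$sd,
              if (x$n_used < x$n_folds)
                sprintf(" (%d fold(s) undefined, excluded)",
                        x$n_folds - x$n_used) else ""))
  invisible(x)
}

# Fit + predict one fold for a registered method. `data` carries the
# precomputed shared pieces (genotypes, phenotypes, G).
fold_predict <- function(method, data, train_ids, test_ids, seed, config) {
  y_train <- data$phenotypes[train_ids]
  if (is.function(method)) return(method(data, train_ids, test_ids))
  if (inherits(method, "learner_spec")) {
    ft <- grm_features(data$G, train_ids, test_ids)
    fit <- fit_spec(method, ft$X_train, y_train,
                    k_inner = config$k_inner %||% 5, seed = seed)
    return(predict(fit, ft$X_test))
  }
  switch(method,
    svr = , krr = , enet = {
      spec <- learner_spec(method, params = config$params,
                           grid = config$grid)
      ft <- grm_features(data$G, train_ids, test_ids)
      fit <- fit_spec(spec, ft$X_train, y_train,
                      k_inner = config$k_inner %||% 5, seed = seed)
      predict(fit, ft$X_test)
    },
    self = {
      ft <- grm_features(data$G, train_ids, test_ids)
      sm <- self_fit_predict(ft$X_train, y_train, ft$X_test,
                             learners = config$learners %||% default_learners(),
                             k_meta = config$k_meta %||% 5, seed = seed,
                             intercept = config$intercept %||% TRUE,
                             test_mode = config$test_mode %||% "refit",
                             k_inner = config$k_inner %||% 5)
      structure(sm$predictions, base_meta = sm$metadata$test_meta)
    },
    gblup = {
      vc <- reml_variance_components(y_train,
                                     grm_submatrix(data$G, train_ids, train_ids))
      gblup_predict(y_train, data$G, train_ids, test_ids, vc)$gebv
    },
    bayesb = {
      cfg <- config$bayesb %||% bayesb_config()
      cfg$seed <- seed
      post <- bayesb_fit(data$genotypes[train_ids, , drop = FALSE], y_train, cfg)
      bayesb_predict(post, data$genotypes[test_ids, , drop = FALSE])
    },
    stop("unknown method: ", method))
}

#' K-fold cross-validated prediction accuracy
#'
#' The evaluation protocol: the data are split into k random balanced
#' folds; each fold in turn is the test set, the remaining folds the
#' training set, and the whole pipeline (variance-component estimation,
#' hyperparameter tuning, metadata generation) runs inside the training
#' side only. Per-fold Pearson accuracies are aggregated to mean +/- sd
#' (sd across folds). Folds whose accuracy is undefined (constant
#' predictions) are excluded from the aggregate with a warning.
#'
#' @param method one of \code{"svr"}, \code{"krr"}, \code{"enet"},
#'   \code{"self"}, \code{"gblup"}, \code{"bayesb"}; or a [learner_spec()];
#'   or a function \code{(data, train_ids, test_ids) -> predictions} (data
#'   has elements genotypes, phenotypes, G).
#' @param genotypes complete [genotype_matrix()].
#' @param phenotypes named numeric vector aligned with the genotype rows.
#' @param k fold count (default 20); every fold must have >= 3
#'   individuals, so leave-one-out is rejected.
#' @param seed RNG seed (fold plan + per-fold pipeline seeds).
#' @param plan optional precomputed [make_fold_plan()] (shared-fold
#'   comparisons); overrides k/seed for the split.
#' @param config method options: \code{params}/\code{grid}/\code{k_inner}
#'   for single learners, \code{learners}/\code{k_meta}/\code{intercept}/
#'   \code{test_mode} for \code{"self"}, \code{bayesb} (a
#'   [bayesb_config()]) for \code{"bayesb"}.
#' @param G optional precomputed [vanraden_grm()] of all individuals.
#' @return a \code{cv_result}; for \code{method = "self"} the \code{extra}
#'   field holds a per-fold accuracy matrix of the base learners (computed
#'   from their refit-on-training test predictions on the same folds).
#' @export
cross_validate <- function(method, genotypes, phenotypes, k = 20, seed = 1L,
                           plan = NULL, config = list(), G = NULL) {
  ids <- rownames(genotypes)
  if (is.null(names(phenotypes))) names(phenotypes) <- ids
  y <- phenotypes[ids]
  if (anyNA(y)) stop("phenotypes missing for some genotyped individuals")
  n <- length(ids)
  plan <- plan %||% make_fold_plan(n, k, seed = seed)
  fold_sizes <- tabulate(plan$assignment, plan$k)
  if (min(fold_sizes) < 3)
    stop("fold plan has a fold of size ", min(fold_sizes),
         "; Pearson accuracy needs >= 3 test individuals per fold ",
         "(leave-one-out is not supported)")
  label <- if (is.character(method)) method
           else if (inherits(method, "learner_spec")) method$label else "custom"
  needs_grm <- is.null(G) &&
    (inherits(method, "learner_spec") ||
       (is.character(method) && method %in% c("svr", "krr", "enet", "self", "gblup")))
  data <- list(genotypes = genotypes, phenotypes = y,
               G = if (needs_grm) vanraden_grm(genotypes) else G)

  fold_acc <- rep(NA_real_, plan$k)
  base_acc <- NULL
  for (f in seq_len(plan$k)) {
    test_ids <- ids[plan$assignment == f]
    train_ids <- ids[plan$assignment != f]
    preds <- fold_predict(method, data, train_ids, test_ids,
                          seed = derive_seed(seed, f), config = config)
    bm <- attr(preds, "base_meta")
    pv <- if (is.null(names(preds))) as.numeric(preds)
          else as.numeric(preds)[match(test_ids, names(preds))]
    fold_acc[f] <- tryCatch(pearson_accuracy(y[test_ids], pv),
                            error = function(e) {
                              warning("fold ", f, ": ", conditionMessage(e),
                                      "; excluded from the mean")
                              NA_real_
                            })
    if (!is.null(bm)) {
      if (is.null(base_acc))
        base_acc <- matrix(NA_real_, plan$k, ncol(bm),
                           dimnames = list(NULL, colnames(bm)))
      for (j in seq_len(ncol(bm)))
        base_acc[f, j] <- tryCatch(pearson_accuracy(y[test_ids], bm[, j]),
                                   error = function(e) NA_real_)
    }
  }
  new_cv_result(label, fold_acc, seed = plan$seed,
                extra = if (!is.null(base_acc)) list(base_accuracy = base_acc))
}

#' Compare methods on shared cross-validation folds
#'
#' All methods are evaluated on byte-identical train/test splits (one fold
#' plan drawn per comparison), making the per-method means directly
#' comparable, paired by fold.
#'
#' @param methods character vector (or named list) of methods accepted by
#'   [cross_validate()].
#' @param genotypes,phenotypes,k,seed as in [cross_validate()].
#' @param configs optional named list of per-method config lists.
#' @return a \code{method_comparison}: \code{results} (named list of
#'   cv_results), \code{summary} data.frame (method, mean, sd),
#'   \code{mean_diff} pairwise mean-difference matrix, \code{plan}.
#' @export
compare_methods <- function(methods, genotypes, phenotypes, k = 20, seed = 1L,
                            configs = list()) {
  n <- nrow(genotypes)
  plan <- make_fold_plan(n, k, seed = seed)
  labels <- names(methods) %||% vapply(methods, function(m)
    if (is.character(m)) m else "custom", "")
  if (is.null(names(methods))) names(methods) <- labels
  needs_grm <- any(vapply(methods, function(m)
    inherits(m, "learner_spec") ||
      (is.character(m) && m %in% c("svr", "krr", "enet", "self", "gblup")), TRUE))
  G <- if (needs_grm) vanraden_grm(genotypes) else NULL
  results <- lapply(names(methods), function(lbl)
    cross_validate(methods[[lbl]], genotypes, phenotypes, seed = seed,
                   plan = plan, config = configs[[lbl]] %||% list(), G = G))
  names(results) <- names(methods)
  means <- vapply(results, `[[`, numeric(1), "mean")
  summary <- data.frame(method = names(methods), mean = means,
                        sd = vapply(results, `[[`, numeric(1), "sd"),
                        row.names = NULL)
  mean_diff <- outer(means, means, "-")
  dimnames(mean_diff) <- list(names(methods), names(methods))
  structure(list(results = results, summary = summary, mean_diff = mean_diff,
                 plan = plan, seed = seed), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison, %d-fold CV (seed %d):\n", x$plan$k, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %.3f +/- %.3f\n", s$method[i], s$mean[i], s$sd[i]))
  invisible(x)
}
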