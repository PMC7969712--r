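test_that("fold plans are balanced, exhaustive and deterministic", {
  p <- make_fold_plan(10, 5, seed = 1)
  expect_equal(unname(tabulate(p$assignment, 5)), rep(2L, 5))

  p2 <- make_fold_plan(7, 3, seed = 2)
  expect_equal(sort(tabulate(p2$assignment, 3), decreasing = TRUE), c(3L, 2L, 2L))
  expect_length(p2$assignment, 7)

  expect_identical(make_fold_plan(50, 5, seed = 9)$assignment,
                   make_fold_plan(50, 5, seed = 9)$assignment)
  expect_error(make_fold_plan(4, 5), "exceeds")
  expect_error(make_fold_plan(4, 1), "k >= 2")
})

test_that("an oracle base learner reproduces the phenotypes in the metadata", {
  d <- sim_data(60, 100, seed = 21)
  ids <- rownames(d$genotypes)
  tr <- ids[1:45]; te <- ids[46:60]
  G <- vanraden_grm(d$genotypes)
  ft <- stackgs:::grm_features(G, tr, te)
  plan <- make_fold_plan(45, 5, seed = 4)
  md <- generate_metadata(list(oracle_spec(d$phenotypes)), ft$X_train,
                          d$phenotypes[tr], ft$X_test, plan = plan)
  expect_equal(unname(md$train_meta[, 1]), unname(d$phenotypes[tr]),
               tolerance = 1e-12)
  expect_equal(unname(md$test_meta[, 1]), unname(d$phenotypes[te]),
               tolerance = 1e-12)
})

test_that("out-of-fold metadata never sees its own response (leakage guard)", {
  set.seed(22)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("s", 1:n), NULL))
  y <- rnorm(n)
  plan <- make_fold_plan(n, 5, seed = 8)
  md <- generate_metadata(list(mean_spec()), X, y, X_test = NULL, plan = plan)
  for (i in seq_len(n)) {
    f <- plan$assignment[i]
    expected <- mean(y[plan$assignment != f])     # recomputed independently
    expect_equal(unname(md$train_meta[i, 1]), expected, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(md$train_meta[i, 1], mean(y))))
  }
})

test_that("metadata bookkeeping: every row written once, shape n x L", {
  set.seed(23)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("s", 1:n), NULL))
  y <- rnorm(n)
  specs <- list(mean_spec("m1"), ridge_spec(1, "r1"), oracle_spec(setNames(y, rownames(X))))
  md <- generate_metadata(specs, X, y, X_test = X[1:10, ],
                          plan = make_fold_plan(n, 5, seed = 3))
  expect_equal(dim(md$train_meta), c(100L, 3L))
  expect_equal(dim(md$test_meta), c(10L, 3L))
  expect_false(anyNA(md$train_meta))
  expect_equal(colnames(md$train_meta), c("m1", "r1", "oracle"))
})

test_that("the OLS meta-learner inverts affine metadata and matches normal equations", {
  set.seed(24)
  y <- rnorm(50)
  # perfect regressor
  f1 <- fit_meta_ols(matrix(y, ncol = 1), y)
  expect_equal(f1$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(f1$weights), 1, tolerance = 1e-10)

  # affine inversion: meta = 2y + 3 -> weight 0.5, intercept -1.5
  f2 <- fit_meta_ols(matrix(2 * y + 3, ncol = 1), y)
  expect_equal(unname(f2$weights), 0.5, tolerance = 1e-10)
  expect_equal(f2$intercept, -1.5, tolerance = 1e-10)

  # L = 3 random metadata vs the normal-equations oracle
  M <- matrix(rnorm(150), 50, 3)
  f3 <- fit_meta_ols(M, y)
  Z <- cbind(1, M)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(c(f3$intercept, unname(f3$weights)), as.numeric(beta),
               tolerance = 1e-8)

  # duplicated learners: minimum-norm solution with a warning
  Md <- cbind(M[, 1], M[, 1])
  expect_warning(f4 <- fit_meta_ols(Md, y), "rank-deficient")
  expect_equal(f4$weights[1], f4$weights[2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a single-base-learner stack is an affine transform of that learner", {
  d <- sim_data(120, 300, seed = 25)
  ids <- rownames(d$genotypes)
  tr <- ids[1:90]; te <- ids[91:120]
  G <- vanraden_grm(d$genotypes)
  ft <- stackgs:::grm_features(G, tr, te)
  spec <- learner_spec("krr", params = krr_params(lambda = 1, kernel = "linear"))
  sm <- self_fit_predict(ft$X_train, d$phenotypes[tr], ft$X_test,
                         learners = list(spec), seed = 6)
  base <- predict(fit_krr(ft$X_train, d$phenotypes[tr],
                          krr_params(lambda = 1, kernel = "linear")), ft$X_test)
  w <- unname(sm$meta$weights[1])
  expect_gt(w, 0)
  expect_equal(unname(sm$predictions), unname(sm$meta$intercept + w * base),
               tolerance = 1e-10)
  r_self <- pearson_accuracy(d$phenotypes[te], sm$predictions)
  r_base <- pearson_accuracy(d$phenotypes[te], base)
  expect_equal(r_self, r_base, tolerance = 1e-12)
})

test_that("stacking is invariant to base-learner order", {
  set.seed(26)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("s", 1:n), NULL))
  y <- as.numeric(X %*% rnorm(6) + rnorm(n))
  Xt <- X[1:12, ]
  specs <- list(ridge_spec(0.5, "rA"), ridge_spec(5, "rB"), mean_spec("mC"))
  s1 <- self_fit_predict(X, y, Xt, learners = specs, seed = 5)
  s2 <- self_fit_predict(X, y, Xt, learners = rev(specs), seed = 5)
  expect_equal(unname(s1$predictions), unname(s2$predictions), tolerance = 1e-10)
  expect_equal(s1$meta$weights[c("rA", "rB", "mC")],
               s2$meta$weights[c("rA", "rB", "mC")], tolerance = 1e-10)
})

test_that("fold-model averaging is available as the alternative test-metadata mode", {
  set.seed(27)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("s", 1:n), NULL))
  y <- as.numeric(X %*% rnorm(4) + rnorm(n, sd = 0.5))
  Xt <- X[1:10, ] + 0.1
  plan <- make_fold_plan(n, 5, seed = 2)
  md_avg <- generate_metadata(list(mean_spec()), X, y, Xt, plan = plan,
                              test_mode = "average")
  # averaging five fold-trained mean predictors = mean of the fold means
  fold_means <- vapply(1:5, function(f) mean(y[plan$assignment != f]), numeric(1))
  expect_equal(unname(md_avg$test_meta[, 1]), rep(mean(fold_means), 10),
               tolerance = 1e-12)
  md_refit <- generate_metadata(list(mean_spec()), X, y, Xt, plan = plan,
                                test_mode = "refit")
  expect_equal(unname(md_refit$test_meta[, 1]), rep(mean(y), 10),
               tolerance = 1e-12)
})

test_that("meta-learner respects the no-intercept flag", {
  set.seed(28)
  y <- rnorm(40)
  f <- fit_meta_ols(matrix(y, ncol = 1), y, intercept = FALSE)
  expect_equal(f$intercept, 0)
  expect_equal(unname(f$weights), 1, tolerance = 1e-10)
})
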