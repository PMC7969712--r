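make_xy <- function(n = 30, m = 6, seed = 90, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m, dimnames = list(paste0("s", 1:n), NULL))
  y <- as.numeric(X %*% rnorm(m) + rnorm(n, sd = noise))
  list(X = X, y = y)
}

test_that("SVR handles the flat and saturated-tube limits", {
  d <- make_xy(25, 4)
  yc <- rep(3.7, 25)
  f <- fit_svr(d$X, yc, svr_params(C = 1, epsilon = 0.1))
  expect_lt(max(abs(predict(f, d$X) - 3.7)), 0.1 + 1e-6)

  # epsilon swallowing the response range with tiny C: near-constant output
  f2 <- fit_svr(d$X, d$y, svr_params(C = 1e-3, epsilon = diff(range(d$y))))
  expect_lt(sd(predict(f2, d$X)), 0.05 * sd(d$y))
})

test_that("the SVR solution satisfies the dual KKT optimality certificate", {
  d <- make_xy(30, 5, seed = 91)
  C <- 2; eps <- 0.15; gamma <- 0.2
  f <- fit_svr(d$X, d$y, svr_params(C = C, epsilon = eps, gamma = gamma))
  m <- f$model
  # reconstruct the kernel expansion by hand
  K <- exp(-gamma * as.matrix(dist(d$X))^2)
  beta <- rep(0, 30)
  beta[m$index] <- m$coefs
  pred_hand <- as.numeric(K %*% beta) - m$rho
  expect_equal(unname(predict(f, d$X)), pred_hand, tolerance = 1e-8)

  tol <- 5e-3 * (1 + max(abs(d$y)))
  resid <- pred_hand - d$y
  expect_lt(abs(sum(beta)), tol)                   # equality constraint
  expect_lt(max(abs(beta)) - C, tol)               # box constraint
  inactive <- abs(beta) < 1e-8
  atbound <- abs(abs(beta) - C) < 1e-8
  interior <- !inactive & !atbound
  # complementary slackness of the epsilon-insensitive loss
  expect_true(all(abs(resid[inactive]) <= eps + tol))
  expect_true(all(abs(abs(resid[interior]) - eps) <= tol))
  expect_true(all(abs(resid[atbound]) >= eps - tol))
})

test_that("KRR reduces to interpolation, shrinkage, and the direct inverse", {
  d <- make_xy(20, 5, seed = 92)
  # strictly PD Gaussian kernel, lambda = 0: exact interpolation
  f0 <- fit_krr(d$X, d$y, krr_params(lambda = 0, kernel = "gaussian", gamma = 0.3))
  expect_equal(unname(predict(f0, d$X)), d$y, tolerance = 1e-8)

  # K = I (features are orthonormal rows), lambda = 1: predictions y/2
  Xi <- diag(6)
  yi <- rnorm(6)
  fi <- fit_krr(Xi, yi, krr_params(lambda = 1, kernel = "linear"))
  expect_equal(unname(predict(fi, Xi)), yi / 2, tolerance = 1e-12)

  # direct-inverse oracle at n = 50
  d2 <- make_xy(50, 8, seed = 93)
  lam <- 0.7
  f <- fit_krr(d2$X, d2$y, krr_params(lambda = lam, kernel = "gaussian", gamma = 0.1))
  K <- exp(-0.1 * as.matrix(dist(d2$X))^2)
  pred_oracle <- as.numeric(K %*% solve(K + lam * diag(50), d2$y))
  expect_equal(unname(predict(f, d2$X)), pred_oracle, tolerance = 1e-10)

  # singular K with lambda = 0 is an explicit error
  Xs <- matrix(rep(1, 12), 6, 2)
  expect_error(fit_krr(Xs, rnorm(6), krr_params(lambda = 0, kernel = "linear")),
               "lambda > 0")
})

test_that("elastic net recovers its unpenalized, fully-shrunk and ridge limits", {
  d <- make_xy(60, 8, seed = 94)
  # alpha = 0: ordinary least squares
  f0 <- fit_enet(d$X, d$y, enet_params(alpha = 0, rho = 0.5))
  ols <- unname(coef(lm(d$y ~ d$X)))
  expect_equal(c(f0$intercept, f0$w), ols, tolerance = 1e-6)

  # enormous alpha: all weights zero, predictions = mean(y)
  fb <- fit_enet(d$X, d$y, enet_params(alpha = 1e4, rho = 0.5))
  expect_equal(max(abs(fb$w)), 0)
  expect_equal(unname(predict(fb, d$X)), rep(mean(d$y), 60), tolerance = 1e-8)

  # rho = 0: closed-form ridge on centered data
  d2 <- make_xy(40, 6, seed = 95)
  lam <- 0.25
  fr <- fit_enet(d2$X, d2$y, enet_params(alpha = lam, rho = 0))
  Xc <- scale(d2$X, center = TRUE, scale = FALSE)
  yc <- d2$y - mean(d2$y)
  b <- solve(crossprod(Xc) + diag(40 * lam, 6), crossprod(Xc, yc))
  expect_equal(fr$w, as.numeric(b), tolerance = 1e-7)
})

test_that("learners are deterministic and permutation-equivariant", {
  d <- make_xy(35, 6, seed = 96)
  for (kind in c("svr", "krr", "enet")) {
    p1 <- predict(fit_learner(kind, d$X, d$y), d$X)
    p2 <- predict(fit_learner(kind, d$X, d$y), d$X)
    expect_identical(p1, p2)
    perm <- sample(35)
    p3 <- predict(fit_learner(kind, d$X[perm, ], d$y[perm]), d$X)
    expect_equal(p3, p1, tolerance = 1e-4)
  }
})

test_that("grid search scores the lattice, picks the argmax and is reproducible", {
  d <- make_xy(60, 5, seed = 97, noise = 1)
  grid <- data.frame(lambda = c(1e-4, 0.1, 1, 10, 100), kernel = "linear",
                     stringsAsFactors = FALSE)
  gs <- grid_search("krr", d$X, d$y, grid = grid, k_inner = 4, seed = 3)
  expect_equal(nrow(gs$scores), 5)
  expect_equal(gs$best_index, which.max(gs$scores$score))
  expect_equal(gs$params$lambda, grid$lambda[gs$best_index])

  gs2 <- grid_search("krr", d$X, d$y, grid = grid, k_inner = 4, seed = 3)
  expect_identical(gs$scores, gs2$scores)
  expect_identical(gs$best_index, gs2$best_index)

  # singleton grid short-circuits
  g1 <- grid_search("svr", d$X, d$y,
                    grid = data.frame(C = 2, epsilon = 0.1, gamma = 0.2))
  expect_equal(g1$params$C, 2)
  expect_true(is.na(g1$scores$score))
})

test_that("parameter constructors reject invalid values", {
  expect_error(svr_params(C = -1), "C")
  expect_error(svr_params(epsilon = -0.1), "epsilon")
  expect_error(krr_params(lambda = -1), "lambda")
  expect_error(enet_params(rho = 1.5), "rho")
  expect_error(fit_svr(matrix(c(1, NA, 1, 1), 2, 2), c(1, 2), svr_params()),
               "non-finite")
})
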