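# Shared fixtures, built in code at test time.

# Small complete genotype matrix with controllable size.
tiny_genotypes <- function(n = 10, m = 20, seed = 101, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  genotype_matrix(matrix(rbinom(n * m, 2, rep(p, each = n)), n, m))
}

# Simulated dataset shorthand.
sim_data <- function(n, m, h2 = 0.5, arch = "polygenic", seed = 1, ...) {
  simulate_dataset(sim_config(n, m, h2 = h2, architecture = arch,
                              seed = seed, ...))
}

# Mock learner specs -------------------------------------------------------

# Predicts the true phenotype of any individual (identified by rownames).
oracle_spec <- function(y_full) {
  learner_spec("custom", label = "oracle",
               fit = function(X, y) NULL,
               predict = function(model, X) unname(y_full[rownames(X)]))
}

# Predicts the mean of its own training responses everywhere.
mean_spec <- function(label = "mean") {
  learner_spec("custom", label = label,
               fit = function(X, y) mean(y),
               predict = function(model, X) rep(model, nrow(X)))
}

# Deterministic non-trivial learner: ridge on the features (no RNG), used
# where real learners would be slow or stochastic mocks unsuitable.
ridge_spec <- function(lambda = 1, label = "ridge") {
  learner_spec("custom", label = label,
               fit = function(X, y) {
                 Xc <- scale(X, center = TRUE, scale = FALSE)
                 b <- solve(crossprod(Xc) + diag(lambda, ncol(X)),
                            crossprod(Xc, y - mean(y)))
                 list(b = b, mx = attr(Xc, "scaled:center"), my = mean(y))
               },
               predict = function(model, X)
                 as.numeric(model$my + sweep(X, 2, model$mx) %*% model$b))
}

# Fixed-parameter base learners (no tuning) for fast stacking runs.
fast_learners <- function(m_features) {
  list(learner_spec("svr", params = svr_params(C = 1, epsilon = 0.1,
                                               gamma = 1 / m_features)),
       learner_spec("krr", params = krr_params(lambda = 1, kernel = "linear")),
       learner_spec("enet", params = enet_params(alpha = 0.01, rho = 0.5)))
}
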