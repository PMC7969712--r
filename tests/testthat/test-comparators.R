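test_that("REML recovers simulated variance components and maximizes the criterion", {
  d <- sim_data(500, 800, h2 = 0.5, seed = 31)
  G <- vanraden_grm(d$genotypes)
  vc <- reml_variance_components(d$phenotypes, G)
  expect_lt(abs(vc$h2 - 0.5), 0.15)
  expect_gt(vc$sigma_g2, 0)
  expect_gt(vc$sigma_e2, 0)

  # optimizer sanity: the returned ratio beats 20 random grid points
  set.seed(32)
  deltas <- exp(runif(20, -8, 8))
  obj_opt <- stackgs:::reml_neg2_profile(d$phenotypes, G, vc$delta)
  for (dl in deltas)
    expect_gte(stackgs:::reml_neg2_profile(d$phenotypes, G, dl) + 1e-6, obj_opt)
})

test_that("REML flags a pure-noise phenotype as near-zero heritability", {
  set.seed(33)
  d <- sim_data(400, 600, h2 = 0.5, seed = 33)
  G <- vanraden_grm(d$genotypes)
  y_noise <- rnorm(400)
  names(y_noise) <- rownames(d$genotypes)
  vc <- reml_variance_components(y_noise, G)
  expect_lt(vc$h2, 0.2)
})

test_that("GBLUP interpolates when noise-free and shrinks to zero when heritability vanishes", {
  d <- sim_data(50, 300, seed = 34)
  G <- vanraden_grm(d$genotypes)
  ids <- rownames(d$genotypes)
  tr <- ids[1:40]; te <- ids[41:50]
  y <- d$phenotypes

  vc0 <- structure(list(sigma_g2 = 1, sigma_e2 = 0, h2 = 1, delta = 0,
                        boundary = TRUE), class = "variance_components")
  fit <- gblup_predict(y[tr], G, tr, te, vc0)
  expect_equal(unname(fit$gebv_train), unname(y[tr] - fit$mu), tolerance = 1e-6)

  vc_small <- structure(list(sigma_g2 = 1e-10, sigma_e2 = 1, h2 = 1e-10,
                             delta = 1e10, boundary = TRUE),
                        class = "variance_components")
  fit2 <- gblup_predict(y[tr], G, tr, te, vc_small)
  expect_lt(max(abs(fit2$gebv)), 1e-6)
})

test_that("GBLUP is equivariant under a consistent permutation of individuals", {
  d <- sim_data(80, 200, seed = 35)
  G <- vanraden_grm(d$genotypes)
  ids <- rownames(d$genotypes)
  tr <- ids[1:60]; te <- ids[61:80]
  vc <- reml_variance_components(d$phenotypes[tr], grm_submatrix(G, tr, tr))
  f1 <- gblup_predict(d$phenotypes[tr], G, tr, te, vc)
  perm_tr <- sample(tr); perm_te <- sample(te)
  f2 <- gblup_predict(d$phenotypes[perm_tr], G, perm_tr, perm_te, vc)
  expect_equal(f2$gebv[te], f1$gebv[te], tolerance = 1e-8)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-10)
})

test_that("BayesB shrinks everything under a pure-noise phenotype", {
  set.seed(36)
  g <- tiny_genotypes(150, 300, seed = 36, maf = c(0.1, 0.5))
  y <- rnorm(150)
  names(y) <- rownames(g)
  post <- bayesb_fit(g, y, bayesb_config(pi = 0.999, n_iter = 1500,
                                         burn_in = 500, seed = 1))
  expect_lt(mean(post$inclusion_prob), 0.05)
  expect_lt(max(abs(post$effect_mean)), 0.5)
})

test_that("BayesB finds a planted major QTL", {
  d <- sim_data(400, 800, h2 = 0.5, arch = "major_gene", seed = 37)
  post <- bayesb_fit(d$genotypes, d$phenotypes,
                     bayesb_config(pi = 0.95, n_iter = 3000, burn_in = 1000,
                                   seed = 2))
  major <- d$truth$qtl_indices[1]
  rank_major <- rank(-post$inclusion_prob)[major]
  expect_lte(rank_major, 0.05 * 800)   # top 5% of markers
})

test_that("BayesB chains with different seeds agree on the posterior-mean GEBVs", {
  d <- sim_data(200, 400, h2 = 0.5, seed = 38)
  cfgA <- bayesb_config(n_iter = 3000, burn_in = 1000, seed = 11)
  cfgB <- bayesb_config(n_iter = 3000, burn_in = 1000, seed = 99)
  pA <- bayesb_fit(d$genotypes, d$phenotypes, cfgA)
  pB <- bayesb_fit(d$genotypes, d$phenotypes, cfgB)
  gA <- bayesb_predict(pA, d$genotypes)
  gB <- bayesb_predict(pB, d$genotypes)
  expect_gt(cor(gA, gB), 0.95)

  # identical seed: identical chain
  pA2 <- bayesb_fit(d$genotypes, d$phenotypes, cfgA)
  expect_identical(pA$effect_mean, pA2$effect_mean)
})

test_that("BayesB prediction is the linear marker score (loop oracle)", {
  g <- tiny_genotypes(30, 50, seed = 39)
  y <- rnorm(30); names(y) <- rownames(g)
  post <- bayesb_fit(g, y, bayesb_config(n_iter = 400, burn_in = 200,
                                         thin = 1, seed = 3))
  gebv <- bayesb_predict(post, g)
  for (i in seq_len(30)) {
    acc <- 0
    for (j in seq_len(50))
      acc <- acc + (unclass(g)[i, j] - 2 * post$allele_freq[j]) * post$effect_mean[j]
    expect_equal(unname(gebv[i]), unname(acc), tolerance = 1e-10)
  }

  # all-zero effects give all-zero GEBVs; a single effect is proportional
  post0 <- post
  post0$effect_mean[] <- 0
  expect_equal(max(abs(bayesb_predict(post0, g))), 0)
  post1 <- post
  post1$effect_mean[] <- 0; post1$effect_mean[7] <- 2
  centered <- unclass(g)[, 7] - 2 * post$allele_freq[7]
  expect_equal(unname(bayesb_predict(post1, g)), unname(2 * centered),
               tolerance = 1e-12)

  # marker mismatch is an explicit alignment error
  g_missing <- genotype_matrix(unclass(g)[, -3])
  expect_error(bayesb_predict(post, g_missing), "lack training marker")
})

test_that("BayesB with pi = 0 and a common fixed effect variance behaves like GBLUP", {
  d <- sim_data(300, 600, h2 = 0.5, seed = 40)
  G <- vanraden_grm(d$genotypes)
  ids <- rownames(d$genotypes)
  tr <- ids[1:240]; te <- ids[241:300]
  vc <- reml_variance_components(d$phenotypes[tr], grm_submatrix(G, tr, tr))
  gb <- gblup_predict(d$phenotypes[tr], G, tr, te, vc)

  p <- colMeans(d$genotypes[tr, ]) / 2
  fixed_var <- vc$sigma_g2 / sum(2 * p * (1 - p))
  cfg <- bayesb_config(pi = 0, n_iter = 4000, burn_in = 1000,
                       fixed_effect_var = fixed_var, seed = 4)
  post <- bayesb_fit(d$genotypes[tr, ], d$phenotypes[tr], cfg)
  bb <- bayesb_predict(post, d$genotypes[te, ])
  expect_gt(cor(bb, gb$gebv), 0.98)
})

test_that("variance-component edge cases raise informative errors", {
  expect_error(reml_variance_components(rnorm(5), diag(5)), "at least 10")
  y <- rnorm(20)
  expect_error(reml_variance_components(y, -diag(20)), "positive semi-definite")
})
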