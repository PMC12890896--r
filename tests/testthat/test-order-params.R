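test_that("Gram-path order parameters match the explicit-projector oracle", {
  for (seed in 1:5) {
    fx <- rand_feature_pair(P = 8 + seed, N = 40, seed = seed)
    g <- gram_set(fx$X1, fx$X2, path = "finite")
    oc <- oracle_ops(fx$X1, fx$X2, fx$Y1, fx$Y2)
    op <- order_params(g, fx$Y1, fx$Y2)
    expect_lt(abs(op$gamma_feature - oc$gamma_feature), 1e-8)
    expect_lt(abs(op$gamma_RF - oc$gamma_RF), 1e-8)
    expect_lt(abs(op$gamma_rule - oc$gamma_rule), 1e-8)
    expect_lt(abs(gamma_sim(g, fx$Y1, fx$Y2)$gamma_sim - oc$gamma_sim), 1e-8)
  }
})

test_that("identical, opposite, and orthogonal task pairs hit the analytic anchors", {
  fx <- rand_feature_pair(P = 10, N = 40, seed = 2)
  gid <- gram_set(fx$X1, fx$X1, path = "finite")
  op <- order_params(gid, fx$Y1, fx$Y1)
  expect_equal(op$gamma_feature, 1, tolerance = 1e-8)
  expect_equal(op$gamma_RF, 1, tolerance = 1e-8)
  expect_equal(op$gamma_rule, 1, tolerance = 1e-8)
  expect_equal(conflict(op), 0, tolerance = 1e-8)
  sim <- gamma_sim(gid, fx$Y1, fx$Y1)
  expect_equal(sim$gamma_sim, 1, tolerance = 1e-8)
  expect_equal(c(sim$feature_term, sim$cosine_term, sim$projection_term),
               c(1, 1, 1), tolerance = 1e-8)

  # same inputs, flipped labels: rule reverses
  opf <- order_params(gid, fx$Y1, -fx$Y1)
  expect_equal(opf$gamma_rule, -opf$gamma_RF, tolerance = 1e-8)
  expect_equal(conflict(opf), 2, tolerance = 1e-8)
  expect_equal(gamma_sim(gid, fx$Y1, -fx$Y1)$gamma_sim, -1, tolerance = 1e-8)

  # feature rows in orthogonal blocks: no shared subspace
  B1 <- cbind(matrix(rnorm(6 * 12), 6, 12), matrix(0, 6, 12))
  B2 <- cbind(matrix(0, 6, 12), matrix(rnorm(6 * 12), 6, 12))
  go <- gram_set(B1, B2, path = "finite")
  expect_equal(gamma_feature(go), 0, tolerance = 1e-8)
  y <- rep(c(-1, 1), 3)
  expect_lt(abs(gamma_sim(go, y, y)$gamma_sim), 1e-6)
})

test_that("gamma_feature and gamma_rule are exactly symmetric under task exchange", {
  fx <- rand_feature_pair(P = 9, N = 35, seed = 4)
  g12 <- gram_set(fx$X1, fx$X2, path = "finite")
  g21 <- gram_set(fx$X2, fx$X1, path = "finite")
  expect_equal(gamma_feature(g12), gamma_feature(g21), tolerance = 1e-10)
  expect_equal(gamma_rule(g12, fx$Y1, fx$Y2), gamma_rule(g21, fx$Y2, fx$Y1),
               tolerance = 1e-10)
})

test_that("order parameters are invariant to a global feature rescaling", {
  fx <- rand_feature_pair(P = 7, N = 30, seed = 6)
  g <- gram_set(fx$X1, fx$X2, path = "finite")
  for (c_ in c(0.05, 3, 40)) {
    gc <- gram_set(c_ * fx$X1, c_ * fx$X2, path = "finite")
    expect_equal(gamma_feature(gc), gamma_feature(g), tolerance = 1e-8)
    expect_equal(gamma_rf(gc, fx$Y1, fx$Y2), gamma_rf(g, fx$Y1, fx$Y2),
                 tolerance = 1e-8)
    expect_equal(gamma_rule(gc, fx$Y1, fx$Y2), gamma_rule(g, fx$Y1, fx$Y2),
                 tolerance = 1e-8)
    expect_equal(gamma_sim(gc, fx$Y1, fx$Y2)$gamma_sim,
                 gamma_sim(g, fx$Y1, fx$Y2)$gamma_sim, tolerance = 1e-8)
  }
})

test_that("algebraic and ensemble bounds hold across a task-relation grid", {
  for (rs in c(0.4, 0.6)) for (rt in c(0.5, 0.8)) for (rf in c(0, 0.25, 0.5)) {
    vals <- vapply(1:5, function(s) {
      # ensemble bounds presume inputs in general position (N0 >= P)
      sq <- td_pair(P = 40, N0 = 80, rho_shared = rs, rho_target = rt,
                    rho_flip = rf, seed = s + round(100 * (rs + rt + rf)))
      g <- gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = 1)
      op <- order_params(g, sq[[1]]$Y, sq[[2]]$Y)
      # algebraic bounds hold for every single instance
      expect_gte(op$gamma_feature, -1e-8)
      expect_lte(op$gamma_feature, 1 + 1e-8)
      expect_gte(op$gamma_RF, -1e-8)
      # exact Cauchy-Schwarz bound under the PSD cross-projection: the
      # one-sided |gamma_rule| <= gamma_RF form presumes task symmetry and
      # holds only on ensemble averages
      grf_rev <- gamma_rf(gram_set(sq[[2]]$X, sq[[1]]$X, path = "kernel",
                                   depth = 1), sq[[2]]$Y, sq[[1]]$Y)
      expect_lte(abs(op$gamma_rule), sqrt(op$gamma_RF * grf_rev) + 1e-8)
      gs <- gamma_sim(g, sq[[1]]$Y, sq[[2]]$Y)$gamma_sim
      expect_gte(gs, -1 - 1e-6)
      expect_lte(gs, 1 + 1e-6)
      c(op$gamma_RF, op$gamma_rule)
    }, numeric(2))
    # ensemble bounds (gamma_RF <= 1, gamma_rule >= 0 for rho_flip <= 0.5)
    # hold for the seed-averaged values up to finite-P fluctuation
    expect_lte(mean(vals[1, ]), 1 + 0.05)
    expect_gte(mean(vals[2, ]), -0.05)
  }
})

test_that("finite-width order parameters approach the kernel limit", {
  sq <- td_pair(P = 12, N0 = 15, rho_shared = 0.5, rho_target = 1,
                rho_flip = 0.2, seed = 3)
  gk <- gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = 1)
  ok <- order_params(gk, sq[[1]]$Y, sq[[2]]$Y)
  av <- average_order_params(sq[[1]]$X, sq[[2]]$X, sq[[1]]$Y, sq[[2]]$Y,
                             feature_map_spec(1, 8000, 15, seed = 1),
                             n_seeds = 6)
  expect_lt(abs(av$mean[["gamma_RF"]] - ok$gamma_RF), 0.03)
  expect_lt(abs(av$mean[["gamma_rule"]] - ok$gamma_rule), 0.03)
  expect_lt(abs(av$mean[["gamma_feature"]] - ok$gamma_feature), 0.03)
})

test_that("rank-deficient finite Grams are rejected with a clear error", {
  set.seed(10)
  Phi1 <- matrix(rnorm(30 * 10), 30, 10)  # P > N
  g <- gram_set(Phi1, Phi1, path = "finite")
  expect_error(gamma_rf(g, rep(c(-1, 1), 15), rep(c(-1, 1), 15)), "rank deficient")
})

test_that("LMG variance decomposition recovers a planted predictor and is invariant", {
  set.seed(12)
  n <- 80
  tab <- data.frame(gamma_feature = rnorm(n), gamma_RF = rnorm(n),
                    gamma_rule = rnorm(n))
  y <- 0.3 + 2 * tab$gamma_rule + rnorm(n, sd = 0.01)
  shares <- pve_decomposition(tab, y)
  expect_gt(shares[["gamma_rule"]], 0.9)
  expect_equal(sum(shares), 1, tolerance = 1e-10)
  perm <- sample(n)
  expect_equal(pve_decomposition(tab[perm, ], y[perm]), shares, tolerance = 1e-8)
  expect_error(pve_decomposition(tab, rep(1, n)), "constant")
})
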