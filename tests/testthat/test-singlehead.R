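test_that("minimum-norm readout interpolates and equals the scaled rule vector", {
  set.seed(1)
  Phi <- matrix(abs(rnorm(6 * 20)), 6, 20)
  Y <- c(2, 0, 0, -1, 0, 1)
  st <- min_norm_readout(Phi, Y)
  expect_lt(normalized_loss(st, Phi, Y), 1e-10)
  # single nonzero label reproduced exactly
  Y1 <- c(0, 0, 3, 0, 0, 0)
  st1 <- min_norm_readout(Phi, Y1)
  expect_equal(drop(Phi %*% st1$a) / sqrt(20), Y1, tolerance = 1e-10)
  # a / ||Y|| is the rule vector of the order-parameter module
  V <- sqrt(20) * t(Phi) %*% solve(tcrossprod(Phi)) %*% Y / sqrt(sum(Y^2))
  expect_equal(st$a / sqrt(sum(Y^2)), drop(V), tolerance = 1e-10)
  # linearity in the labels
  expect_equal(min_norm_readout(Phi, 3 * Y)$a, 3 * st$a, tolerance = 1e-10)
})

test_that("sequential update is a no-op when the new task is already solved", {
  set.seed(2)
  Phi <- matrix(abs(rnorm(5 * 16)), 5, 16)
  Y <- sample(c(-1, 1), 5, replace = TRUE)
  st <- min_norm_readout(Phi, Y)
  st2 <- sequential_min_change(st, Phi, Y)
  expect_equal(st2$a, st$a, tolerance = 1e-12)
})

test_that("sequential update matches the KKT least-change oracle on toy instances", {
  for (seed in 1:6) {
    set.seed(seed)
    P <- 3; N <- 6
    Phi1 <- matrix(rnorm(P * N), P, N)
    Phi2 <- matrix(rnorm(P * N), P, N)
    Y1 <- rnorm(P); Y2 <- rnorm(P)
    st <- min_norm_readout(Phi1, Y1)
    st2 <- sequential_min_change(st, Phi2, Y2)
    expect_equal(st2$a, oracle_min_change(st$a, Phi2, Y2), tolerance = 1e-10)
    expect_lt(normalized_loss(st2, Phi2, Y2), 1e-10)
  }
})

test_that("normalized loss hits its fixed anchors", {
  set.seed(3)
  Phi <- matrix(abs(rnorm(4 * 10)), 4, 10)
  Y <- c(1, -1, 1, 1)
  st <- min_norm_readout(Phi, Y)
  expect_lt(normalized_loss(st, Phi, Y), 1e-10)
  expect_equal(normalized_loss(rep(0, 10), Phi, Y), 1)       # zero readout
  neg <- min_norm_readout(Phi, -Y)
  expect_equal(normalized_loss(neg, Phi, Y), 4, tolerance = 1e-8)  # predictions -Y
})

test_that("forgetting curves vanish for identical tasks and hit 4 for opposite rules", {
  sq <- td_pair(P = 25, N0 = 12, rho_shared = 1, rho_target = 1,
                rho_flip = 0, seed = 4)
  spec <- feature_map_spec(1, 600, 12, seed = 2)
  cv <- forgetting_curve(sq, spec, path = "kernel")
  expect_equal(cv$F, c(0, 0), tolerance = 1e-10)
  # opposite-rule pair: same inputs, negated labels
  t1 <- sq$tasks[[1]]
  opp <- task_sequence(list(t1, task_dataset(t1$X, -t1$Y, 2L)), "custom")
  expect_equal(forgetting_curve(opp, spec, path = "kernel")$F[2], 4,
               tolerance = 1e-8)
  expect_equal(forgetting_curve(opp, spec, path = "finite")$F[2], 4,
               tolerance = 1e-8)
})

test_that("a two-task curve is consistent with the standalone computation", {
  sq <- td_pair(P = 20, N0 = 10, rho_shared = 0.5, rho_target = 1,
                rho_flip = 0.3, seed = 5)
  spec <- feature_map_spec(1, 500, 10, seed = 7)
  F21 <- forgetting_curve(sq, spec, path = "finite")$F[2]
  Phis <- clforget:::featurize_sequence(sq, spec, "finite")
  st <- min_norm_readout(Phis[[1]], sq[[1]]$Y)
  st <- sequential_min_change(st, Phis[[2]], sq[[2]]$Y)
  expect_equal(F21, normalized_loss(st, Phis[[1]], sq[[1]]$Y), tolerance = 1e-12)
})

test_that("conflict predicts simulated two-task forgetting on symmetric pairs", {
  rel_err <- vapply(1:6, function(s) {
    sq <- td_pair(P = 60, N0 = 60, rho_shared = 0.5, rho_target = 0.6,
                  rho_flip = 0.25, seed = s)
    g <- gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = 1)
    pred <- predict_f21(order_params(g, sq[[1]]$Y, sq[[2]]$Y))
    sim <- kernel_f21(sq)
    c(sim, pred)
  }, numeric(2))
  expect_lt(abs(mean(rel_err[1, ]) / mean(rel_err[2, ]) - 1), 0.1)
})

test_that("the penalty effect is negative for identical tasks and near F21-1 for unrelated ones", {
  spec <- feature_map_spec(1, 400, 40, seed = 3)
  sq_id <- td_pair(P = 30, N0 = 40, rho_shared = 1, rho_target = 1,
                   rho_flip = 0, seed = 6)
  d <- delta_f21(sq_id, spec, path = "kernel")
  expect_lt(abs(d$F21), 1e-8)
  expect_equal(d$delta_F21, -d$F21_lambda0, tolerance = 1e-10)
  expect_lte(d$delta_F21, 0)
  # disjoint stimuli: the lambda = 0 reference readout is uninformative on task 1
  sq_un <- td_pair(P = 30, N0 = 40, rho_shared = 0, rho_target = 0,
                   rho_flip = 0, seed = 7)
  du <- delta_f21(sq_un, spec, path = "kernel")
  expect_equal(du$delta_F21, du$F21 - du$F21_lambda0, tolerance = 1e-12)
  expect_lt(abs(du$F21_lambda0 - 1), 0.35)
})

test_that("exponential fit recovers noiseless parameters within 1 percent", {
  tt <- 1:30
  Fv <- 0.3 * (1 - exp(-(tt - 1) / 4))
  ft <- fit_exponential(Fv)
  expect_lt(abs(ft$Fmax - 0.3) / 0.3, 0.01)
  expect_lt(abs(ft$tau - 4) / 4, 0.01)
})

test_that("exponential fit is robust to additive noise", {
  set.seed(11)
  tt <- 1:30
  base <- 0.3 * (1 - exp(-(tt - 1) / 4))
  errs <- vapply(1:100, function(r) {
    Fv <- base + c(0, rnorm(29, sd = 0.01))
    ft <- fit_exponential(Fv)
    abs(ft$tau - 4) / 4
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("degenerate curves are flagged instead of fitted", {
  expect_warning(ftc <- fit_exponential(c(0, rep(0.2, 9))), "pinned")
  expect_equal(ftc$Fmax, 0.2, tolerance = 0.01)
  ft0 <- fit_exponential(rep(0, 10))
  expect_true(ft0$degenerate)
  expect_equal(ft0$Fmax, 0)
  expect_true(is.na(ft0$tau))
})

test_that("the asymptote inversion matches its closed form and round-trips", {
  expect_equal(predict_fmax(0.2, 1), 0.2 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(predict_fmax(0.2, 1e-6), 0.2, tolerance = 1e-6)  # tau -> 0 limit
  expect_error(predict_fmax(-0.1, 1), "F21")
  tt <- 1:25
  Fv <- 0.4 * (1 - exp(-(tt - 1) / 3))
  ft <- fit_exponential(Fv)
  expect_lt(abs(predict_fmax(Fv[2], ft$tau) - 0.4) / 0.4, 0.01)
})
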