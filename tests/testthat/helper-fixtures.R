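# Shared fixtures and independent oracles used across the suite.

# small random feature pair with full row rank (P < N)
rand_feature_pair <- function(P = 8, N = 30, seed = 1) {
  set.seed(seed)
  list(X1 = matrix(rnorm(P * N), P, N),
       X2 = matrix(rnorm(P * N), P, N),
       Y1 = sample(c(-1, 1), P, replace = TRUE),
       Y2 = sample(c(-1, 1), P, replace = TRUE))
}

# Explicit-projector oracle for the order parameters: materializes the
# N x N projectors and the feature-space bilinear forms directly from the
# defining expressions. Independent of the package's Gram-block algebra.
oracle_ops <- function(X1, X2, Y1, Y2) {
  N <- ncol(X1)
  Pi <- function(X) t(X) %*% solve(X %*% t(X)) %*% X
  Vi <- function(X, Y) sqrt(N) * t(X) %*% solve(X %*% t(X)) %*% Y / sqrt(sum(Y^2))
  P1 <- Pi(X1); P2 <- Pi(X2)
  V1 <- Vi(X1, Y1); V2 <- Vi(X2, Y2)
  P12 <- (P2 %*% t(X1) %*% X1 %*% P2 + P1 %*% t(X2) %*% X2 %*% P1) / (2 * N)
  list(
    gamma_feature = sum(diag(P1 %*% P2)) / nrow(X1),
    gamma_RF = drop(t(V2) %*% P12 %*% V2),
    gamma_rule = drop(t(V2) %*% P12 %*% V1),
    gamma_sim = sum(diag(P1 %*% P2)) / nrow(X1) +
      drop(t(V1) %*% V2) / sqrt(sum(V1^2) * sum(V2^2)) -
      drop(t(V1) %*% P2 %*% V1) / sum(V1^2)
  )
}

# Equality-constrained least-change oracle: minimize ||a - a_prev||^2
# subject to Phi a / sqrt(N) = Y, solved through the KKT system.
oracle_min_change <- function(a_prev, Phi, Y) {
  N <- ncol(Phi)
  P <- nrow(Phi)
  A <- Phi / sqrt(N)
  kkt <- rbind(cbind(diag(N), t(A)),
               cbind(A, matrix(0, P, P)))
  rhs <- c(a_prev, Y)
  drop(solve(kkt, rhs))[seq_len(N)]
}

# two-task target-distractor pair from a fresh Gaussian pool
td_pair <- function(P, N0, rho_shared, rho_target, rho_flip,
                    target_fraction = 0.5, seed = 1) {
  pool <- make_gaussian_pool(4 * P + 200, N0, seed + 7000)
  pars <- td_params(rho_shared, rho_target, rho_flip, target_fraction,
                    P = P, T_tasks = 2L, seed = seed)
  target_distractor_sequence(pool, pars)
}

# simulated two-task forgetting in the exact infinite-width limit:
# min-norm readout for task 1, minimum-change update for task 2, evaluated
# through surrogate features of the joint depth-L kernel Gram
kernel_f21 <- function(seq2, depth = 1) {
  spec <- feature_map_spec(depth = depth, width = 2L, input_dim = ncol(seq2[[1]]$X))
  forgetting_curve(seq2, spec, path = "kernel")$F[2]
}
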