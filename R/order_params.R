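# Task-relation order parameters. All four scalars are functions of the
# tasks' last-layer feature geometry only, so they are computed from the
# P x P Gram blocks G_ij = Phi_i Phi_j^T / N (finite path) or the
# infinite-width kernel (kernel path). Writing u_i = G_ii^{-1} Y_i / ||Y_i||,
# the rule vector is V_i = Phi_i^T u_i / sqrt(N) and every bilinear form
# below reduces to products of Gram blocks with u_1, u_2; the N x N
# projectors are never materialized.

op_duals <- function(grams, Y1, Y2) {
  assert_that(sum(Y1^2) > 0 && sum(Y2^2) > 0, "zero-norm label vector")
  if (!is.null(grams$width) && max(nrow(grams$G11), nrow(grams$G22)) > grams$width) {
    stop(sprintf(
      "finite-path Gram is rank deficient: P = %d exceeds the feature width N = %d; use the kernel path",
      max(nrow(grams$G11), nrow(grams$G22)), grams$width), call. = FALSE)
  }
  list(u1 = jitter_solve(grams$G11, Y1 / sqrt(sum(Y1^2)), grams$jitter),
       u2 = jitter_solve(grams$G22, Y2 / sqrt(sum(Y2^2)), grams$jitter))
}

#' Feature-subspace overlap between two tasks
#'
#' `gamma_feature = Tr(P1 P2) / P`, the normalized overlap of the two tasks'
#' P-dimensional feature subspaces; 1 for identical inputs, 0 for mutually
#' orthogonal feature rows. Label-independent. Computed as
#' `Tr(G11^{-1} G12 G22^{-1} G21) / P`.
#'
#' @param grams a [gram_set()].
#' @return a scalar in `[0, 1]` (up to numerical error).
#' @export
gamma_feature <- function(grams) {
  stopifnot(inherits(grams, "gram_set"))
  A <- jitter_solve(grams$G11, grams$G12, grams$jitter)    # G11^-1 G12
  B <- jitter_solve(grams$G22, t(grams$G12), grams$jitter) # G22^-1 G21
  sum(A * t(B)) / nrow(grams$G11)
}

#' Relevant-feature similarity
#'
#' `gamma_RF = V2' P12 V2` with `P12` the symmetrized cross-projection of
#' one task's feature subspace onto the other's: it measures how much the
#' rule vector of task 2 projects onto the feature subspace shared by both
#' tasks. In Gram algebra,
#' `gamma_RF = (u2' G21 G12 u2 + || G21 G11^{-1} G12 u2 ||^2) / 2`.
#'
#' @param grams a [gram_set()]; `Y1`, `Y2` label vectors.
#' @return a nonnegative scalar (<= 1 for generic task ensembles).
#' @export
gamma_rf <- function(grams, Y1, Y2) {
  u <- op_duals(grams, Y1, Y2)
  G12 <- grams$G12; G21 <- t(G12)
  t1 <- drop(crossprod(G12 %*% u$u2))               # u2' G21 G12 u2
  w <- G21 %*% jitter_solve(grams$G11, G12 %*% u$u2, grams$jitter)
  (t1 + drop(crossprod(w))) / 2
}

#' Rule similarity
#'
#' `gamma_rule = V2' P12 V1`: the similarity of the two tasks' rule vectors
#' after projection onto the shared feature subspace. Exactly symmetric
#' under task exchange. In Gram algebra,
#' `gamma_rule = (u2' G21 G12 G22^{-1} G21 u1 + u2' G21 G11^{-1} G12 G21 u1) / 2`.
#'
#' @inheritParams gamma_rf
#' @return a scalar in `[-gamma_RF, gamma_RF]`.
#' @export
gamma_rule <- function(grams, Y1, Y2) {
  u <- op_duals(grams, Y1, Y2)
  G12 <- grams$G12; G21 <- t(G12)
  a <- G12 %*% u$u2                                    # X1-side image of V2
  b <- G21 %*% u$u1                                    # X2-side image of V1
  t1 <- drop(crossprod(a, G12 %*% jitter_solve(grams$G22, b, grams$jitter)))
  t2 <- drop(crossprod(a, jitter_solve(grams$G11, G12 %*% b, grams$jitter)))
  (t1 + t2) / 2
}

#' All single-head order parameters for a task pair
#'
#' Convenience wrapper returning `gamma_feature`, `gamma_RF`, `gamma_rule`
#' and their difference, the conflict `gamma_RF - gamma_rule`, which is
#' directly proportional to short-term forgetting in the fixed-feature
#' single-head model.
#'
#' @inheritParams gamma_rf
#' @return an object of class `order_params`.
#' @export
order_params <- function(grams, Y1, Y2) {
  gf <- gamma_feature(grams)
  grf <- gamma_rf(grams, Y1, Y2)
  gr <- gamma_rule(grams, Y1, Y2)
  structure(list(gamma_feature = gf, gamma_RF = grf, gamma_rule = gr,
                 conflict = grf - gr),
            class = "order_params")
}

#' @export
print.order_params <- function(x, ...) {
  cat(sprintf("<order_params> gamma_feature=%.4f  gamma_RF=%.4f  gamma_rule=%.4f  conflict=%.4f\n",
              x$gamma_feature, x$gamma_RF, x$gamma_rule, x$conflict))
  invisible(x)
}

#' Conflict between two tasks
#'
#' `gamma_RF - gamma_rule`; twice this value predicts short-term forgetting
#' of task 1 after learning task 2 in the fixed-feature single-head model.
#'
#' @param op an [order_params()] object.
#' @return a nonnegative scalar (up to numerical error).
#' @export
conflict <- function(op) {
  stopifnot(inherits(op, "order_params"))
  op$gamma_RF - op$gamma_rule
}

#' Multihead task-similarity score
#'
#' `gamma_sim = gamma_feature + cos(V1, V2) - V1' P2 V1 / ||V1||^2`, the
#' order parameter that sets the critical load of multihead continual
#' learning. It is 1 for identical tasks, -1 for same-input opposite-rule
#' tasks, and near 0 for tasks with disjoint feature subspaces.
#'
#' @inheritParams gamma_rf
#' @return an object of class `sim_op` with the three addends and their sum.
#' @export
gamma_sim <- function(grams, Y1, Y2) {
  u <- op_duals(grams, Y1, Y2)
  G12 <- grams$G12
  n1 <- drop(crossprod(u$u1, grams$G11 %*% u$u1))   # ||V1||^2
  n2 <- drop(crossprod(u$u2, grams$G22 %*% u$u2))   # ||V2||^2
  assert_that(n1 > 0 && n2 > 0, "zero-norm rule vector")
  feat <- gamma_feature(grams)
  cosv <- drop(crossprod(u$u1, G12 %*% u$u2)) / sqrt(n1 * n2)
  b <- crossprod(G12, u$u1)                          # G21 u1
  proj <- drop(crossprod(b, jitter_solve(grams$G22, b, grams$jitter))) / n1
  structure(list(gamma_sim = feat + cosv - proj,
                 feature_term = feat, cosine_term = cosv, projection_term = proj),
            class = "sim_op")
}

#' @export
print.sim_op <- function(x, ...) {
  cat(sprintf("<sim_op> gamma_sim=%.4f (feature %.4f + cosine %.4f - projection %.4f)\n",
              x$gamma_sim, x$feature_term, x$cosine_term, x$projection_term))
  invisible(x)
}

#' Order parameters averaged over finite-width feature draws
#'
#' The finite-width path is stochastic in the random feature map; this
#' helper featurizes a task pair with `n_seeds` independent maps and
#' returns the mean and spread of every order parameter.
#'
#' @param X1,X2 input matrices; `Y1`, `Y2` labels.
#' @param spec a [feature_map_spec()] (its seed field is replaced per draw).
#' @param n_seeds number of feature draws.
#' @param include_sim also average `gamma_sim`.
#' @return a list with `mean` and `sd` named vectors.
#' @export
average_order_params <- function(X1, X2, Y1, Y2, spec, n_seeds = 40L,
                                 include_sim = FALSE) {
  draws <- vapply(seq_len(n_seeds), function(k) {
    sp <- spec; sp$seed <- derive_seed(spec$seed, "opavg", k)
    Xall <- rbind(X1, X2)
    Phi <- sample_features(sp, Xall)$Phi
    i1 <- seq_len(nrow(X1))
    g <- gram_set(Phi[i1, , drop = FALSE], Phi[-i1, , drop = FALSE], path = "finite")
    op <- order_params(g, Y1, Y2)
    out <- c(gamma_feature = op$gamma_feature, gamma_RF = op$gamma_RF,
             gamma_rule = op$gamma_rule, conflict = op$conflict)
    if (include_sim) out <- c(out, gamma_sim = gamma_sim(g, Y1, Y2)$gamma_sim)
    out
  }, numeric(if (include_sim) 5L else 4L))
  list(mean = rowMeans(draws),
       sd = apply(draws, 1, stats::sd),
       n_seeds = n_seeds)
}
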