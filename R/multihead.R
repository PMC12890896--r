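# Multihead continual learning at finite load: one shared hidden layer
# (L = 1), one frozen readout per finished task, and a quadratic
# perturbation penalty on hidden-weight changes when a new task is learned.
# The zero-temperature Gibbs solution is approximated by its point
# estimate: interpolate the current task while keeping lambda * ||W - W1||^2
# + ridge * ||a||^2 minimal, found by alternating an exact (ridge) head
# solve with Adam steps on the hidden weights under penalty continuation.

#' Training configuration for the multihead trainer
#'
#' @param lambda perturbation-penalty scale; `Inf` (default) requests the
#'   minimum-perturbation interpolator, `0` decouples the tasks.
#' @param sigma weight scale of the Gaussian initialization.
#' @param ridge L2 scale on the new head (stands in for the vanishing
#'   weight-decay term of the zero-temperature limit).
#' @param tol interpolation tolerance on the normalized training loss.
#' @param max_outer maximum continuation stages.
#' @param inner_steps Adam steps on W per continuation stage.
#' @param lr Adam learning rate.
#' @param seed integer seed for the initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lambda = Inf, sigma = 1.0, ridge = 1e-6, tol = 1e-8,
                         max_outer = 30L, inner_steps = 300L, lr = 0.01,
                         seed = 1L) {
  assert_that(tol > 0, "tol must be > 0")
  assert_that(lambda >= 0, "lambda must be >= 0 (Inf allowed)")
  structure(list(lambda = lambda, sigma = sigma, ridge = ridge, tol = tol,
                 max_outer = as.integer(max_outer),
                 inner_steps = as.integer(inner_steps),
                 lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

mh_phi <- function(X, W) pmax(X %*% W / sqrt(ncol(X)), 0)

# exact ridge head solve for f = Phi a / sqrt(N); uses the dual form when
# P < N. ridge -> 0 recovers the minimum-norm interpolator.
mh_head_solve <- function(Phi, y, ridge) {
  n <- ncol(Phi); P <- nrow(Phi)
  if (P <= n) {
    b <- crossprod(Phi, jitter_solve(tcrossprod(Phi) + diag(ridge * n, P),
                                     y, 0))
  } else {
    b <- jitter_solve(crossprod(Phi) + diag(ridge * n, n), crossprod(Phi, y), 0)
  }
  sqrt(n) * drop(b)
}

mh_loss <- function(X, y, W, a) {
  pred <- drop(mh_phi(X, W) %*% a) / sqrt(length(a))
  sum((pred - y)^2) / sum(y^2)
}

# Second-task optimizer: penalty continuation that tracks the
# zero-temperature solution branch. Minimizes
#   0.5 ||f(W, a) - y||^2 + 0.5 mu ||W - W1||^2_F
# by Adam on W with the head re-solved exactly (tiny ridge) along the way,
# ramping mu down by 3x per stage from lambda (a large start for
# lambda = Inf) until the task is interpolated; a Gauss-Newton polish
# (mh_descend) then pushes the training loss to tolerance with minimal
# extra weight motion. Warm-starting each stage keeps the iterate on the
# branch selected by the penalty — in the overfitting regime that branch
# has a diverging head norm and a vanishing weight perturbation.
mh_continue <- function(X, y, W1, cfg, a_ridge = 1e-12, stage_mse = 1e-6,
                        mu_decay = 2) {
  max_stages <- cfg$max_outer
  inner <- cfg$inner_steps
  N0 <- ncol(X); n <- ncol(W1); sn <- sqrt(n)
  lambda <- cfg$lambda
  mu <- if (is.infinite(lambda)) 10 else lambda
  W <- W1
  m1 <- v1 <- matrix(0, N0, n); it <- 0
  a <- mh_head_solve(mh_phi(X, W), y, a_ridge)
  nl <- mh_loss(X, y, W, a)
  stage <- 0L
  while (nl > stage_mse && stage < max_stages) {
    stage <- stage + 1L
    for (k in seq_len(inner)) {
      H <- X %*% W / sqrt(N0)
      Phi <- pmax(H, 0)
      err <- drop(Phi %*% a) / sn - y
      Gm <- (err %o% (a / sn)) * (H > 0)
      grad <- crossprod(X, Gm) / sqrt(N0) + mu * (W - W1)
      it <- it + 1
      m1 <- 0.9 * m1 + 0.1 * grad
      v1 <- 0.999 * v1 + 0.001 * grad^2
      W <- W - cfg$lr * (m1 / (1 - 0.9^it)) / (sqrt(v1 / (1 - 0.999^it)) + 1e-8)
      if (k %% 25L == 0L) a <- mh_head_solve(mh_phi(X, W), y, a_ridge)
    }
    a <- mh_head_solve(mh_phi(X, W), y, a_ridge)
    nl <- mh_loss(X, y, W, a)
    mu <- mu / mu_decay
  }
  st <- mh_descend(X, y, W, cfg, max_steps = 60L, a_ridge = a_ridge)
  list(W = st$W, a = st$a, loss = st$nl, converged = st$nl <= cfg$tol,
       stages = stage)
}

mh_state <- function(X, y, W, a_ridge) {
  H <- X %*% W / sqrt(ncol(X))
  M <- (H > 0) * 1
  Phi <- H * M
  a <- mh_head_solve(Phi, y, a_ridge)
  res <- y - drop(Phi %*% a) / sqrt(length(a))
  list(W = W, M = M, a = a, res = res, nl = sum(res^2) / sum(y^2))
}

# min-norm weight correction realizing `target` through the linearized
# (fixed-activation-mask) constraint: delta = A' (A A')^{-1} target
mh_correction <- function(X, st, target) {
  N0 <- ncol(X); n <- length(st$a)
  AAt <- (tcrossprod(X) / N0) * (st$M %*% (st$a^2 * t(st$M))) / n
  cvec <- jitter_solve(AAt, target, 1e-10)
  (crossprod(X, st$M * cvec) * rep(st$a, each = N0)) / sqrt(N0 * n)
}

# Gauss-Newton descent on the training residual with backtracking line
# search; monotone in the normalized loss.
mh_descend <- function(X, y, W, cfg, max_steps = 150L, a_ridge = 1e-10) {
  st <- mh_state(X, y, W, a_ridge)
  for (k in seq_len(max_steps)) {
    if (st$nl <= cfg$tol) break
    delta <- mh_correction(X, st, st$res)
    s <- 1
    repeat {
      cand <- mh_state(X, y, st$W + s * delta, a_ridge)
      if (cand$nl < st$nl || s < 1 / 64) break
      s <- s / 2
    }
    if (cand$nl >= st$nl) break   # no improving step at this mask
    st <- cand
  }
  st
}

# Constrained minimum-perturbation solver. Finds hidden weights W near
# `anchor` such that the ridge head on Phi(W) interpolates (X, y):
# repeatedly (i) solve the head exactly, (ii) linearize the residual
# constraint at the current ReLU activation mask, (iii) take the damped
# minimum-norm weight correction toward the anchor satisfying the
# linearized constraint. The fixed point is an interpolator with
# (locally) minimal ||W - anchor||_F^2 — the lambda -> infinity limit of
# the perturbation-penalized cost.
mh_min_perturb <- function(X, y, W_start, anchor, cfg, max_retract = 120L,
                           a_ridge = 1e-10) {
  N0 <- ncol(X)
  st <- mh_descend(X, y, W_start, cfg, max_steps = 150L, a_ridge = a_ridge)
  # feasible-direction retraction: move toward the anchor inside the
  # tangent space of the interpolation constraint, then re-polish
  if (st$nl <= cfg$tol) {
    step <- 0.2
    for (r in seq_len(max_retract)) {
      dw <- sum((st$W - anchor)^2)
      if (dw <= 1e-14) break
      E <- anchor - st$W
      Ae <- drop((((X %*% E) / sqrt(N0)) * st$M) %*% st$a) / sqrt(length(st$a))
      Etan <- E - mh_correction(X, st, Ae)
      cand <- mh_descend(X, y, st$W + step * Etan, cfg, max_steps = 8L,
                         a_ridge = a_ridge)
      if (cand$nl <= cfg$tol && sum((cand$W - anchor)^2) < dw) {
        improved <- (dw - sum((cand$W - anchor)^2)) / max(dw, 1e-300)
        st <- cand
        if (improved < 5e-3) break
      } else {
        step <- step / 2
        if (step < 1e-3) break
      }
    }
  }
  list(W = st$W, a = st$a, loss = st$nl, converged = st$nl <= cfg$tol)
}

#' Train the first task of a multihead network
#'
#' Initializes `W0 ~ N(0, sigma^2)` and minimizes the training MSE with a
#' weak pull toward the initialization (the first-task cost has no
#' perturbation penalty). When the head alone can interpolate (P <= N) the
#' hidden weights are left at `W0` exactly.
#'
#' @param task a [task_dataset()].
#' @param width hidden-layer width N.
#' @param cfg a [train_config()].
#' @return an object of class `multihead_net` with slots `W` (current
#'   hidden weights), `W0` (init), `W1` (post-task-1 snapshot), `heads`.
#' @export
train_task1 <- function(task, width, cfg = train_config()) {
  stopifnot(inherits(task, "task_dataset"))
  N0 <- ncol(task$X)
  W0 <- with_seed(cfg$seed,
                  matrix(stats::rnorm(N0 * width, sd = cfg$sigma), N0, width))
  a <- mh_head_solve(mh_phi(task$X, W0), task$Y, cfg$ridge * 1e-4)
  nl <- mh_loss(task$X, task$Y, W0, a)
  if (nl <= cfg$tol) {
    W <- W0; conv <- TRUE
  } else {
    fit <- mh_min_perturb(task$X, task$Y, W0, W0, cfg)
    W <- fit$W; a <- fit$a; nl <- fit$loss; conv <- fit$converged
  }
  if (!conv) {
    stop(sprintf("task-1 training did not reach tolerance (final normalized loss %.3g)", nl),
         call. = FALSE)
  }
  structure(list(W = W, W0 = W0, W1 = W, heads = list(a),
                 width = width, N0 = N0, cfg = cfg, stage = 1L),
            class = "multihead_net")
}

#' @export
print.multihead_net <- function(x, ...) {
  cat(sprintf("<multihead_net> N0=%d, N=%d, tasks learned=%d, ||W-W1||^2=%.3g\n",
              x$N0, x$width, x$stage, sum((x$W - x$W1)^2)))
  invisible(x)
}

#' Learn a second task with a fresh head and a perturbation penalty
#'
#' Adds head `a2` and re-optimizes the shared hidden weights under the
#' penalty `lambda ||W - W1||^2`, leaving `a1` untouched. With
#' `lambda = Inf` the head-only solution is used whenever it interpolates
#' (then `W` does not move at all); otherwise penalty continuation finds an
#' interpolator with minimal weight perturbation.
#'
#' @param net a `multihead_net` after [train_task1()].
#' @param task2 the second [task_dataset()].
#' @param cfg a [train_config()]; defaults to the net's.
#' @return the updated `multihead_net` (stage 2).
#' @export
continue_task2 <- function(net, task2, cfg = NULL) {
  stopifnot(inherits(net, "multihead_net"), net$stage == 1L)
  cfg <- cfg %||% net$cfg
  X <- task2$X; y <- task2$Y
  if (cfg$lambda > 0) {
    # with any weight-change penalty: if the head alone interpolates, the
    # hidden weights must not move at all (the FR solution, exact)
    a2 <- mh_head_solve(mh_phi(X, net$W1), y, cfg$ridge * 1e-4)
    if (mh_loss(X, y, net$W1, a2) <= cfg$tol) {
      net$W <- net$W1
      net$heads <- c(net$heads, list(a2))
      net$stage <- 2L
      return(net)
    }
  }
  fit <- mh_continue(X, y, net$W1, cfg)
  if (!fit$converged) {
    warning(sprintf("task-2 training stalled above tolerance (normalized loss %.3g)", fit$loss))
  }
  net$W <- fit$W
  net$heads <- c(net$heads, list(fit$a))
  net$stage <- 2L
  net$cfg <- cfg
  net
}

#' Solo-learning baseline for the second task
#'
#' Trains the second task alone from fresh initializations and returns the
#' seed-averaged raw normalized loss on a perturbed test set; this is the
#' normalizer of the anterograde-interference metric.
#'
#' @param task2 the task; `width` hidden width; `cfg` a [train_config()].
#' @param test2 perturbed test set (defaults to `eta = 0.1` perturbation).
#' @param n_seeds number of fresh initializations (>= 5 recommended).
#' @return list with `G20` (mean), `sd`, `per_seed`.
#' @export
baseline_task2 <- function(task2, width, cfg = train_config(), test2 = NULL,
                           n_seeds = 5L) {
  if (is.null(test2)) test2 <- perturbed_test(task2, 0.1, derive_seed(cfg$seed, "test2"))
  vals <- vapply(seq_len(n_seeds), function(k) {
    ck <- cfg; ck$seed <- derive_seed(cfg$seed, "baseline", k)
    solo <- train_task1(task2, width, ck)
    mh_loss(test2$X, test2$Y, solo$W, solo$heads[[1]])
  }, numeric(1))
  list(G20 = mean(vals), sd = stats::sd(vals), per_seed = vals)
}

#' Retrograde and anterograde metrics after two tasks
#'
#' `F21`: normalized training loss of head 1 on task 1 under the final
#' hidden weights (forgetting). `G21`: head-1 loss on a perturbed task-1
#' test set. `G22`: head-2 loss on a perturbed task-2 test set, normalized
#' by the solo-learning baseline `G20`. Also reports `||a2||^2 / N` and
#' `||W2 - W1||^2`.
#'
#' @param net a stage-2 `multihead_net`.
#' @param task1,task2 the training tasks.
#' @param test1,test2 perturbed test sets (default `eta = 0.1`).
#' @param G20 solo baseline (a number or the list from [baseline_task2()]);
#'   `NULL` skips the normalized test metrics (only `F21`, `a2_norm`,
#'   `dW_norm` are then reported).
#' @return an object of class `multihead_metrics`.
#' @export
multihead_metrics <- function(net, task1, task2, test1 = NULL, test2 = NULL,
                              G20 = NULL) {
  stopifnot(inherits(net, "multihead_net"), net$stage == 2L)
  F21 <- mh_loss(task1$X, task1$Y, net$W, net$heads[[1]])
  a2 <- net$heads[[2]]
  out <- list(F21 = F21,
              a2_norm = sum(a2^2) / net$width,
              dW_norm = sum((net$W - net$W1)^2))
  if (!is.null(G20)) {
    g20 <- if (is.list(G20)) G20$G20 else G20
    assert_that(g20 > 0, "G20 must be > 0")
    if (is.null(test1)) test1 <- perturbed_test(task1, 0.1, derive_seed(net$cfg$seed, "test1"))
    if (is.null(test2)) test2 <- perturbed_test(task2, 0.1, derive_seed(net$cfg$seed, "test2"))
    out$G21 <- mh_loss(test1$X, test1$Y, net$W, net$heads[[1]])
    out$G22 <- mh_loss(test2$X, test2$Y, net$W, net$heads[[2]]) / g20
    out$G20 <- g20
  }
  structure(out, class = "multihead_metrics")
}

#' @export
print.multihead_metrics <- function(x, ...) {
  cat(sprintf("<multihead_metrics> F21=%.3g  a2_norm=%.3g  dW_norm=%.3g",
              x$F21, x$a2_norm, x$dW_norm))
  if (!is.null(x$G21)) cat(sprintf("  G21=%.3g  G22=%.3g", x$G21, x$G22))
  cat("\n")
  invisible(x)
}

#' Critical load from the similarity score
#'
#' `alpha_c = gamma_sim^{-2}` for positive similarity; for
#' `gamma_sim <= 0` the generalization regime never appears and
#' `alpha_c = Inf`.
#'
#' @param gsim similarity score in `[-1, 1]` (a number or a `sim_op`).
#' @return the critical load.
#' @export
critical_load <- function(gsim) {
  g <- if (inherits(gsim, "sim_op")) gsim$gamma_sim else as.numeric(gsim)
  assert_that(g >= -1 - 1e-6 && g <= 1 + 1e-6, "gamma_sim out of [-1, 1]")
  if (g <= 0) Inf else 1 / g^2
}

#' Classify the continual-learning regime at a given load
#'
#' Fixed representations (FR) for `alpha < 1`; overfitting (OF) for
#' `1 < alpha < alpha_c`; generalization (G) for `alpha > alpha_c`.
#'
#' @param alpha load `P / N` (> 0).
#' @param gsim similarity score.
#' @return an object of class `phase_diagnosis` with `regime`, `alpha_c`,
#'   and an `on_boundary` flag for loads within 1e-9 of a boundary.
#' @export
classify_regime <- function(alpha, gsim) {
  assert_that(alpha > 0, "alpha must be > 0")
  g <- if (inherits(gsim, "sim_op")) gsim$gamma_sim else as.numeric(gsim)
  ac <- critical_load(g)
  on_b <- abs(alpha - 1) <= 1e-9 || (is.finite(ac) && abs(alpha - ac) <= 1e-9)
  regime <- if (alpha < 1) "FR" else if (alpha < ac) "OF" else "G"
  structure(list(alpha = alpha, gamma_sim = g, alpha_c = ac,
                 regime = regime, on_boundary = on_b),
            class = "phase_diagnosis")
}

#' @export
print.phase_diagnosis <- function(x, ...) {
  cat(sprintf("<phase_diagnosis> alpha=%.3g, gamma_sim=%.3g, alpha_c=%.3g -> %s%s\n",
              x$alpha, x$gamma_sim, x$alpha_c, x$regime,
              if (x$on_boundary) " (on boundary)" else ""))
  invisible(x)
}

#' Empirical critical load from a forgetting-vs-load scan
#'
#' The transition out of the zero-forgetting regimes is located as the
#' smallest load at which seed-averaged `F21` exceeds `threshold`, linearly
#' interpolated between the bracketing grid points.
#'
#' @param alphas sorted load grid (>= 5 points spanning alpha > 1).
#' @param F21_values seed-averaged forgetting at each load.
#' @param threshold crossing threshold on `F21`.
#' @return the estimated `alpha_c` (`Inf` with a warning if no crossing).
#' @export
empirical_alpha_c <- function(alphas, F21_values, threshold = 0.01) {
  assert_that(length(alphas) == length(F21_values), "grid and values differ in length")
  assert_that(length(alphas) >= 5, "need at least 5 grid points")
  assert_that(!is.unsorted(alphas), "alpha grid must be sorted")
  above <- which(F21_values > threshold)
  if (length(above) == 0) {
    warning("F21 never exceeds the threshold; returning Inf")
    return(Inf)
  }
  i <- above[1]
  if (i == 1) return(alphas[1])
  f0 <- F21_values[i - 1]; f1 <- F21_values[i]
  alphas[i - 1] + (threshold - f0) / (f1 - f0) * (alphas[i] - alphas[i - 1])
}

#' Two-task run and metrics at one load
#'
#' Convenience driver: trains task 1, continues with task 2, and computes
#' metrics; used by the load scans and the penalty sweep.
#'
#' @param task1,task2 training tasks; `width` hidden width; `cfg` a
#'   [train_config()].
#' @param G20 optional solo baseline for normalized test metrics.
#' @param test1,test2 optional perturbed test sets.
#' @return a `multihead_metrics` object.
#' @export
multihead_run <- function(task1, task2, width, cfg = train_config(),
                          G20 = NULL, test1 = NULL, test2 = NULL) {
  net <- train_task1(task1, width, cfg)
  net <- continue_task2(net, task2, cfg)
  multihead_metrics(net, task1, task2, test1, test2, G20)
}

#' Sweep the perturbation-penalty scale
#'
#' Runs the two-task trainer over a log-spaced grid of `lambda`, computing
#' seed-averaged forgetting (`F21`) and the normalized test losses on both
#' tasks, and returns the grid value minimizing `max(G21, G22)` — the
#' memorization/new-learning trade-off.
#'
#' @param task1,task2 training tasks; `width` hidden width.
#' @param lambdas penalty grid (>= 8 log-spaced values recommended).
#' @param cfg a [train_config()] (its `lambda` field is overridden).
#' @param n_seeds seeds per grid point.
#' @param eta test-set perturbation scale.
#' @return list with `table` (data.frame of per-lambda means) and
#'   `optimal_lambda`.
#' @export
lambda_sweep <- function(task1, task2, width, lambdas, cfg = train_config(),
                         n_seeds = 3L, eta = 0.1) {
  assert_that(length(lambdas) >= 2, "need a lambda grid")
  test1 <- perturbed_test(task1, eta, derive_seed(cfg$seed, "sweep_t1"))
  test2 <- perturbed_test(task2, eta, derive_seed(cfg$seed, "sweep_t2"))
  g20 <- baseline_task2(task2, width, cfg, test2, n_seeds = max(n_seeds, 3L))
  rows <- lapply(lambdas, function(lam) {
    per <- vapply(seq_len(n_seeds), function(k) {
      ck <- cfg; ck$lambda <- lam; ck$seed <- derive_seed(cfg$seed, "sweep", k)
      m <- multihead_run(task1, task2, width, ck, G20 = g20,
                         test1 = test1, test2 = test2)
      c(m$F21, m$G21, m$G22, m$a2_norm, m$dW_norm)
    }, numeric(5))
    mm <- rowMeans(per)
    data.frame(lambda = lam, F21 = mm[1], G21 = mm[2], G22 = mm[3],
               a2_norm = mm[4], dW_norm = mm[5], max_G = max(mm[2], mm[3]))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, optimal_lambda = tab$lambda[which.min(tab$max_G)], G20 = g20$G20)
}

#' Locate the head-only interpolation threshold
#'
#' With hidden weights frozen at a random draw, a new head can drive the
#' training residual to zero exactly when the number of examples does not
#' exceed the width; this scans a load grid for the feasibility boundary
#' and refines it by bisection. The boundary is the FR/OF phase boundary,
#' which is task-independent and sits at load 1.
#'
#' @param width hidden width N; `input_dim` input dimension.
#' @param alphas initial load grid (sorted, spanning the boundary).
#' @param resid_tol residual threshold defining feasibility (normalized
#'   training loss).
#' @param refine_to bisection stops when the bracket is this wide.
#' @param seed integer seed for the weights and the Gaussian task.
#' @return list with `boundary` (bracket midpoint), `bracket`, and the
#'   per-grid-point feasibility table.
#' @export
head_interpolation_boundary <- function(width, input_dim,
                                        alphas = c(0.6, 0.8, 0.95, 1.05, 1.2, 1.5),
                                        resid_tol = 1e-6, refine_to = 0.1,
                                        seed = 1L) {
  assert_that(!is.unsorted(alphas), "alpha grid must be sorted")
  W0 <- with_seed(derive_seed(seed, "boundaryW"),
                  matrix(stats::rnorm(input_dim * width), input_dim, width))
  feasible_at <- function(alpha, k = 0L) {
    P <- max(round_half_up(alpha * width), 1)
    pool <- make_gaussian_pool(P, input_dim, derive_seed(seed, "boundaryX", k + P))
    y <- with_seed(derive_seed(seed, "boundaryY", k + P),
                   sample(c(-1, 1), P, replace = TRUE))
    Phi <- mh_phi(pool$X, W0)
    a <- mh_head_solve(Phi, y, 1e-12)
    mh_loss(pool$X, y, W0, a) <= resid_tol
  }
  feas <- vapply(alphas, feasible_at, logical(1))
  if (all(feas) || !any(feas)) {
    stop("alpha grid does not bracket the feasibility boundary", call. = FALSE)
  }
  lo <- max(alphas[feas])
  hi <- min(alphas[!feas])
  k <- 0L
  while (hi - lo > refine_to) {
    mid <- (lo + hi) / 2
    k <- k + 1L
    if (feasible_at(mid, k)) lo <- mid else hi <- mid
  }
  list(boundary = (lo + hi) / 2, bracket = c(lo, hi),
       grid = data.frame(alpha = alphas, feasible = feas))
}

#' Representation-similarity analysis of the hidden layer
#'
#' `K(X) = Phi(W, X) Phi(W, X)' / N` under the network's current weights;
#' the learned component subtracts the same kernel under a reference weight
#' matrix (default: the random initialization). The block score is the mean
#' learned similarity within label classes minus the mean across classes —
#' positive when the representation clusters by task label (the 2x2 block
#' structure associated with good generalization).
#'
#' @param net a `multihead_net`.
#' @param X inputs to evaluate; `y` optional +-1 labels for the block score.
#' @param reference_W reference weights (default `net$W0`).
#' @return an object of class `rep_similarity` with `K`, `K_ref`,
#'   `learned`, `block_score`.
#' @export
representation_similarity <- function(net, X, y = NULL, reference_W = NULL) {
  stopifnot(inherits(net, "multihead_net"))
  assert_that(nrow(as.matrix(X)) > 0, "X is empty")
  refW <- reference_W %||% net$W0
  K <- tcrossprod(mh_phi(X, net$W)) / net$width
  Kref <- tcrossprod(mh_phi(X, refW)) / net$width
  learned <- K - Kref
  score <- NA_real_
  if (!is.null(y)) {
    y <- sign(as.numeric(y))
    same <- outer(y, y) > 0
    diag(same) <- NA
    off <- row(learned) != col(learned)
    score <- mean(learned[off & !is.na(same) & same]) -
      mean(learned[off & !is.na(same) & !same])
  }
  structure(list(K = K, K_ref = Kref, learned = learned, block_score = score),
            class = "rep_similarity")
}

#' @export
print.rep_similarity <- function(x, ...) {
  cat(sprintf("<rep_similarity> P=%d, block score=%s\n", nrow(x$K),
              if (is.na(x$block_score)) "NA" else sprintf("%.4g", x$block_score)))
  invisible(x)
}
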