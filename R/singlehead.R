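# Single-head continual learning in the fixed-feature regime: the readout
# interpolates each task in turn with the minimum change to its weights
# (the strong-penalty, zero-temperature limit), and forgetting of task 1 is
# tracked as a normalized MSE. Also: the conflict-based predictor of
# two-task forgetting and the exponential-relaxation description of
# long-term forgetting.

#' Minimum-norm interpolating readout for one task
#'
#' `a = sqrt(N) Phi' (Phi Phi')^{-1} Y`: the smallest readout (in L2) whose
#' predictions `Phi a / sqrt(N)` reproduce `Y` exactly. Up to the `1/||Y||`
#' normalization this is the task's rule vector.
#'
#' @param Phi feature matrix `[P x N]` (or a `feature_ensemble`).
#' @param Y label vector.
#' @param jitter relative diagonal jitter for the Gram inversion.
#' @return an object of class `readout_state`: list with `a`, `t = 1`.
#' @export
min_norm_readout <- function(Phi, Y, jitter = 1e-13) {
  if (inherits(Phi, "feature_ensemble")) Phi <- Phi$Phi
  n <- ncol(Phi)
  G <- tcrossprod(Phi)
  a <- sqrt(n) * crossprod(Phi, jitter_solve(G, as.numeric(Y), jitter))
  structure(list(a = drop(a), t = 1L, width = n), class = "readout_state")
}

#' Minimum-change update of the readout for a new task
#'
#' `a_t = a_prev + Phi' (Phi Phi')^{-1} (sqrt(N) Y - Phi a_prev)`: among all
#' readouts interpolating the new task, the one closest to `a_prev`. If
#' `a_prev` already interpolates, the readout is returned unchanged.
#'
#' @param state a `readout_state`.
#' @param Phi feature matrix of the new task; `Y` its labels.
#' @param jitter relative diagonal jitter.
#' @return the updated `readout_state`.
#' @export
sequential_min_change <- function(state, Phi, Y, jitter = 1e-13) {
  stopifnot(inherits(state, "readout_state"))
  if (inherits(Phi, "feature_ensemble")) Phi <- Phi$Phi
  n <- ncol(Phi)
  assert_that(n == state$width, "feature width changed between tasks")
  resid <- sqrt(n) * as.numeric(Y) - drop(Phi %*% state$a)
  delta <- crossprod(Phi, jitter_solve(tcrossprod(Phi), resid, jitter))
  structure(list(a = state$a + drop(delta), t = state$t + 1L, width = n),
            class = "readout_state")
}

#' Normalized mean-squared-error loss of a readout on a dataset
#'
#' `sum_mu (Phi_mu . a / sqrt(N) - y_mu)^2 / ||Y||^2`; equals 0 for an
#' interpolator, 1 for the zero readout, and 4 when predictions are exactly
#' `-Y`.
#'
#' @param state a `readout_state` (or a plain numeric readout vector).
#' @param Phi feature matrix; `Y` labels.
#' @return a nonnegative scalar.
#' @export
normalized_loss <- function(state, Phi, Y) {
  a <- if (inherits(state, "readout_state")) state$a else as.numeric(state)
  if (inherits(Phi, "feature_ensemble")) Phi <- Phi$Phi
  Y <- as.numeric(Y)
  assert_that(sum(Y^2) > 0, "zero-norm label vector")
  pred <- drop(Phi %*% a) / sqrt(ncol(Phi))
  sum((pred - Y)^2) / sum(Y^2)
}

# Featurize all tasks of a sequence with one shared feature map.
# path "finite": one weight draw applied to the stacked inputs.
# path "kernel": surrogate features realizing the joint depth-L kernel Gram
# exactly, so downstream Gram-determined computations are the exact
# infinite-width limit.
featurize_sequence <- function(seq, spec, path = c("finite", "kernel")) {
  path <- match.arg(path)
  Xall <- do.call(rbind, lapply(seq$tasks, function(tk) tk$X))
  Phi_all <- if (path == "finite") {
    sample_features(spec, Xall)$Phi
  } else {
    gram_features(nngp_gram(spec$depth, spec$sigma, Xall))
  }
  P <- seq$P
  lapply(seq_along(seq$tasks), function(t) {
    Phi_all[(t - 1) * P + seq_len(P), , drop = FALSE]
  })
}

#' Forgetting curve of the first task along a sequence
#'
#' Featurizes every task with the same fixed feature map, learns task 1 by
#' minimum-norm interpolation, then each later task by minimum-change
#' interpolation, and records `F_{t,1}`, the normalized training loss on
#' task 1 after step t (`F_{1,1} = 0` by construction).
#'
#' @param seq a [task_sequence()].
#' @param spec a [feature_map_spec()]; its depth and sigma also parameterize
#'   the kernel path.
#' @param path `"kernel"` (deterministic infinite-width limit, default) or
#'   `"finite"` (one random feature draw at the spec's width and seed).
#' @param jitter relative diagonal jitter.
#' @return an object of class `forgetting_curve`: list with `F` (length-T
#'   vector), `path`, `spec`.
#' @export
forgetting_curve <- function(seq, spec, path = c("kernel", "finite"), jitter = 1e-13) {
  path <- match.arg(path)
  stopifnot(inherits(seq, "task_sequence"))
  Phis <- featurize_sequence(seq, spec, path)
  Y1 <- seq$tasks[[1]]$Y
  st <- min_norm_readout(Phis[[1]], Y1, jitter)
  Fv <- numeric(length(seq$tasks))
  Fv[1] <- normalized_loss(st, Phis[[1]], Y1)
  for (t in seq.int(2L, length.out = length(seq$tasks) - 1L)) {
    st <- sequential_min_change(st, Phis[[t]], seq$tasks[[t]]$Y, jitter)
    Fv[t] <- normalized_loss(st, Phis[[1]], Y1)
  }
  structure(list(F = Fv, path = path, spec = spec, protocol = seq$protocol),
            class = "forgetting_curve")
}

#' @export
print.forgetting_curve <- function(x, ...) {
  cat(sprintf("<forgetting_curve> T=%d, path=%s, F2,1=%.4g, F_T,1=%.4g\n",
              length(x$F), x$path, if (length(x$F) >= 2) x$F[2] else NA, x$F[length(x$F)]))
  invisible(x)
}

#' Conflict-based prediction of two-task forgetting
#'
#' In the fixed-feature single-head model with symmetric task relations,
#' short-term forgetting is `F_{2,1} = 2 (gamma_RF - gamma_rule)`.
#'
#' @param op an [order_params()] object.
#' @return the predicted `F_{2,1}`.
#' @export
predict_f21 <- function(op) {
  2 * conflict(op)
}

#' Effect of the perturbation penalty on two-task forgetting
#'
#' `Delta F_{2,1} = F_{2,1} - F_{2,1}(lambda = 0)`, where the reference
#' learns task 2 alone (no memory of task 1) and is evaluated on task 1's
#' training data. On the kernel path the reference is deterministic; on the
#' finite path it is averaged over `n_ref_seeds` fresh feature draws.
#'
#' @param seq a T >= 2 [task_sequence()].
#' @param spec a [feature_map_spec()].
#' @param path `"kernel"` or `"finite"`.
#' @param n_ref_seeds fresh draws for the finite-path reference (>= 10).
#' @param jitter relative diagonal jitter.
#' @return list with `delta_F21`, `F21`, `F21_lambda0`.
#' @export
delta_f21 <- function(seq, spec, path = c("kernel", "finite"),
                      n_ref_seeds = 10L, jitter = 1e-13) {
  path <- match.arg(path)
  pair <- task_sequence(seq$tasks[1:2], protocol = seq$protocol,
                        params = seq$params, seed = seq$seed)
  F21 <- forgetting_curve(pair, spec, path, jitter)$F[2]
  ref_once <- function(sp) {
    Phis <- featurize_sequence(pair, sp, path)
    st <- min_norm_readout(Phis[[2]], pair$tasks[[2]]$Y, jitter)
    normalized_loss(st, Phis[[1]], pair$tasks[[1]]$Y)
  }
  F21_0 <- if (path == "kernel") {
    ref_once(spec)
  } else {
    mean(vapply(seq_len(max(n_ref_seeds, 10L)), function(k) {
      sp <- spec; sp$seed <- derive_seed(spec$seed, "lambda0", k)
      ref_once(sp)
    }, numeric(1)))
  }
  list(delta_F21 = F21 - F21_0, F21 = F21, F21_lambda0 = F21_0)
}

#' Exponential-relaxation fit of a forgetting curve
#'
#' Fits `F_{t,1} ~= Fmax (1 - exp(-(t-1)/tau))` over t = 2..T by least
#' squares: for each candidate `tau` on a log grid in `[0.1, 10 T]` the
#' optimal `Fmax` is closed-form, and the best grid point is refined by
#' one-dimensional optimization of `log(tau)`.
#'
#' @param curve a [forgetting_curve()] or a plain numeric vector of
#'   `F_{t,1}` values starting at t = 1.
#' @param grid_points log-grid resolution for the initialization.
#' @return an object of class `exp_fit`: list with `Fmax`, `tau`, `rms`
#'   (residual root-mean-square) and `degenerate`/`pinned` flags.
#' @export
fit_exponential <- function(curve, grid_points = 200L) {
  Fv <- if (inherits(curve, "forgetting_curve")) curve$F else as.numeric(curve)
  T_tasks <- length(Fv)
  assert_that(T_tasks >= 4, "need T >= 4 points to fit the relaxation form")
  tt <- 2:T_tasks
  y <- Fv[tt]
  if (all(abs(y) <= 1e-14)) {
    return(structure(list(Fmax = 0, tau = NA_real_, rms = 0, degenerate = TRUE,
                          pinned = FALSE), class = "exp_fit"))
  }
  assert_that(sum(y != 0) >= 3, "need at least 3 nonzero values to fit")
  g_of <- function(tau) 1 - exp(-(tt - 1) / tau)
  sse <- function(log_tau) {
    g <- g_of(exp(log_tau))
    fmax <- sum(y * g) / sum(g^2)
    sum((y - fmax * g)^2)
  }
  lo <- log(0.1); hi <- log(10 * T_tasks)
  grid <- seq(lo, hi, length.out = grid_points)
  vals <- vapply(grid, sse, numeric(1))
  best <- grid[which.min(vals)]
  opt <- stats::optimize(sse, lower = max(lo, best - 0.5), upper = min(hi, best + 0.5))
  tau <- exp(opt$minimum)
  # flat objectives near the lower bound mean the curve carries no time
  # constant (e.g. an immediate plateau): pin tau and warn
  pinned <- sse(lo) <= opt$objective + 1e-12 * max(opt$objective, 1)
  if (pinned) tau <- exp(lo)
  g <- g_of(tau)
  fmax <- sum(y * g) / sum(g^2)
  if (pinned) {
    warning("tau pinned at the lower bound (curve is consistent with an immediate plateau)")
  }
  structure(list(Fmax = fmax, tau = tau,
                 rms = sqrt(mean((y - fmax * g)^2)),
                 degenerate = FALSE, pinned = pinned),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<exp_fit> degenerate (all-zero curve): Fmax=0, tau undefined\n")
  } else {
    cat(sprintf("<exp_fit> Fmax=%.4g, tau=%.4g, residual RMS=%.3g%s\n",
                x$Fmax, x$tau, x$rms, if (isTRUE(x$pinned)) " (tau pinned)" else ""))
  }
  invisible(x)
}

#' Predict the forgetting asymptote from F2,1 and the time constant
#'
#' Inverts the relaxation form at t = 2: `Fmax = F_{2,1} / (1 - exp(-1/tau))`.
#'
#' @param F21 two-task forgetting (>= 0).
#' @param tau relaxation time constant (> 0).
#' @return the implied asymptote `Fmax`.
#' @export
predict_fmax <- function(F21, tau) {
  assert_that(F21 >= 0, "F21 must be >= 0")
  assert_that(tau > 0, "tau must be > 0")
  F21 / (1 - exp(-1 / tau))
}
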