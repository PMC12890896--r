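#' clforget: order parameters and phase transitions of continual learning
#'
#' Simulators and diagnostics for catastrophic forgetting in deep, wide
#' networks: task-relation order parameters from random ReLU features or
#' their infinite-width kernel limit, parametric task-sequence generators,
#' single-head minimum-change interpolation, and a multihead trainer with
#' phase classification against the critical load predicted by the task
#' similarity score.
#'
#' @keywords internal
"_PACKAGE"

# Internal numerical helpers shared across modules.

#' Solve a symmetric PSD system with relative diagonal jitter
#'
#' Gram matrices at or near the interpolation threshold are badly
#' conditioned; all P x P inversions in the package go through this helper,
#' which adds `eps * tr(G)/P` to the diagonal before a Cholesky solve and
#' falls back to an eigenvalue-thresholded pseudo-inverse solve when the
#' Cholesky fails even after jitter.
#'
#' @param G symmetric positive semidefinite matrix.
#' @param B right-hand side (vector or matrix).
#' @param eps relative jitter; the absolute jitter is `eps * mean(diag(G))`.
#' @return the solution of `(G + jitter I) x = B`.
#' @keywords internal
jitter_solve <- function(G, B, eps = 1e-10) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  p <- nrow(G)
  jit <- eps * mean(diag(G))
  if (!is.finite(jit) || jit <= 0) jit <- eps
  Gj <- G + diag(jit, p)
  ch <- tryCatch(chol(Gj), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, forwardsolve(t(ch), B)))
  }
  # fall back: eigenvalue-thresholded solve, with a condition diagnostic
  ee <- eigen(Gj, symmetric = TRUE)
  tol <- max(ee$values) * 1e-12
  keep <- ee$values > tol
  if (!any(keep)) {
    stop(sprintf(
      "Gram matrix is numerically singular beyond jitter tolerance (condition number ~ %.3g)",
      max(ee$values) / max(min(ee$values), .Machine$double.xmin)
    ))
  }
  V <- ee$vectors[, keep, drop = FALSE]
  V %*% ((crossprod(V, B)) / ee$values[keep])
}

# Evaluate an expression under a local, restored RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation; keeps results < 2^31 and reproducible
# across platforms. `tag` separates independent random streams.
derive_seed <- function(seed, tag, k = 0L) {
  h <- sum(utf8ToInt(as.character(tag))) %% 100003
  s <- abs(as.numeric(seed)) %% 1e6   # keep products exactly representable
  as.integer((s * 2654435 + h * 97 + as.numeric(k)) %% 2147483647)
}

# Round half away from zero (fractional counts in the task generators;
# base round() rounds half to even, which would make counts seed-dependent
# in spirit if parameters land on .5).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
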