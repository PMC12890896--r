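# Random ReLU feature maps and their infinite-width (arc-cosine / NNGP)
# kernel limit. Finite-width features are the stochastic path; the kernel
# is the deterministic path used by default everywhere downstream.

#' Specification of a random ReLU feature map
#'
#' Describes a depth-`L` fully connected ReLU network with `N` units per
#' hidden layer, input dimension `N0`, i.i.d. Gaussian weights with standard
#' deviation `sigma`, and a seed making the draw reproducible. Pre-activations
#' are scaled by `1/sqrt(fan-in)` so that activations stay O(1) as width
#' grows and the finite-width Gram converges to the kernel limit.
#'
#' @param depth number of hidden layers (L >= 1).
#' @param width units per hidden layer (N >= 1).
#' @param input_dim input dimensionality N0.
#' @param sigma weight scale (sd of the Gaussian weights), > 0.
#' @param activation only `"relu"` is supported.
#' @param seed integer seed for the weight draw.
#' @return an object of class `feature_map_spec`.
#' @export
#' @examples
#' spec <- feature_map_spec(depth = 1, width = 200, input_dim = 10, seed = 1)
feature_map_spec <- function(depth = 1L, width = 1000L, input_dim,
                             sigma = 1.0, activation = "relu", seed = 1L) {
  assert_that(length(depth) == 1 && depth >= 1, "depth must be a positive integer")
  assert_that(length(width) == 1 && width >= 1, "width must be a positive integer")
  assert_that(length(input_dim) == 1 && input_dim >= 1, "input_dim must be a positive integer")
  assert_that(is.numeric(sigma) && sigma > 0, "sigma must be > 0")
  activation <- match.arg(activation, "relu")
  structure(
    list(depth = as.integer(depth), width = as.integer(width),
         input_dim = as.integer(input_dim), sigma = as.numeric(sigma),
         activation = activation, seed = as.integer(seed)),
    class = "feature_map_spec"
  )
}

#' @export
print.feature_map_spec <- function(x, ...) {
  cat(sprintf("<feature_map_spec> depth L=%d, width N=%d, N0=%d, sigma=%g, %s, seed=%d\n",
              x$depth, x$width, x$input_dim, x$sigma, x$activation, x$seed))
  invisible(x)
}

#' Rescale every input row to Euclidean norm sqrt(N0)
#'
#' Fixes the input scale so that kernels are comparable across datasets and
#' the arc-cosine angle is well defined. Idempotent; preserves row order.
#'
#' @param X numeric matrix, one example per row.
#' @return matrix of the same shape with each row of norm `sqrt(ncol(X))`.
#' @export
normalize_inputs <- function(X) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "inputs contain non-finite values")
  nrms <- sqrt(rowSums(X^2))
  bad <- which(nrms == 0)
  if (length(bad) > 0) {
    stop(sprintf("degenerate input: all-zero row(s) at index %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  X * (sqrt(ncol(X)) / nrms)
}

#' Sample finite-width random ReLU features
#'
#' Applies the layerwise map `h^0 = x`, `h^l = relu(W^l h^{l-1} / sqrt(fan-in))`
#' with i.i.d. `N(0, sigma^2)` weights, and returns the last-hidden-layer
#' activations for every row of `X`. Deterministic given the spec's seed.
#'
#' @param spec a [feature_map_spec()].
#' @param X numeric matrix `[P x N0]`.
#' @return a `feature_ensemble`: list with `Phi` (`P x N` activation matrix,
#'   all entries >= 0 for ReLU) and the originating `spec`.
#' @export
sample_features <- function(spec, X) {
  stopifnot(inherits(spec, "feature_map_spec"))
  X <- as.matrix(X)
  assert_that(ncol(X) == spec$input_dim,
              sprintf("X has %d columns but spec$input_dim is %d", ncol(X), spec$input_dim))
  assert_that(all(is.finite(X)), "inputs contain non-finite values")
  H <- X
  with_seed(spec$seed, {
    for (l in seq_len(spec$depth)) {
      fan_in <- ncol(H)
      W <- matrix(stats::rnorm(fan_in * spec$width, sd = spec$sigma),
                  nrow = fan_in, ncol = spec$width)
      H <- pmax(H %*% W / sqrt(fan_in), 0)
    }
  })
  structure(list(Phi = H, spec = spec), class = "feature_ensemble")
}

#' Depth-composed arc-cosine (NNGP) ReLU kernel
#'
#' Exact infinite-width limit of the random-feature Gram matrix
#' `Phi(X) Phi(X')^T / N`. Layer 0 is the linear kernel `x . x' / N0`; each
#' ReLU layer applies the arc-cosine update
#' `K^l = sigma^2 * sqrt(q q') / (2 pi) * (sin t + (pi - t) cos t)` with
#' `cos t` the correlation under `K^{l-1}` and `q, q'` the self-kernels.
#'
#' @param depth number of ReLU layers (L >= 1).
#' @param sigma weight scale.
#' @param X,Xp input matrices with the same number of columns; `Xp` defaults
#'   to `X`.
#' @return the kernel matrix `K^L(X, Xp)`.
#' @export
#' @examples
#' X <- normalize_inputs(matrix(rnorm(20), 4, 5))
#' K <- nngp_gram(1, 1, X) # diagonal is 1/2 for unit-normalized inputs
nngp_gram <- function(depth, sigma, X, Xp = X) {
  X <- as.matrix(X); Xp <- as.matrix(Xp)
  assert_that(ncol(X) == ncol(Xp), "input dimension mismatch between X and Xp")
  assert_that(depth >= 1, "depth must be >= 1")
  n0 <- ncol(X)
  K <- tcrossprod(X, Xp) / n0      # cross kernel
  qx <- rowSums(X^2) / n0          # self kernels
  qy <- rowSums(Xp^2) / n0
  for (l in seq_len(depth)) {
    if (any(qx < -1e-12) || any(qy < -1e-12)) {
      stop("numerically negative self-kernel; input normalization is broken", call. = FALSE)
    }
    qx <- pmax(qx, 0); qy <- pmax(qy, 0)
    denom <- sqrt(outer(qx, qy))
    ct <- K / pmax(denom, .Machine$double.xmin)
    ct <- pmin(pmax(ct, -1), 1)    # clip rounding overshoot, never raise
    theta <- acos(ct)
    K <- sigma^2 * denom / (2 * pi) * (sin(theta) + (pi - theta) * cos(theta))
    qx <- sigma^2 * qx / 2         # theta = 0 on the diagonal
    qy <- sigma^2 * qy / 2
  }
  K
}

#' Gram blocks for a pair of tasks
#'
#' Builds the `G11`, `G22`, `G12` blocks used by all order-parameter and
#' simulator code, either from explicit finite-width features
#' (`Gij = Phi_i Phi_j^T / N`) or from the infinite-width kernel.
#'
#' @param x1,x2 for `path = "finite"`: `feature_ensemble` objects (or plain
#'   activation matrices sharing a width); for `path = "kernel"`: input
#'   matrices `[P x N0]`.
#' @param path `"finite"` or `"kernel"`.
#' @param depth,sigma kernel parameters (kernel path only).
#' @param jitter relative diagonal jitter used for inversions downstream.
#' @return an object of class `gram_set` with elements `G11`, `G22`, `G12`,
#'   `jitter`.
#' @export
gram_set <- function(x1, x2, path = c("finite", "kernel"),
                     depth = 1L, sigma = 1.0, jitter = 1e-10) {
  path <- match.arg(path)
  if (path == "finite") {
    P1 <- if (inherits(x1, "feature_ensemble")) x1$Phi else as.matrix(x1)
    P2 <- if (inherits(x2, "feature_ensemble")) x2$Phi else as.matrix(x2)
    assert_that(ncol(P1) == ncol(P2), "feature widths differ between tasks")
    n <- ncol(P1)
    g <- list(G11 = tcrossprod(P1) / n,
              G22 = tcrossprod(P2) / n,
              G12 = tcrossprod(P1, P2) / n,
              width = n)
  } else {
    X1 <- as.matrix(x1); X2 <- as.matrix(x2)
    g <- list(G11 = nngp_gram(depth, sigma, X1),
              G22 = nngp_gram(depth, sigma, X2),
              G12 = nngp_gram(depth, sigma, X1, X2))
  }
  g$G11 <- (g$G11 + t(g$G11)) / 2
  g$G22 <- (g$G22 + t(g$G22)) / 2
  g$jitter <- jitter
  g$path <- path
  structure(g, class = "gram_set")
}

#' @export
print.gram_set <- function(x, ...) {
  cat(sprintf("<gram_set> P1=%d, P2=%d, path=%s, jitter=%g\n",
              nrow(x$G11), nrow(x$G22), x$path, x$jitter))
  invisible(x)
}

# Surrogate features realizing a given joint Gram matrix exactly.
# Any Gram-determined computation (min-norm interpolation, order parameters)
# run on these features reproduces the infinite-width kernel answer, because
# Phi Phi^T / ncol(Phi) == K by construction.
gram_features <- function(K) {
  K <- (K + t(K)) / 2
  ee <- eigen(K, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  F <- ee$vectors %*% diag(sqrt(ev), length(ev))
  sqrt(ncol(F)) * F
}
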