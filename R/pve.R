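# Variance decomposition of a forgetting statistic over the three
# single-head order parameters.

#' Proportion of variance explained by each order parameter
#'
#' Decomposes the variance of a response (e.g. `F_{2,1}` or the fitted time
#' constant across a task-relation grid) over the three predictors
#' `gamma_feature`, `gamma_RF`, `gamma_rule` by LMG relative importance:
#' the incremental R^2 of each predictor is averaged over all 3! orders of
#' entry into a linear model, then the three shares are normalized to sum
#' to one. LMG is order-invariant, which matters here because the
#' predictors are strongly correlated across task-relation grids.
#'
#' @param op_table data frame (or matrix) with columns `gamma_feature`,
#'   `gamma_RF`, `gamma_rule`; predictors are standardized internally.
#' @param response numeric vector, one value per row (>= 10 rows).
#' @return named numeric vector of three nonnegative shares summing to 1.
#' @export
pve_decomposition <- function(op_table, response) {
  op_table <- as.data.frame(op_table)
  nm <- c("gamma_feature", "gamma_RF", "gamma_rule")
  assert_that(all(nm %in% names(op_table)),
              "op_table needs columns gamma_feature, gamma_RF, gamma_rule")
  assert_that(nrow(op_table) >= 10, "need at least 10 rows")
  y <- as.numeric(response)
  assert_that(length(y) == nrow(op_table), "response length mismatch")
  if (stats::sd(y) == 0) {
    stop("response is constant; proportion of variance explained is undefined",
         call. = FALSE)
  }
  Xs <- scale(as.matrix(op_table[nm]))
  Xs[is.nan(Xs)] <- 0   # constant predictor contributes nothing
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, Xs[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  shares <- numeric(3)
  for (p in perms) {
    for (k in seq_along(p)) {
      shares[p[k]] <- shares[p[k]] + r2(p[seq_len(k)]) - r2(p[seq_len(k - 1)])
    }
  }
  shares <- pmax(shares / length(perms), 0)
  stats::setNames(shares / sum(shares), nm)
}
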