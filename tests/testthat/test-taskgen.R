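test_that("gaussian pool rows are normalized and seed-reproducible", {
  p1 <- make_gaussian_pool(10, 4, seed = 0)
  expect_equal(dim(p1$X), c(10L, 4L))
  expect_equal(unname(sqrt(rowSums(p1$X^2))), rep(2, 10))  # sqrt(N0) = 2
  expect_identical(p1$X, make_gaussian_pool(10, 4, seed = 0)$X)
  expect_false(identical(p1$X, make_gaussian_pool(10, 4, seed = 1)$X))
})

test_that("target-distractor construction realizes the requested index counts", {
  sq <- td_pair(P = 100, N0 = 20, rho_shared = 0.6, rho_target = 1,
                rho_flip = 0, seed = 5)
  m1 <- sq[[1]]$meta; m2 <- sq[[2]]$meta
  shared <- intersect(m1$pool_index, m2$pool_index)
  expect_length(shared, 60)                                 # round(0.6 * 100)
  expect_equal(sum(sq[[1]]$Y != 0), 50)                     # target_fraction 0.5
  # with rho_target = 1 every +-1 label sits on a shared stimulus
  expect_true(all(which(sq[[1]]$Y != 0) %in% seq_len(60)))
  expect_true(all(which(sq[[2]]$Y != 0) %in% seq_len(60)))
  expect_equal(sum(sq[[1]]$Y), 0)                           # balanced labels
})

test_that("degenerate target-distractor parameters give identical or label-consistent tasks", {
  sq <- td_pair(P = 40, N0 = 10, rho_shared = 1, rho_target = 1,
                rho_flip = 0, seed = 2)
  expect_identical(sq[[1]]$X, sq[[2]]$X)
  expect_identical(sq[[1]]$Y, sq[[2]]$Y)
  # rho_flip = 0: shared labels never differ even when tasks have unique rows
  sq2 <- td_pair(P = 40, N0 = 10, rho_shared = 0.5, rho_target = 1,
                 rho_flip = 0, seed = 3)
  sh <- sq2[[1]]$meta$shared_rows
  expect_identical(sq2[[1]]$Y[sh], sq2[[2]]$Y[sh])
})

test_that("flip fraction matches rho_flip within binomial error across seeds", {
  rho_flip <- 0.3
  n_targets <- 20   # P = 40, target_fraction 0.5, all targets shared
  flips <- vapply(1:200, function(s) {
    sq <- td_pair(P = 40, N0 = 8, rho_shared = 1, rho_target = 1,
                  rho_flip = rho_flip, seed = s)
    length(sq[[2]]$meta$flipped_rows) / n_targets
  }, numeric(1))
  se <- sqrt(rho_flip * (1 - rho_flip) / (200 * n_targets))
  expect_lt(abs(mean(flips) - rho_flip), 3 * se)
})

test_that("infeasible target-distractor counts raise a parameter error", {
  expect_error(td_params(rho_shared = 0.1, rho_target = 1, rho_flip = 0,
                         target_fraction = 0.5, P = 100),
               "infeasible")
})

test_that("generators are pure functions of their seed", {
  a <- td_pair(P = 30, N0 = 6, rho_shared = 0.5, rho_target = 0.5,
               rho_flip = 0.2, seed = 9)
  b <- td_pair(P = 30, N0 = 6, rho_shared = 0.5, rho_target = 0.5,
               rho_flip = 0.2, seed = 9)
  expect_identical(a$tasks, b$tasks)
})

test_that("permutation sequences permute columns, keep norms, and record the map", {
  set.seed(1)
  X <- normalize_inputs(matrix(rnorm(12 * 10), 12, 10))
  Y <- sample(c(-1, 1), 12, replace = TRUE)
  sq0 <- permutation_sequence(X, Y, T_tasks = 3, perm_ratio = 0, seed = 4)
  expect_identical(sq0[[2]]$X, X)                          # ratio 0: identical
  sq <- permutation_sequence(X, Y, T_tasks = 3, perm_ratio = 1, seed = 4)
  for (t in 2:3) {
    perm <- sq[[t]]$meta$perm
    expect_setequal(perm, 1:10)
    expect_identical(sq[[t]]$X, X[, perm])                 # column permutation of task 1
    expect_equal(rowSums(sq[[t]]$X^2), rowSums(X^2))       # norms exact
    expect_identical(sq[[t]]$Y, Y)
  }
  expect_warning(permutation_sequence(X, Y, 2, perm_ratio = 0.05, seed = 1),
                 "fewer than 2")
})

test_that("split sequences use disjoint classes with balanced dichotomies", {
  set.seed(8)
  M <- 400
  X <- matrix(rnorm(M * 6), M, 6)
  labels <- rep(1:8, each = 50)
  sq <- split_sequence(X, labels, T_tasks = 3, classes_per_task = 2, P = 40, seed = 2)
  cls <- lapply(sq$tasks, function(tk) tk$meta$classes)
  expect_length(unique(unlist(cls)), 6)                    # no class reused
  for (tk in sq$tasks) expect_equal(sum(tk$Y), 0)          # balanced +-1
  expect_error(split_sequence(X, labels, T_tasks = 5, classes_per_task = 2,
                              P = 40, seed = 2), "classes")
})

test_that("split-ratio pairs share exactly the complementary fraction of rows", {
  set.seed(3)
  M <- 600
  X <- matrix(rnorm(M * 5), M, 5)
  labels <- rep(1:6, each = 100)
  sq0 <- split_ratio_pair(X, labels, split_ratio = 0, P = 100, seed = 6)
  expect_identical(sq0[[1]]$X, sq0[[2]]$X)
  expect_identical(sq0[[1]]$Y, sq0[[2]]$Y)
  sq25 <- split_ratio_pair(X, labels, split_ratio = 0.25, P = 100, seed = 6)
  shared_rows <- sum(vapply(seq_len(100), function(i) {
    any(colSums(abs(t(sq25[[2]]$X) - sq25[[1]]$X[i, ])) < 1e-12)
  }, logical(1)))
  expect_equal(shared_rows, 75)
  sq1 <- split_ratio_pair(X, labels, split_ratio = 1, P = 100, seed = 6)
  shared_rows1 <- sum(vapply(seq_len(100), function(i) {
    any(colSums(abs(t(sq1[[2]]$X) - sq1[[1]]$X[i, ])) < 1e-12)
  }, logical(1)))
  expect_equal(shared_rows1, 0)
})

test_that("perturbed test sets keep labels and scale displacement as eta sqrt(N0)", {
  tk <- td_pair(P = 30, N0 = 100, rho_shared = 0.5, rho_target = 1,
                rho_flip = 0, seed = 7)[[1]]
  p0 <- perturbed_test(tk, 0, seed = 1)
  expect_equal(p0$X, tk$X)                                  # eta = 0 fixed point
  p <- perturbed_test(tk, 0.1, seed = 1)
  expect_identical(p$Y, tk$Y)
  # pre-normalization displacement ~ eta * sqrt(N0) = 1.0
  disp <- vapply(1:100, function(s) {
    Z <- clforget:::with_seed(s, matrix(rnorm(length(tk$X)), nrow(tk$X)))
    mean(sqrt(rowSums((0.1 * Z)^2)))
  }, numeric(1))
  expect_equal(mean(disp), 1.0, tolerance = 0.02)
})

test_that("label binarization honors and reproduces dichotomies", {
  labels <- rep(0:9, 3)
  dich <- setNames(rep(c(1, -1), 5), as.character(0:9))   # even/odd-ish fixed map
  out <- binarize_labels(labels, dich)
  expect_equal(out$Y[labels == 3], rep(dich[["3"]], 3))
  r1 <- binarize_labels(labels, NULL, seed = 5)
  expect_equal(sum(r1$dichotomy), 0)                       # balanced: 5 per side
  expect_identical(r1$Y, binarize_labels(labels, r1$dichotomy)$Y)
  expect_error(binarize_labels(labels, dich[1:9]), "not assigned")
})

test_that("sequence validation flags inconsistent members", {
  sq <- td_pair(P = 20, N0 = 5, rho_shared = 0.5, rho_target = 1,
                rho_flip = 0, seed = 1)
  expect_true(validate_sequence(sq))
  bad <- sq
  bad$tasks[[2]]$Y[] <- 0
  expect_error(validate_sequence(bad), "all-zero labels")
})
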