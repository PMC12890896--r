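# Task-sequence generators with controllable task relations: the
# target-distractor construction (shared stimuli / shared targets / label
# flips), input-permutation sequences, and class-split sequences, plus
# perturbed test sets. A synthetic Gaussian stimulus pool stands in for an
# image corpus so every code path runs without external data.

#' A single task's dataset
#'
#' @param X input matrix `[P x N0]`.
#' @param Y label vector of length `P`; 0 marks distractors in the
#'   target-distractor protocol, +-1 mark targets.
#' @param task_id identifier within a sequence.
#' @param meta provenance list (protocol, parameters, index sets).
#' @return an object of class `task_dataset`.
#' @export
task_dataset <- function(X, Y, task_id = 1L, meta = list()) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  assert_that(nrow(X) == length(Y), "X and Y disagree on the number of examples")
  assert_that(sum(Y != 0) > 0, "labels are all zero; at least one nonzero label required")
  structure(list(X = X, Y = Y, task_id = task_id, meta = meta),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> id=%s, P=%d, N0=%d, labels: %d target / %d distractor\n",
              x$task_id, nrow(x$X), ncol(x$X), sum(x$Y != 0), sum(x$Y == 0)))
  invisible(x)
}

#' An ordered sequence of same-sized tasks
#'
#' @param tasks list of [task_dataset()] objects sharing `P` and `N0`.
#' @param protocol generation protocol name.
#' @param params protocol parameters.
#' @param seed generating seed.
#' @return an object of class `task_sequence` (also a list of tasks).
#' @export
task_sequence <- function(tasks, protocol = "custom", params = list(), seed = NA_integer_) {
  assert_that(length(tasks) >= 2, "a task sequence needs T >= 2 tasks")
  P <- nrow(tasks[[1]]$X); N0 <- ncol(tasks[[1]]$X)
  for (tk in tasks) {
    assert_that(nrow(tk$X) == P && ncol(tk$X) == N0,
                "all tasks in a sequence must share P and N0")
  }
  structure(list(tasks = tasks, protocol = protocol, params = params,
                 seed = seed, P = P, N0 = N0),
            class = "task_sequence")
}

#' @export
length.task_sequence <- function(x) length(x$tasks)

#' @export
`[[.task_sequence` <- function(x, i) x$tasks[[i]]

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> T=%d, P=%d, N0=%d, protocol=%s\n",
              length(x$tasks), x$P, x$N0, x$protocol))
  invisible(x)
}

#' Validate a task sequence against its invariants
#'
#' Checks shared dimensions, finite inputs, and nonzero labels; errors with
#' the failing task index.
#'
#' @param seq a [task_sequence()].
#' @return `TRUE` invisibly.
#' @export
validate_sequence <- function(seq) {
  stopifnot(inherits(seq, "task_sequence"))
  for (i in seq_along(seq$tasks)) {
    tk <- seq$tasks[[i]]
    assert_that(inherits(tk, "task_dataset"), sprintf("task %d is not a task_dataset", i))
    assert_that(all(is.finite(tk$X)), sprintf("task %d has non-finite inputs", i))
    assert_that(nrow(tk$X) == seq$P && ncol(tk$X) == seq$N0,
                sprintf("task %d has inconsistent dimensions", i))
    assert_that(sum(tk$Y != 0) > 0, sprintf("task %d has all-zero labels", i))
  }
  invisible(TRUE)
}

#' Synthetic Gaussian stimulus pool
#'
#' i.i.d. standard-normal rows, row-normalized to norm `sqrt(N0)`. Used as
#' the stimulus corpus for the target-distractor protocol.
#'
#' @param M pool size.
#' @param N0 input dimension.
#' @param seed integer seed.
#' @param labels optional integer class labels of length `M` (for the split
#'   protocols a labeled pool is required).
#' @return an object of class `stimulus_pool`: list with `X`, `labels`, `seed`.
#' @export
make_gaussian_pool <- function(M, N0, seed = 1L, labels = NULL) {
  assert_that(M >= 1 && N0 >= 1, "M and N0 must be >= 1")
  X <- with_seed(seed, matrix(stats::rnorm(M * N0), nrow = M, ncol = N0))
  X <- normalize_inputs(X)
  if (!is.null(labels)) assert_that(length(labels) == M, "labels must have length M")
  structure(list(X = X, labels = labels, seed = as.integer(seed)),
            class = "stimulus_pool")
}

#' Parameters of the target-distractor construction
#'
#' `rho_shared` is the fraction of each task's P stimuli reused across the
#' whole sequence; `rho_target` the fraction of the +-1-labeled (target)
#' stimuli that are taken from the shared set; `rho_flip` the probability
#' that a shared target's label is flipped in task t > 1 relative to task 1;
#' `target_fraction` the fraction of stimuli carrying +-1 (vs 0) labels.
#'
#' @param rho_shared,rho_target in `[0, 1]`.
#' @param rho_flip in `[0, 0.5]`.
#' @param target_fraction in `(0, 1]`.
#' @param P examples per task.
#' @param T_tasks number of tasks.
#' @param seed integer seed.
#' @param strict error when `rho_target` requests more shared targets than
#'   there are shared stimuli; with `strict = FALSE` the count is capped at
#'   the shared-set size instead (useful for sweeps over the full parameter
#'   grid, where corners with low `rho_shared` are otherwise unreachable).
#' @return an object of class `td_params`.
#' @export
td_params <- function(rho_shared, rho_target, rho_flip,
                      target_fraction = 0.5, P, T_tasks = 2L, seed = 1L,
                      strict = TRUE) {
  assert_that(rho_shared >= 0 && rho_shared <= 1, "rho_shared must be in [0,1]")
  assert_that(rho_target >= 0 && rho_target <= 1, "rho_target must be in [0,1]")
  assert_that(rho_flip >= 0 && rho_flip <= 0.5, "rho_flip must be in [0,0.5]")
  assert_that(target_fraction > 0 && target_fraction <= 1,
              "target_fraction must be in (0,1]")
  assert_that(T_tasks >= 2, "T_tasks must be >= 2")
  n_sh <- round_half_up(rho_shared * P)
  n_tg <- round_half_up(target_fraction * P)
  n_tg_sh <- min(round_half_up(rho_target * n_tg), n_sh)
  if (strict && round_half_up(rho_target * n_tg) > n_sh) {
    stop(sprintf(
      "infeasible parameters: rho_target requests %d shared targets but only %d stimuli are shared",
      round_half_up(rho_target * n_tg), n_sh), call. = FALSE)
  }
  structure(list(rho_shared = rho_shared, rho_target = rho_target,
                 rho_flip = rho_flip, target_fraction = target_fraction,
                 P = as.integer(P), T_tasks = as.integer(T_tasks),
                 seed = as.integer(seed),
                 n_shared = as.integer(n_sh), n_target = as.integer(n_tg),
                 n_target_shared = as.integer(n_tg_sh)),
            class = "td_params")
}

# balanced +1/-1 vector of length n (difference at most one), random order
balanced_signs <- function(n) {
  if (n == 0) return(numeric(0))
  s <- rep(c(1, -1), length.out = n)
  sample(s)
}

#' Generate a target-distractor task sequence
#'
#' Each task has `P` stimuli: `round(rho_shared * P)` drawn once and reused
#' in every task, the rest unique per task. Per task, `round(target_fraction
#' * P)` stimuli carry balanced +-1 labels, the remainder 0; a fraction
#' `rho_target` of the targets sit on shared stimuli. For shared targets,
#' tasks t > 1 flip each label independently with probability `rho_flip`
#' relative to task 1, so all pairwise task relations are statistically
#' identical. Deterministic given `params$seed`.
#'
#' @param pool a [make_gaussian_pool()] pool (or any `stimulus_pool`).
#' @param params a [td_params()] object.
#' @return a [task_sequence()]; per-task `meta` records the index sets.
#' @export
target_distractor_sequence <- function(pool, params) {
  stopifnot(inherits(pool, "stimulus_pool"), inherits(params, "td_params"))
  P <- params$P; T_tasks <- params$T_tasks
  n_sh <- params$n_shared; n_tg <- params$n_target; n_tg_sh <- params$n_target_shared
  n_unique <- P - n_sh
  need <- n_sh + T_tasks * n_unique
  assert_that(nrow(pool$X) >= need,
              sprintf("pool too small: need %d stimuli, have %d", need, nrow(pool$X)))
  with_seed(params$seed, {
    idx_all <- sample.int(nrow(pool$X), need)
    idx_shared <- idx_all[seq_len(n_sh)]
    idx_rest <- if (n_sh > 0) idx_all[-seq_len(n_sh)] else idx_all

    # which shared stimuli are targets (common to all tasks)
    sh_target_pos <- if (n_tg_sh > 0) sample.int(max(n_sh, 1), n_tg_sh) else integer(0)
    base_sh_labels <- numeric(n_sh)
    base_sh_labels[sh_target_pos] <- balanced_signs(n_tg_sh)

    tasks <- vector("list", T_tasks)
    for (t in seq_len(T_tasks)) {
      idx_uni <- idx_rest[((t - 1) * n_unique + seq_len(n_unique))]
      n_tg_uni <- n_tg - n_tg_sh
      uni_labels <- numeric(n_unique)
      if (n_tg_uni > 0) {
        if (n_tg_uni > n_unique) {
          stop(sprintf(
            "infeasible parameters: %d unique targets requested but only %d unique stimuli per task",
            n_tg_uni, n_unique), call. = FALSE)
        }
        uni_target_pos <- sample.int(n_unique, n_tg_uni)
        uni_labels[uni_target_pos] <- balanced_signs(n_tg_uni)
      }
      sh_labels <- base_sh_labels
      flipped <- integer(0)
      if (t > 1 && n_tg_sh > 0 && params$rho_flip > 0) {
        flip <- stats::runif(n_tg_sh) < params$rho_flip
        flipped <- sh_target_pos[flip]
        sh_labels[flipped] <- -sh_labels[flipped]
      }
      idx <- c(idx_shared, idx_uni)
      tasks[[t]] <- task_dataset(
        X = pool$X[idx, , drop = FALSE],
        Y = c(sh_labels, uni_labels),
        task_id = t,
        meta = list(pool_index = idx, shared_rows = seq_len(n_sh),
                    shared_target_rows = sh_target_pos, flipped_rows = flipped)
      )
    }
  })
  task_sequence(tasks, protocol = "target_distractor",
                params = unclass(params), seed = params$seed)
}

#' Generate an input-permutation task sequence
#'
#' Task 1 is `(X, Y)`; every later task applies one fresh random permutation
#' of a uniformly chosen subset of `round(perm_ratio * N0)` coordinates to
#' all rows of `X` (labels unchanged). The subset and permutation are
#' resampled per task so pairwise similarity is stationary along the
#' sequence.
#'
#' @param X input matrix, `Y` labels.
#' @param T_tasks sequence length.
#' @param perm_ratio fraction of coordinates permuted, in `[0, 1]`.
#' @param seed integer seed.
#' @return a [task_sequence()]; each task's `meta$perm` stores the full
#'   column permutation applied to task 1's inputs.
#' @export
permutation_sequence <- function(X, Y, T_tasks, perm_ratio, seed = 1L) {
  X <- as.matrix(X)
  assert_that(perm_ratio >= 0 && perm_ratio <= 1, "perm_ratio must be in [0,1]")
  N0 <- ncol(X)
  k <- round_half_up(perm_ratio * N0)
  if (perm_ratio > 0 && k < 2) {
    warning("perm_ratio rounds to fewer than 2 coordinates; permuting 2 (minimum nontrivial cycle)")
    k <- 2L
  }
  with_seed(seed, {
    tasks <- vector("list", T_tasks)
    tasks[[1]] <- task_dataset(X, Y, task_id = 1L,
                               meta = list(perm = seq_len(N0), perm_ratio = perm_ratio))
    for (t in seq.int(2L, length.out = T_tasks - 1L)) {
      perm <- seq_len(N0)
      if (k >= 2) {
        subset <- sample.int(N0, k)
        perm[subset] <- subset[sample.int(k)]
      }
      tasks[[t]] <- task_dataset(X[, perm, drop = FALSE], Y, task_id = t,
                                 meta = list(perm = perm, perm_ratio = perm_ratio))
    }
  })
  task_sequence(tasks, protocol = "permutation",
                params = list(perm_ratio = perm_ratio, T_tasks = T_tasks),
                seed = seed)
}

# draw a balanced random dichotomy over `classes`; returns named +-1 vector
random_dichotomy <- function(classes) {
  k <- length(classes)
  assert_that(k >= 2, "need at least two classes for a dichotomy")
  side <- rep(c(1, -1), length.out = k)[sample.int(k)]
  stats::setNames(side, as.character(classes))
}

#' Map multiway class labels to +-1 by a dichotomy
#'
#' @param labels integer/character class labels.
#' @param dichotomy named vector mapping every class to +1 or -1; if `NULL`
#'   a balanced random dichotomy is drawn from `seed`.
#' @param seed used only when `dichotomy` is `NULL`.
#' @return list with `Y` (+-1 vector) and `dichotomy` (the mapping used).
#' @export
binarize_labels <- function(labels, dichotomy = NULL, seed = 1L) {
  cls <- sort(unique(as.character(labels)))
  if (is.null(dichotomy)) {
    dichotomy <- with_seed(seed, random_dichotomy(cls))
  }
  missing <- setdiff(cls, names(dichotomy))
  assert_that(length(missing) == 0,
              sprintf("class(es) not assigned by the dichotomy: %s",
                      paste(missing, collapse = ", ")))
  list(Y = unname(dichotomy[as.character(labels)]), dichotomy = dichotomy)
}

#' Generate a class-split task sequence
#'
#' Each task draws `P` examples from its own disjoint set of
#' `classes_per_task` source classes; +-1 labels come from a per-task
#' balanced random dichotomy over those classes.
#'
#' @param X input matrix; `labels` integer class labels per row.
#' @param T_tasks sequence length; `classes_per_task` classes per task.
#' @param P examples per task.
#' @param seed integer seed.
#' @return a [task_sequence()]; `meta$classes` records each task's classes.
#' @export
split_sequence <- function(X, labels, T_tasks, classes_per_task, P, seed = 1L) {
  X <- as.matrix(X)
  cls <- sort(unique(labels))
  assert_that(length(cls) >= T_tasks * classes_per_task,
              sprintf("need %d distinct classes, have %d",
                      T_tasks * classes_per_task, length(cls)))
  with_seed(seed, {
    cls_order <- sample(cls)
    tasks <- vector("list", T_tasks)
    for (t in seq_len(T_tasks)) {
      task_cls <- cls_order[(t - 1) * classes_per_task + seq_len(classes_per_task)]
      rows <- which(labels %in% task_cls)
      assert_that(length(rows) >= P,
                  sprintf("task %d: only %d examples available for P=%d", t, length(rows), P))
      # draw near-equal counts per class so the balanced dichotomy balances Y
      per_cls <- split(rows, labels[rows])[as.character(task_cls)]
      take <- integer(0)
      quota <- rep(P %/% classes_per_task, classes_per_task)
      extra <- P - sum(quota)
      if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
      for (j in seq_along(per_cls)) {
        assert_that(length(per_cls[[j]]) >= quota[j],
                    sprintf("task %d: class %s has %d examples, needs %d",
                            t, task_cls[j], length(per_cls[[j]]), quota[j]))
        take <- c(take, sample(per_cls[[j]], quota[j]))
      }
      dich <- random_dichotomy(task_cls)
      tasks[[t]] <- task_dataset(
        X[take, , drop = FALSE],
        unname(dich[as.character(labels[take])]),
        task_id = t,
        meta = list(classes = task_cls, dichotomy = dich, rows = take)
      )
    }
  })
  task_sequence(tasks, protocol = "split",
                params = list(classes_per_task = classes_per_task, T_tasks = T_tasks, P = P),
                seed = seed)
}

#' Two tasks related by a controllable split ratio
#'
#' Task 2 equals task 1 with `round(split_ratio * P)` of its examples
#' replaced by examples from classes unused in task 1 (labels from a fresh
#' dichotomy on the replacement classes). `split_ratio = 0` gives identical
#' tasks; `split_ratio = 1` fully disjoint tasks.
#'
#' @param X input matrix; `labels` class labels; `split_ratio` in `[0,1]`;
#'   `P` examples per task; `classes_per_task` classes backing each side;
#'   `seed` integer seed.
#' @return a T=2 [task_sequence()].
#' @export
split_ratio_pair <- function(X, labels, split_ratio, P, classes_per_task = 2L, seed = 1L) {
  assert_that(split_ratio >= 0 && split_ratio <= 1, "split_ratio must be in [0,1]")
  base <- split_sequence(X, labels, T_tasks = 2L, classes_per_task = classes_per_task,
                         P = P, seed = seed)
  n_rep <- round_half_up(split_ratio * P)
  t1 <- base$tasks[[1]]
  X2 <- t1$X; Y2 <- t1$Y
  replaced <- integer(0)
  if (n_rep > 0) {
    with_seed(derive_seed(seed, "split_ratio"), {
      replaced <- sample.int(P, n_rep)
    })
    X2[replaced, ] <- base$tasks[[2]]$X[seq_len(n_rep), , drop = FALSE]
    Y2[replaced] <- base$tasks[[2]]$Y[seq_len(n_rep)]
  }
  t2 <- task_dataset(X2, Y2, task_id = 2L,
                     meta = list(replaced_rows = replaced, split_ratio = split_ratio,
                                 donor_classes = base$tasks[[2]]$meta$classes))
  task_sequence(list(t1, t2), protocol = "split_ratio",
                params = list(split_ratio = split_ratio, P = P,
                              classes_per_task = classes_per_task),
                seed = seed)
}

#' Perturbed copy of a task for generalization tests
#'
#' Adds isotropic Gaussian noise with per-row expected norm `eta * sqrt(N0)`
#' to the inputs and renormalizes; labels unchanged. With `eta = 0` the
#' inputs are returned unchanged (normalization is a fixed point on
#' normalized data).
#'
#' @param task a [task_dataset()].
#' @param eta perturbation scale >= 0.
#' @param seed integer seed.
#' @return a [task_dataset()] with perturbed inputs.
#' @export
perturbed_test <- function(task, eta, seed = 1L) {
  stopifnot(inherits(task, "task_dataset"))
  assert_that(eta >= 0, "eta must be >= 0")
  if (eta == 0) {
    Xp <- normalize_inputs(task$X)
  } else {
    Z <- with_seed(seed, matrix(stats::rnorm(length(task$X)), nrow = nrow(task$X)))
    Xp <- normalize_inputs(task$X + eta * Z)
  }
  task_dataset(Xp, task$Y, task_id = task$task_id,
               meta = c(task$meta, list(perturbation_eta = eta)))
}
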