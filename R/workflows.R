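# End-to-end experiment drivers: a validated configuration object, four
# named drivers (order-parameter grids, single-head forgetting curves,
# multihead load scans, penalty sweeps), CSV/JSON outputs with a manifest,
# and a small reporting helper. Every random draw flows from seeds recorded
# in the manifest.

driver_names <- c("ops-grid", "singlehead-curve", "multihead-phase", "lambda-sweep")

#' Experiment configuration
#'
#' Builds and validates the configuration consumed by [run_experiment()].
#' Can also be read from a YAML or JSON file with [load_config()].
#'
#' @param driver one of `"ops-grid"`, `"singlehead-curve"`,
#'   `"multihead-phase"`, `"lambda-sweep"`.
#' @param params named list of driver parameters (see the vignette).
#' @param seeds integer vector of seeds (explicit, never derived from time).
#' @param out_dir output directory (`NULL` for no file output).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(driver, params = list(), seeds = 1L, out_dir = NULL) {
  if (!driver %in% driver_names) {
    stop(sprintf("config error at $driver: '%s' is not one of %s",
                 driver, paste(driver_names, collapse = ", ")), call. = FALSE)
  }
  required <- switch(driver,
    "ops-grid" = c("P", "N0", "depth"),
    "singlehead-curve" = c("P", "N0", "depth", "T_tasks"),
    "multihead-phase" = c("N", "N0", "alphas"),
    "lambda-sweep" = c("N", "N0", "P", "lambdas"))
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop(sprintf("config error at $params$%s: required field missing",
                 missing[1]), call. = FALSE)
  }
  assert_that(length(seeds) >= 1 && all(is.finite(seeds)),
              "config error at $seeds: need at least one finite seed")
  structure(list(driver = driver, params = params,
                 seeds = as.integer(seeds), out_dir = out_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package).
#' @return an [experiment_config()].
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  experiment_config(driver = raw$driver %||% stop("config error at $driver: missing"),
                    params = as.list(raw$params),
                    seeds = raw$seeds %||% 1L,
                    out_dir = raw$out_dir)
}

td_pair_for <- function(p, P, N0, seed) {
  pool <- make_gaussian_pool(max(4L * P, 2L * P + 200L), N0,
                             derive_seed(seed, "pool"))
  pars <- td_params(p$rho_shared, p$rho_target, p$rho_flip,
                    p$target_fraction %||% 0.5, P = P,
                    T_tasks = p$T_tasks %||% 2L, seed = seed,
                    strict = isTRUE(p$strict))
  target_distractor_sequence(pool, pars)
}

run_ops_grid <- function(cfg) {
  p <- cfg$params
  rho_shared <- p$rho_shared %||% seq(0.1, 0.9, length.out = 5)
  rho_target <- p$rho_target %||% seq(0, 1, length.out = 11)
  rho_flip <- p$rho_flip %||% seq(0, 0.5, length.out = 11)
  grid <- expand.grid(rho_shared = rho_shared, rho_target = rho_target,
                      rho_flip = rho_flip, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    per_seed <- vapply(cfg$seeds, function(s) {
      sq <- td_pair_for(list(rho_shared = g$rho_shared, rho_target = g$rho_target,
                             rho_flip = g$rho_flip,
                             target_fraction = p$target_fraction %||% 0.5),
                        p$P, p$N0, s)
      gs <- gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = p$depth,
                     sigma = p$sigma %||% 1)
      op <- order_params(gs, sq[[1]]$Y, sq[[2]]$Y)
      sim <- gamma_sim(gs, sq[[1]]$Y, sq[[2]]$Y)
      c(op$gamma_feature, op$gamma_RF, op$gamma_rule, op$conflict, sim$gamma_sim)
    }, numeric(5))
    mm <- rowMeans(per_seed)
    cbind(g, data.frame(gamma_feature = mm[1], gamma_RF = mm[2],
                        gamma_rule = mm[3], conflict = mm[4], gamma_sim = mm[5]))
  })
  list(table = do.call(rbind, rows))
}

run_singlehead_curve <- function(cfg) {
  p <- cfg$params
  spec <- feature_map_spec(depth = p$depth, width = p$width %||% 2000L,
                           input_dim = p$N0, sigma = p$sigma %||% 1,
                           seed = cfg$seeds[1])
  path <- p$path %||% "kernel"
  curves <- vapply(cfg$seeds, function(s) {
    sq <- td_pair_for(p, p$P, p$N0, s)
    forgetting_curve(sq, spec, path = path)$F
  }, numeric(p$T_tasks %||% 2L))
  Fbar <- if (is.matrix(curves)) rowMeans(curves) else curves
  Fsd <- if (is.matrix(curves) && length(cfg$seeds) > 1) {
    apply(curves, 1, stats::sd)
  } else rep(NA_real_, length(Fbar))
  res <- list(table = data.frame(t = seq_along(Fbar), F_t1 = Fbar, sd = Fsd),
              F21 = Fbar[2])
  if (length(Fbar) >= 4 && sum(Fbar != 0) >= 3) {
    fit <- fit_exponential(Fbar)
    res$fit <- fit
    res$Fmax_predicted <- if (!fit$degenerate && !is.na(fit$tau)) {
      predict_fmax(Fbar[2], fit$tau)
    } else NA_real_
  }
  ops <- vapply(cfg$seeds, function(s) {
    sq <- td_pair_for(p, p$P, p$N0, s)
    gs <- gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = p$depth,
                   sigma = p$sigma %||% 1)
    op <- order_params(gs, sq[[1]]$Y, sq[[2]]$Y)
    c(op$gamma_feature, op$gamma_RF, op$gamma_rule)
  }, numeric(3))
  mo <- rowMeans(ops)
  res$order_params <- stats::setNames(mo, c("gamma_feature", "gamma_RF", "gamma_rule"))
  res$F21_predicted <- 2 * (mo[2] - mo[3])
  res$delta_F21 <- mean(vapply(cfg$seeds, function(s) {
    delta_f21(td_pair_for(p, p$P, p$N0, s), spec, path = path)$delta_F21
  }, numeric(1)))
  res
}

run_multihead_phase <- function(cfg) {
  p <- cfg$params
  N <- p$N; N0 <- p$N0
  tcfg <- train_config(lambda = p$lambda %||% Inf, seed = cfg$seeds[1],
                       tol = p$tol %||% 1e-8)
  gsim <- mean(vapply(cfg$seeds, function(s) {
    sq <- td_pair_for(p, p$P_ref %||% 200L, N0, s)
    gamma_sim(gram_set(sq[[1]]$X, sq[[2]]$X, path = "kernel", depth = 1),
              sq[[1]]$Y, sq[[2]]$Y)$gamma_sim
  }, numeric(1)))
  rows <- lapply(p$alphas, function(al) {
    per <- vapply(cfg$seeds, function(s) {
      P <- max(round_half_up(al * N), 2)
      sq <- td_pair_for(p, P, N0, derive_seed(s, "phase", round(100 * al)))
      ck <- tcfg; ck$seed <- derive_seed(s, "phaseW", round(100 * al))
      m <- multihead_run(sq[[1]], sq[[2]], N, ck)
      c(m$F21, m$a2_norm, m$dW_norm)
    }, numeric(3))
    mm <- rowMeans(per)
    data.frame(alpha = al, F21 = mm[1], a2_norm = mm[2], dW_norm = mm[3],
               regime = classify_regime(al, gsim)$regime)
  })
  tab <- do.call(rbind, rows)
  ac_emp <- if (sum(tab$alpha > 1) >= 5) {
    tryCatch(empirical_alpha_c(tab$alpha[tab$alpha > 1], tab$F21[tab$alpha > 1]),
             warning = function(w) Inf)
  } else NA_real_
  list(table = tab, gamma_sim = gsim,
       alpha_c_theory = critical_load(gsim), alpha_c_empirical = ac_emp)
}

run_lambda_sweep <- function(cfg) {
  p <- cfg$params
  sq <- td_pair_for(p, p$P, p$N0, cfg$seeds[1])
  tcfg <- train_config(seed = cfg$seeds[1], tol = p$tol %||% 1e-8)
  sw <- lambda_sweep(sq[[1]], sq[[2]], p$N, p$lambdas, tcfg,
                     n_seeds = length(cfg$seeds), eta = p$eta %||% 0.1)
  list(table = sw$table, optimal_lambda = sw$optimal_lambda, G20 = sw$G20)
}

#' Run a configured experiment driver
#'
#' Executes the driver named in the config and, when `out_dir` is set,
#' writes `results.csv`, `summary.json` and a `manifest.json` holding the
#' full configuration, seeds and per-stage timings.
#'
#' @param cfg an [experiment_config()].
#' @return a result bundle: list with `table` (data frame), driver-specific
#'   summaries, `config` and `timings`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time()
  res <- switch(cfg$driver,
    "ops-grid" = run_ops_grid(cfg),
    "singlehead-curve" = run_singlehead_curve(cfg),
    "multihead-phase" = run_multihead_phase(cfg),
    "lambda-sweep" = run_lambda_sweep(cfg))
  res$config <- cfg
  res$timings <- list(total_sec = as.numeric(Sys.time() - t0, units = "secs"))
  class(res) <- "result_bundle"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$table, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE)
    summ <- res[setdiff(names(res), c("table", "config"))]
    jsonlite::write_json(summ, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(list(driver = cfg$driver, params = cfg$params,
                              seeds = cfg$seeds,
                              timings = res$timings),
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> driver=%s, %d rows, %.1fs\n",
              x$config$driver, nrow(x$table), x$timings$total_sec))
  invisible(x)
}

#' Summarize a result bundle
#'
#' Renders a compact summary (and optional ggplot2 figures) of a driver's
#' output: forgetting versus conflict for order-parameter grids, the fitted
#' relaxation for single-head curves, the load scan with regime labels for
#' phase experiments, and the trade-off curve for penalty sweeps.
#'
#' @param bundle a `result_bundle` from [run_experiment()].
#' @param plots also build ggplot2 objects (requires ggplot2).
#' @return an object of class `experiment_report`: list with `summary`
#'   (data frame), `notes` (character), and optionally `figures`.
#' @export
report <- function(bundle, plots = FALSE) {
  if (is.null(bundle) || is.null(bundle$table) || nrow(bundle$table) == 0) {
    return(structure(list(summary = data.frame(), notes = "empty report: no results",
                          empty = TRUE), class = "experiment_report"))
  }
  tab <- bundle$table
  driver <- bundle$config$driver
  notes <- character(0)
  if (driver == "multihead-phase") {
    counts <- table(tab$regime)
    notes <- c(notes, sprintf("regimes: %s",
                              paste(names(counts), counts, sep = "=", collapse = ", ")),
               sprintf("alpha_c theory %.3g, empirical %.3g",
                       bundle$alpha_c_theory, bundle$alpha_c_empirical))
  }
  if (driver == "singlehead-curve" && !is.null(bundle$fit) && !bundle$fit$degenerate) {
    notes <- c(notes, sprintf("exponential fit: Fmax=%.4g tau=%.4g (rms %.2g)",
                              bundle$fit$Fmax, bundle$fit$tau, bundle$fit$rms),
               sprintf("Fmax from F21 and tau: %.4g", bundle$Fmax_predicted))
  }
  if (driver == "lambda-sweep") {
    notes <- c(notes, sprintf("optimal lambda %.4g", bundle$optimal_lambda))
  }
  out <- list(summary = tab, notes = notes, empty = FALSE)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    out$figures <- report_figures(bundle)
  }
  structure(out, class = "experiment_report")
}

report_figures <- function(bundle) {
  tab <- bundle$table
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  switch(bundle$config$driver,
    "ops-grid" = list(
      f21_vs_conflict = gg(tab, aes(x = conflict, y = 2 * conflict,
                                    colour = gamma_feature)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "conflict", y = "predicted F21")),
    "singlehead-curve" = list(
      curve = gg(tab, aes(x = t, y = F_t1)) + ggplot2::geom_line() +
        ggplot2::geom_point() + ggplot2::labs(y = "F(t,1)")),
    "multihead-phase" = list(
      phase = gg(tab, aes(x = alpha, y = F21, colour = regime)) +
        ggplot2::geom_point() + ggplot2::geom_line(aes(group = 1))),
    "lambda-sweep" = list(
      tradeoff = gg(tab, aes(x = lambda, y = max_G)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::scale_x_log10()))
}

#' @export
print.experiment_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<experiment_report> empty report: no results\n")
    return(invisible(x))
  }
  cat("<experiment_report>\n")
  for (n in x$notes) cat(" ", n, "\n")
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("  ...", nrow(x$summary) - 10, "more rows\n")
  invisible(x)
}
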