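#' Read and write run traces
#'
#' Lossless CSV round trip for the per-iteration trace of an [run_strategy()]
#' result (columns `t, n_minority, n_majority, n_train, N_t, L, surplus_used,
#' fallback, eligible_size, accuracy, auc`).
#'
#' @param trace a trace data.frame (or an `al_run`, whose trace is taken).
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace data.frame (empty file, empty trace).
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "al_run")) trace <- trace$trace
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trace_columns <- c("t", "n_minority", "n_majority", "n_train", "N_t", "L",
                   "surplus_used", "fallback", "eligible_size", "accuracy",
                   "auc")

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (file.exists(path) && file.size(path) == 0)
    return(data.frame())                      # empty trace, not an error
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("malformed trace file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (!nrow(df) && !ncol(df)) return(df)
  miss <- setdiff(trace_columns, names(df))
  if (length(miss))
    stop("trace file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[trace_columns]
  int_cols <- c("t", "n_minority", "n_majority", "n_train", "N_t", "L",
                "surplus_used", "eligible_size")
  for (cl in int_cols) df[[cl]] <- as.integer(df[[cl]])
  for (cl in c("accuracy", "auc")) df[[cl]] <- as.numeric(df[[cl]])
  df$fallback <- as.logical(df$fallback)
  df
}

#' Experiment presets
#'
#' Named parameter bundles mirroring the three study harnesses:
#' `experiment1` compares the five strategies (T = 40, tau = 0.25, K = 2
#' with quotas 1/1, replicated trials); `experiment2` sweeps the training-set
#' minority ratio from 20% to 80% at K = 10; `experiment3` compares the
#' predicted cost curve (p0 = 0.04) with observed class-balancing costs.
#'
#' @param name preset name.
#' @return named list of configuration values; override any field via
#'   [run_experiment()]'s config.
#' @export
experiment_preset <- function(name = c("experiment1", "experiment2",
                                       "experiment3")) {
  name <- match.arg(name)
  base <- list(pool = list(n_total = 12588, minority_fraction = 0.04,
                           class_separation = 2, dim = 14),
               test_fraction = 1346 / 12588, seed = 1L)
  switch(name,
    experiment1 = utils::modifyList(base, list(
      harness = "compare", n_trials = 10,
      strategies = c("cbal", "ubal", "cbrl", "ubrl", "full"),
      config = list(T = 40, tau = 0.25, k1_hat = 1, k2_hat = 1,
                    eval_every = 5))),
    experiment2 = utils::modifyList(base, list(
      harness = "ratio_sweep", n_trials = 1,
      minority_percent = c(20, 40, 50, 60, 80),
      config = list(T = 40, tau = 0.25, K = 10, eval_every = 5))),
    experiment3 = utils::modifyList(base, list(
      harness = "cost", n_trials = 10, p0 = 0.04,
      config = list(T = 40, tau = 0.25, k1_hat = 1, k2_hat = 1))))
}

#' Run a configured experiment and write its artifacts
#'
#' Drives one of the three experiment harnesses from a configuration list or
#' YAML file, writing CSV tables and a machine-readable manifest (config and
#' seeds) to `out_dir`. Re-running with the same configuration reproduces
#' byte-identical CSV bodies.
#'
#' @param config a preset name (see [experiment_preset()]), a YAML file path,
#'   or a configuration list. List/YAML fields override the preset named in
#'   their `preset` field (default `experiment1`).
#' @param out_dir output directory (created).
#' @return invisibly, the paths written.
#' @export
run_experiment <- function(config = "experiment1", out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else list(preset = config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(experiment_preset(config$preset %||% "experiment1"),
                           config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(pool_spec, c(cfg$pool, list(seed = cfg$seed)))
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }

  if (cfg$harness == "compare") {
    cmp <- compare_strategies(spec, strategies = cfg$strategies,
                              n_trials = cfg$n_trials,
                              test_fraction = cfg$test_fraction,
                              config_args = cfg$config, seed = cfg$seed)
    put(as.data.frame(cmp), "comparison_long.csv")
    put(summary(cmp), "comparison_summary.csv")
  } else if (cfg$harness == "ratio_sweep") {
    K <- cfg$config$K %||% 10
    rows <- lapply(cfg$minority_percent, function(pct) {
      k1 <- as.integer(round(K * pct / 100))
      args <- utils::modifyList(cfg$config,
                                list(k1_hat = k1, k2_hat = K - k1, K = NULL))
      cmp <- compare_strategies(spec, strategies = "cbal",
                                n_trials = cfg$n_trials,
                                test_fraction = cfg$test_fraction,
                                config_args = args, seed = cfg$seed)
      cbind(minority_percent = pct, as.data.frame(cmp))
    })
    put(do.call(rbind, rows), "ratio_sweep_long.csv")
  } else if (cfg$harness == "cost") {
    pool <- make_feature_pool(spec)
    parts <- split_pool(pool, cfg$test_fraction, seed = cfg$seed)
    k1 <- cfg$config$k1_hat %||% 1; k2 <- cfg$config$k2_hat %||% 1
    T <- cfg$config$T %||% 40
    obs <- observed_balancing_costs(parts$train, k1, k2, T,
                                    n_replicates = cfg$n_trials,
                                    seed = cfg$seed)
    pred <- predict_cost_curve(cfg$p0, k1, k2, T,
                               pool_size = length(parts$train$ids),
                               statistic = "mean")
    put(data.frame(t = pred$t, p_t = pred$p_t, predicted_N_t = pred$predicted_n,
                   observed_mean_N_t = obs$mean_N_t,
                   cumulative_L = pred$cumulative),
        "cost_predicted_vs_observed.csv")
  } else stop("unknown harness: ", cfg$harness, call. = FALSE)

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = cfg, files = basename(paths),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("cbal"))),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, manifest))
}

#' Observed class-balancing costs over replicated runs
#'
#' Runs quota-constrained random querying (the class-balanced random-learning
#' annotation loop, no committee) on a pool for `T` iterations in
#' `n_replicates` independent seeded replicates and reports the
#' per-iteration mean observed annotation count — the empirical quantity the
#' cost model predicts.
#'
#' @param pool a `sample_pool`.
#' @param k1_hat,k2_hat per-iteration class quotas.
#' @param T iterations per replicate.
#' @param n_replicates number of replicates.
#' @param seed root seed.
#' @return list with `mean_N_t` (length-`T` vector) and `N_t` (replicate x
#'   iteration matrix).
#' @export
observed_balancing_costs <- function(pool, k1_hat, k2_hat, T,
                                     n_replicates = 50, seed = 1L) {
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          n_replicates))
  N <- matrix(NA_real_, n_replicates, T)
  for (r in seq_len(n_replicates)) {
    oracle <- annotation_oracle(pool)
    unlabeled <- pool$ids
    iter_seeds <- with_seed(rep_seeds[r],
                            sample.int(.Machine$integer.max - 1L, T))
    for (t in seq_len(T)) {
      res <- min_class_query(unlabeled, oracle, k1_hat, k2_hat,
                             pool_ids = unlabeled, fallback = FALSE,
                             seed = iter_seeds[t], iteration = t)
      unlabeled <- setdiff(unlabeled, union(res$ids, res$charged_ids))
      N[r, t] <- res$n_annotated
    }
  }
  list(mean_N_t = colMeans(N), N_t = N)
}
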