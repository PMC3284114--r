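#' Configuration for a training-strategy run
#'
#' Bundles the knobs of the active-learning driver: the strategy variant,
#' iteration budget, committee size, confidence margin and per-iteration
#' class quotas.
#'
#' Strategies: `cbal` (class-balanced active learning: quota-constrained
#' annotation of the eligible set), `ubal` (active learning, first-K eligible
#' samples regardless of class), `cbrl` (quota-constrained annotation of the
#' whole pool), `ubrl` (first-K random samples — the classic baseline), and
#' `full` (annotate the entire pool at once, the ceiling scenario).
#'
#' @param strategy one of `"cbal"`, `"ubal"`, `"cbrl"`, `"ubrl"`, `"full"`.
#' @param T maximum iterations (default 40).
#' @param tau confidence margin in \[0, 0.5\] (default 0.25).
#' @param k1_hat,k2_hat per-iteration minority/majority quotas for balanced
#'   strategies (default 1 and 1).
#' @param K batch size for unbalanced strategies; defaults to
#'   `k1_hat + k2_hat` and must equal it for balanced strategies.
#' @param m committee size (default 10).
#' @param delta stopping-criterion similarity threshold (default 0.02),
#'   applied post hoc via [stopping_iteration()].
#' @param bootstrap_size initial bootstrap training-set size (default 10).
#' @param eval_every evaluate the training set on a test pool every this many
#'   iterations (0 = only record composition; the final iteration is always
#'   evaluated when a test pool is supplied).
#' @param fallback fall back to whole-pool sampling when the eligible set is
#'   exhausted mid-iteration.
#' @param seed root seed; every stream in the run is derived from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(strategy = c("cbal", "ubal", "cbrl", "ubrl", "full"),
                       T = 40, tau = 0.25, k1_hat = 1, k2_hat = 1, K = NULL,
                       m = 10, delta = 0.02, bootstrap_size = 10,
                       eval_every = 0, fallback = TRUE, seed = 1L) {
  strategy <- match.arg(strategy)
  check_number(T, "T", lower = 1, integer = TRUE)
  check_number(tau, "tau", lower = 0, upper = 0.5)
  check_number(k1_hat, "k1_hat", lower = 0, integer = TRUE)
  check_number(k2_hat, "k2_hat", lower = 0, integer = TRUE)
  check_number(m, "m", lower = 2, integer = TRUE)
  check_number(delta, "delta", lower = 0)
  check_number(bootstrap_size, "bootstrap_size", lower = 2, integer = TRUE)
  check_number(eval_every, "eval_every", lower = 0, integer = TRUE)
  K <- K %||% (k1_hat + k2_hat)
  check_number(K, "K", lower = 1, integer = TRUE)
  balanced <- strategy %in% c("cbal", "cbrl")
  if (balanced && K != k1_hat + k2_hat)
    stop("for balanced strategies K must equal k1_hat + k2_hat",
         call. = FALSE)
  if (balanced && k1_hat + k2_hat < 1)
    stop("balanced strategies need k1_hat + k2_hat >= 1", call. = FALSE)
  structure(list(strategy = strategy, T = as.integer(T), tau = tau,
                 k1_hat = as.integer(k1_hat), k2_hat = as.integer(k2_hat),
                 K = as.integer(K), m = as.integer(m), delta = delta,
                 bootstrap_size = as.integer(bootstrap_size),
                 eval_every = as.integer(eval_every),
                 fallback = isTRUE(fallback), seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s: T = %d, tau = %g, quotas %d/%d (K = %d), m = %d, seed = %d\n",
    toupper(x$strategy), x$T, x$tau, x$k1_hat, x$k2_hat, x$K, x$m, x$seed))
  invisible(x)
}

#' Bootstrap an initial labeled training set
#'
#' Randomly annotates `size` samples; if the draw misses a class, further
#' samples are appended (each charged) until both classes are present, so
#' that a committee can always be trained.
#'
#' @param pool a `sample_pool`.
#' @param oracle an [annotation_oracle()].
#' @param size target bootstrap size.
#' @param seed integer seed.
#' @return list with `ids`, `labels`, `n_annotated` and `p0_hat` (the
#'   empirical minority fraction of the bootstrap set, the cost model's
#'   initial probability estimate).
#' @export
bootstrap_init <- function(pool, oracle, size = 10, seed = 1L) {
  stopifnot(inherits(pool, "sample_pool"))
  check_number(size, "size", lower = 2, integer = TRUE)
  if (length(unique(pool$labels)) < 2L)
    stop("cannot initialize: pool contains a single class", call. = FALSE)
  with_seed(seed, {
    ord <- sample(pool$ids)
    ids <- character(0); labels <- integer(0)
    for (id in ord) {
      if (length(ids) >= size && length(unique(labels)) >= 2L) break
      labels <- c(labels, annotate(oracle, id, iteration = 0L,
                                   source = "bootstrap"))
      ids <- c(ids, id)
    }
    if (length(unique(labels)) < 2L)
      stop("bootstrap failed: pool exhausted before both classes observed",
           call. = FALSE)
    list(ids = ids, labels = labels, n_annotated = length(ids),
         p0_hat = mean(labels == 1L))
  })
}

#' Run a training strategy
#'
#' The iterative driver: starting from a bootstrap training set, each
#' iteration (re)trains the committee, determines the candidate set (the
#' eligible set for active strategies, the whole unlabeled pool for random
#' ones), annotates a batch under the strategy's rule, and moves every
#' charged sample out of the unlabeled pool. The per-iteration trace records
#' training-set composition, annotation cost and (optionally) held-out
#' evaluation.
#'
#' For random-learning strategies the committee plays no part in selection,
#' so it is only trained at evaluated iterations and at the end. The `full`
#' strategy ignores the loop: it annotates the entire pool in one step.
#'
#' @param pool unlabeled training pool (a `sample_pool`; labels are hidden
#'   behind the oracle).
#' @param config a [run_config()].
#' @param test_pool optional held-out `sample_pool` for evaluation.
#' @param oracle annotation oracle; defaults to a fresh one over `pool`.
#' @return object of class `al_run`: list with `trace` (data.frame
#'   `t, n_minority, n_majority, n_train, N_t, L, surplus_used, fallback,
#'   eligible_size, accuracy, auc`), `labeled_ids`, `labeled_labels`,
#'   `committee`, `bootstrap`, `p0_hat`, `config`, `oracle`.
#' @export
run_strategy <- function(pool, config, test_pool = NULL,
                         oracle = annotation_oracle(pool)) {
  stopifnot(inherits(pool, "sample_pool"), inherits(config, "run_config"))
  if (!is.null(test_pool) && length(intersect(pool$ids, test_pool$ids)))
    stop("training and test pools must be disjoint", call. = FALSE)
  seeds <- derive_seeds(config$seed, config$T)
  strategy <- config$strategy

  if (strategy == "full") {
    labels <- vapply(pool$ids, annotate, integer(1), oracle = oracle,
                     iteration = 1L, source = "pool")
    committee <- train_committee(pool$features, labels, m = config$m,
                                 seed = seeds$committee[1])
    ev <- if (!is.null(test_pool))
      evaluate_training_set(pool$features, labels, test_pool,
                            seed = seeds$eval[1])
    trace <- data.frame(t = 1L, n_minority = sum(labels == 1L),
                        n_majority = sum(labels == 0L),
                        n_train = length(labels),
                        N_t = length(labels), L = length(labels),
                        surplus_used = 0L, fallback = FALSE,
                        eligible_size = NA_integer_,
                        accuracy = if (is.null(test_pool)) NA_real_
                                   else ev$accuracy,
                        auc = if (is.null(test_pool)) NA_real_ else ev$auc)
    return(structure(list(trace = trace, labeled_ids = pool$ids,
                          labeled_labels = unname(labels),
                          committee = committee,
                          bootstrap = NULL, p0_hat = mean(labels == 1L),
                          config = config, oracle = oracle),
                     class = "al_run"))
  }

  boot <- bootstrap_init(pool, oracle, config$bootstrap_size,
                         seed = seeds$bootstrap)
  labeled_ids <- boot$ids
  labeled_labels <- boot$labels
  unlabeled <- setdiff(pool$ids, labeled_ids)
  active <- strategy %in% c("cbal", "ubal")
  balanced <- strategy %in% c("cbal", "cbrl")
  committee <- NULL
  rows <- vector("list", config$T)
  L <- 0L
  truncated <- FALSE

  for (t in seq_len(config$T)) {
    if (!length(unlabeled)) { truncated <- TRUE; break }
    do_eval <- !is.null(test_pool) &&
      (t == config$T || (config$eval_every > 0 && t %% config$eval_every == 0))
    lab_x <- pool_subset(pool, labeled_ids)$features

    eligible_size <- NA_integer_
    if (active) {
      committee <- train_committee(lab_x, labeled_labels, m = config$m,
                                   seed = seeds$committee[t])
      elig <- find_eligible(committee, pool_subset(pool, unlabeled),
                            config$tau)
      cand <- elig$ids
      eligible_size <- length(cand)
      if (!length(cand)) cand <- unlabeled   # degrade to random sampling
    } else {
      cand <- unlabeled
    }

    res <- tryCatch({
      if (balanced) {
        min_class_query(cand, oracle, config$k1_hat, config$k2_hat,
                        pool_ids = unlabeled, fallback = config$fallback,
                        seed = seeds$query[t], iteration = t)
      } else {
        src <- if (active) "eligible" else "pool"
        with_seed(seeds$query[t], {
          draw <- utils::head(sample(cand), config$K)
          if (length(draw) < config$K && config$fallback) {
            extra <- sample(setdiff(unlabeled, cand))
            draw <- c(draw, utils::head(extra, config$K - length(draw)))
          }
          labs <- vapply(draw, annotate, integer(1), oracle = oracle,
                         iteration = t, source = src)
          structure(list(ids = draw, labels = unname(labs),
                         charged_ids = draw,
                         n_annotated = length(draw), surplus_used = 0L,
                         fallback_triggered = length(draw) > length(cand)),
                    class = "query_result")
        })
      }
    }, cbal_exhaustion_error = function(e) e)

    if (inherits(res, "cbal_exhaustion_error")) {
      truncated <- TRUE
      res <- res$partial
      if (!length(res$ids)) break
    }

    labeled_ids <- c(labeled_ids, res$ids)
    labeled_labels <- c(labeled_labels, res$labels)
    unlabeled <- setdiff(unlabeled, union(res$ids, res$charged_ids))
    L <- L + res$n_annotated

    acc <- auc <- NA_real_
    if (do_eval) {
      ev <- evaluate_training_set(
        pool_subset(pool, labeled_ids)$features, labeled_labels, test_pool,
        seed = seeds$eval[t])
      acc <- ev$accuracy; auc <- ev$auc
    }
    added <- labeled_labels[-seq_along(boot$labels)]
    rows[[t]] <- data.frame(
      t = t, n_minority = sum(added == 1L), n_majority = sum(added == 0L),
      n_train = length(labeled_labels), N_t = res$n_annotated, L = L,
      surplus_used = res$surplus_used, fallback = res$fallback_triggered,
      eligible_size = eligible_size, accuracy = acc, auc = auc)
    if (truncated) break
  }

  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  # returned model reflects the final training set for every strategy
  committee <- train_committee(pool_subset(pool, labeled_ids)$features,
                               labeled_labels, m = config$m,
                               seed = seeds$extra)
  structure(list(trace = trace, labeled_ids = labeled_ids,
                 labeled_labels = labeled_labels, committee = committee,
                 bootstrap = boot, p0_hat = boot$p0_hat, config = config,
                 oracle = oracle, truncated = truncated),
            class = "al_run")
}

#' @export
print.al_run <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<al_run> %s, %d iterations%s\n", toupper(x$config$strategy),
              if (is.null(tr)) 0L else nrow(tr),
              if (isTRUE(x$truncated)) " (pool exhausted)" else ""))
  cat(sprintf("  training set: %d samples (%d minority / %d majority)\n",
              length(x$labeled_ids), sum(x$labeled_labels == 1L),
              sum(x$labeled_labels == 0L)))
  cat(sprintf("  annotation cost: %d oracle calls (bootstrap %d + L %d)\n",
              x$oracle$calls,
              if (is.null(x$bootstrap)) 0L else x$bootstrap$n_annotated,
              if (is.null(tr)) 0L else utils::tail(tr$L, 1)))
  invisible(x)
}

#' @export
summary.al_run <- function(object, ...) {
  tr <- object$trace
  ev <- tr[!is.na(tr$auc), , drop = FALSE]
  out <- list(
    strategy = object$config$strategy,
    iterations = nrow(tr),
    train_size = length(object$labeled_ids),
    n_minority = sum(object$labeled_labels == 1L),
    n_majority = sum(object$labeled_labels == 0L),
    total_cost = if (nrow(tr)) utils::tail(tr$L, 1) else 0L,
    oracle_calls = object$oracle$calls,
    p0_hat = object$p0_hat,
    final_accuracy = if (nrow(ev)) utils::tail(ev$accuracy, 1) else NA_real_,
    final_auc = if (nrow(ev)) utils::tail(ev$auc, 1) else NA_real_,
    stopping_t = if (sum(!is.na(tr$accuracy)) >= 2)
      stopping_iteration(tr$accuracy[!is.na(tr$accuracy)],
                         object$config$delta) else NA_integer_)
  class(out) <- "summary.al_run"
  out
}

#' @export
print.summary.al_run <- function(x, ...) {
  cat(sprintf("%s run: %d iterations, training set %d (%d/%d), cost L = %d (+%d bootstrap)\n",
              toupper(x$strategy), x$iterations, x$train_size, x$n_minority,
              x$n_majority, x$total_cost, x$oracle_calls - x$total_cost))
  if (!is.na(x$final_auc))
    cat(sprintf("final evaluation: accuracy %.4f, AUC %.4f; stopping iteration %s\n",
                x$final_accuracy, x$final_auc,
                ifelse(is.na(x$stopping_t), "-", x$stopping_t)))
  invisible(x)
}

#' @export
plot.al_run <- function(x, which = c("cost", "performance"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (which == "cost") {
    graphics::plot(tr$t, tr$N_t, type = "h", lwd = 2, xlab = "iteration t",
                   ylab = expression(N[t]),
                   main = sprintf("%s annotation cost per iteration",
                                  toupper(x$config$strategy)), ...)
  } else {
    ev <- tr[!is.na(tr$auc), , drop = FALSE]
    if (!nrow(ev)) stop("no evaluated iterations in this run", call. = FALSE)
    graphics::plot(ev$t, ev$auc, type = "b", ylim = c(0, 1),
                   xlab = "iteration t", ylab = "AUC / accuracy",
                   main = toupper(x$config$strategy), ...)
    graphics::lines(ev$t, ev$accuracy, type = "b", col = 2, pch = 2)
    graphics::legend("bottomright", c("AUC", "accuracy"), col = c(1, 2),
                     pch = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Stopping criterion over an accuracy sequence
#'
#' The smallest iteration `t >= 1` (1-based, comparing to the previous
#' iteration) at which accuracy has stabilized:
#' `|A_t - A_{t-1}| <= delta`. Returns the sequence length if no iteration
#' satisfies the criterion (exhaustion).
#'
#' @param accuracies numeric vector of per-iteration accuracies (length
#'   >= 2).
#' @param delta similarity threshold (>= 0).
#' @return integer iteration index.
#' @export
stopping_iteration <- function(accuracies, delta) {
  if (!is.numeric(accuracies) || length(accuracies) < 2L)
    stop("need an accuracy sequence of length >= 2", call. = FALSE)
  check_number(delta, "delta", lower = 0)
  # positions are t = 0 .. n-1; diff element i is |A_i - A_{i-1}|
  hit <- which(abs(diff(accuracies)) <= delta)
  if (length(hit)) hit[1] else length(accuracies)
}

#' Compare training strategies over replicated trials
#'
#' The experiment harness: for each trial, a fresh pool is generated from
#' `spec` (trial-specific seed), split at random into train/test, and every
#' strategy is run with shared per-trial seeds so strategies face identical
#' conditions. Results are returned in long format, one row per
#' (trial, strategy, iteration).
#'
#' @param spec a [pool_spec()] describing the synthetic pool to draw each
#'   trial from.
#' @param strategies character vector of strategy names.
#' @param n_trials number of independent trials (>= 1).
#' @param test_fraction fraction of each trial's pool held out for testing.
#' @param config_args named list of [run_config()] arguments shared by all
#'   strategies (e.g. `T`, `tau`, quotas, `eval_every`).
#' @param seed root seed for the whole comparison.
#' @return object of class `al_comparison`: data.frame with columns `trial`,
#'   `strategy` and the per-iteration trace columns.
#' @export
compare_strategies <- function(spec, strategies = c("cbal", "ubal", "cbrl",
                                                    "ubrl", "full"),
                               n_trials = 10, test_fraction = 0.107,
                               config_args = list(), seed = 1L) {
  stopifnot(inherits(spec, "pool_spec"))
  check_number(n_trials, "n_trials", lower = 1, integer = TRUE)
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            2L * n_trials))
  out <- vector("list", n_trials * length(strategies))
  k <- 0L
  for (trial in seq_len(n_trials)) {
    tspec <- spec
    tspec$seed <- trial_seeds[trial]
    pool <- make_feature_pool(tspec)
    parts <- split_pool(pool, test_fraction, seed = trial_seeds[trial])
    for (s in strategies) {
      cfg <- do.call(run_config, c(list(strategy = s,
                                        seed = trial_seeds[n_trials + trial]),
                                   config_args))
      run <- run_strategy(parts$train, cfg, test_pool = parts$test)
      k <- k + 1L
      out[[k]] <- cbind(trial = trial, strategy = s, run$trace)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("al_comparison", "data.frame")
  res
}

#' @export
summary.al_comparison <- function(object, ...) {
  df <- as.data.frame(object)
  ev <- df[!is.na(df$auc), , drop = FALSE]
  agg <- function(d, v)
    stats::aggregate(d[[v]], by = list(strategy = d$strategy, t = d$t),
                     FUN = function(z) c(mean = mean(z), sd = stats::sd(z)))
  cost <- agg(df, "N_t")
  out <- data.frame(strategy = cost$strategy, t = cost$t,
                    mean_N_t = cost$x[, "mean"], sd_N_t = cost$x[, "sd"])
  if (nrow(ev)) {
    perf <- agg(ev, "auc"); acc <- agg(ev, "accuracy")
    perf_df <- data.frame(strategy = perf$strategy, t = perf$t,
                          mean_auc = perf$x[, "mean"],
                          sd_auc = perf$x[, "sd"],
                          mean_accuracy = acc$x[, "mean"])
    out <- merge(out, perf_df, by = c("strategy", "t"), all.x = TRUE)
  }
  out[order(out$strategy, out$t), ]
}

#' @export
plot.al_comparison <- function(x, metric = "auc", ...) {
  ev <- as.data.frame(x)
  ev <- ev[!is.na(ev[[metric]]), , drop = FALSE]
  if (!nrow(ev)) stop("no evaluated iterations to plot", call. = FALSE)
  agg <- stats::aggregate(ev[[metric]],
                          by = list(strategy = ev$strategy, t = ev$t), mean)
  strategies <- unique(agg$strategy)
  graphics::plot(NULL, xlim = range(agg$t), ylim = range(agg$x),
                 xlab = "iteration t", ylab = metric,
                 main = "Strategy comparison", ...)
  for (i in seq_along(strategies)) {
    sub <- agg[agg$strategy == strategies[i], ]
    graphics::lines(sub$t, sub$x, col = i, lwd = 2, type = "b", pch = i)
  }
  graphics::legend("bottomright", toupper(strategies),
                   col = seq_along(strategies), pch = seq_along(strategies),
                   lwd = 2, bty = "n")
  invisible(x)
}
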