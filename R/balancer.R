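#' Simulated annotation oracle with cost accounting
#'
#' Wraps the hidden ground-truth labels of a pool behind a pay-per-call
#' interface. Every *distinct* sample is charged exactly once, ever; samples
#' annotated while hunting for a scarce class but not needed for the current
#' batch are kept in a per-class cache and consumed free of charge at later
#' iterations. An audit log records every annotation event.
#'
#' @param pool a `sample_pool` (its labels become the oracle's label source),
#'   or a named integer vector of labels (1 = minority, 0 = majority).
#' @return object of class `annotation_oracle` (an environment) with fields
#'   `calls` (cumulative distinct annotations charged), `cache` (annotated
#'   but unused ids per class) and `log` (the audit trail).
#' @export
annotation_oracle <- function(pool) {
  labels <- if (inherits(pool, "sample_pool")) {
    stats::setNames(pool$labels, pool$ids)
  } else {
    stopifnot(!is.null(names(pool)))
    stats::setNames(as.integer(pool), names(pool))
  }
  e <- new.env(parent = emptyenv())
  e$labels <- labels
  e$calls <- 0L
  e$charged <- new.env(parent = emptyenv())
  e$cache <- list(minority = character(0), majority = character(0))
  e$log <- list()
  class(e) <- "annotation_oracle"
  e
}

#' @export
print.annotation_oracle <- function(x, ...) {
  cat(sprintf("<annotation_oracle> %d labels, %d charged calls, cache %d/%d\n",
              length(x$labels), x$calls, length(x$cache$minority),
              length(x$cache$majority)))
  invisible(x)
}

oracle_is_charged <- function(oracle, id)
  exists(id, envir = oracle$charged, inherits = FALSE)

oracle_log <- function(oracle, iteration, id, class, charged, source) {
  oracle$log[[length(oracle$log) + 1L]] <-
    data.frame(iteration = iteration, sample_id = id, class = class,
               charged = charged, source = source)
  invisible(NULL)
}

#' Annotation audit log
#'
#' One row per annotation event: `iteration, sample_id, class, charged,
#' source` with source one of `eligible`, `cache`, `fallback`, `bootstrap`,
#' `pool`.
#'
#' @param oracle an [annotation_oracle()].
#' @return data.frame.
#' @export
annotation_log <- function(oracle) {
  if (!length(oracle$log))
    return(data.frame(iteration = integer(0), sample_id = character(0),
                      class = integer(0), charged = logical(0),
                      source = character(0)))
  do.call(rbind, oracle$log)
}

#' Annotate one sample, charging its cost
#'
#' Reveals the true class of a sample and increments the oracle's call
#' counter. Attempting to charge the same sample twice is an accounting bug
#' and raises an internal error.
#'
#' @param oracle an [annotation_oracle()].
#' @param id sample id.
#' @param iteration,source bookkeeping fields for the audit log.
#' @return the true class label (1 = minority, 0 = majority).
#' @export
annotate <- function(oracle, id, iteration = NA_integer_, source = "pool") {
  stopifnot(inherits(oracle, "annotation_oracle"))
  if (!id %in% names(oracle$labels))
    stop("unknown sample id: ", id, call. = FALSE)
  if (oracle_is_charged(oracle, id))
    stop("internal accounting error: sample ", id, " charged twice",
         call. = FALSE)
  assign(id, TRUE, envir = oracle$charged)
  oracle$calls <- oracle$calls + 1L
  lab <- unname(oracle$labels[[id]])
  oracle_log(oracle, iteration, id, lab, TRUE, source)
  lab
}

cache_take <- function(oracle, class, k, iteration) {
  slot <- if (class == 1L) "minority" else "majority"
  take <- utils::head(oracle$cache[[slot]], k)
  oracle$cache[[slot]] <- setdiff(oracle$cache[[slot]], take)
  for (id in take) oracle_log(oracle, iteration, id, class, FALSE, "cache")
  take
}

cache_put <- function(oracle, class, id) {
  slot <- if (class == 1L) "minority" else "majority"
  oracle$cache[[slot]] <- c(oracle$cache[[slot]], id)
}

exhaustion_error <- function(result, msg) {
  stop(structure(class = c("cbal_exhaustion_error", "error", "condition"),
                 list(message = msg, call = NULL, partial = result)))
}

#' Class-ratio-constrained annotation of eligible samples
#'
#' The quota-filling query at the heart of class-balanced training: draw
#' eligible samples uniformly at random without replacement, annotate each,
#' keep it if its class quota (`k1_hat` minority / `k2_hat` majority) is
#' still open, and cache it for future iterations otherwise — the cost is
#' already sunk. Cached annotations from earlier iterations are consumed
#' first, free of charge. If the eligible set is exhausted before the quotas
#' fill and `fallback` is on, drawing continues from the rest of the
#' unlabeled pool (logged as such).
#'
#' @param eligible an `eligible_set` or character vector of candidate ids.
#' @param oracle an [annotation_oracle()].
#' @param k1_hat,k2_hat per-iteration class quotas (k1_hat + k2_hat > 0).
#' @param pool_ids all currently unlabeled ids, used when falling back.
#' @param fallback continue drawing from `pool_ids` when the eligible set is
#'   exhausted (default TRUE).
#' @param seed optional seed for the draw order; `NULL` uses the current RNG
#'   stream.
#' @param iteration recorded in the audit log.
#' @return object of class `query_result`: `ids`, `labels` (quota-exact
#'   batch), `n_annotated` (new oracle calls, the iteration cost N_t),
#'   `surplus_used` (batch slots served from cache) and `fallback_triggered`.
#'   If the quotas cannot be filled even with fallback, an error of class
#'   `cbal_exhaustion_error` carrying the partial batch is raised.
#' @export
min_class_query <- function(eligible, oracle, k1_hat, k2_hat,
                            pool_ids = NULL, fallback = TRUE, seed = NULL,
                            iteration = NA_integer_) {
  ids <- if (inherits(eligible, "eligible_set")) eligible$ids else
    as.character(eligible)
  check_number(k1_hat, "k1_hat", lower = 0, integer = TRUE)
  check_number(k2_hat, "k2_hat", lower = 0, integer = TRUE)
  if (k1_hat + k2_hat <= 0)
    stop("k1_hat + k2_hat must be positive", call. = FALSE)

  run <- function() {
    need <- c(`0` = as.integer(k2_hat), `1` = as.integer(k1_hat))
    batch_ids <- character(0); batch_labels <- integer(0)
    charged_ids <- character(0)
    n_annotated <- 0L; surplus_used <- 0L; fb <- FALSE
    for (cls in c(1L, 0L)) {                      # consume cache first
      k <- need[[as.character(cls)]]
      if (k > 0L) {
        got <- cache_take(oracle, cls, k, iteration)
        if (length(got)) {
          batch_ids <- c(batch_ids, got)
          batch_labels <- c(batch_labels, rep(cls, length(got)))
          surplus_used <- surplus_used + length(got)
          need[[as.character(cls)]] <- k - length(got)
        }
      }
    }
    draw_from <- function(cand, source) {
      cand <- if (length(cand)) sample(cand) else cand
      for (id in cand) {
        if (sum(need) == 0L) break
        if (oracle_is_charged(oracle, id)) next    # cached or already labeled
        lab <- annotate(oracle, id, iteration, source)
        charged_ids <<- c(charged_ids, id)
        n_annotated <<- n_annotated + 1L
        if (need[[as.character(lab)]] > 0L) {
          batch_ids <<- c(batch_ids, id)
          batch_labels <<- c(batch_labels, lab)
          need[[as.character(lab)]] <<- need[[as.character(lab)]] - 1L
        } else cache_put(oracle, lab, id)
      }
    }
    draw_from(ids, "eligible")
    if (sum(need) > 0L && fallback && !is.null(pool_ids)) {
      rest <- setdiff(pool_ids, ids)
      if (length(rest)) { fb <- TRUE; draw_from(rest, "fallback") }
    }
    res <- structure(list(ids = batch_ids, labels = batch_labels,
                          charged_ids = charged_ids,
                          n_annotated = n_annotated,
                          surplus_used = surplus_used,
                          fallback_triggered = fb),
                     class = "query_result")
    if (sum(need) > 0L)
      exhaustion_error(res, sprintf(
        "candidate pool exhausted with quotas unfilled (missing %d minority, %d majority)",
        need[["1"]], need[["0"]]))
    res
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Random (baseline) annotation query
#'
#' `balanced = TRUE` runs [min_class_query()] with the whole pool eligible
#' (class-balanced random learning); `balanced = FALSE` annotates the first
#' `K` randomly drawn samples regardless of class, so the iteration cost is
#' always exactly `K`.
#'
#' @param pool_ids unlabeled candidate ids.
#' @param oracle an [annotation_oracle()].
#' @param K batch size for the unbalanced mode.
#' @param balanced use class quotas?
#' @param k1_hat,k2_hat quotas when `balanced = TRUE`.
#' @param seed optional seed.
#' @param iteration recorded in the audit log.
#' @return a `query_result` (see [min_class_query()]).
#' @export
random_query <- function(pool_ids, oracle, K, balanced = FALSE,
                         k1_hat = NULL, k2_hat = NULL, seed = NULL,
                         iteration = NA_integer_) {
  if (balanced)
    return(min_class_query(pool_ids, oracle, k1_hat, k2_hat,
                           pool_ids = pool_ids, fallback = FALSE,
                           seed = seed, iteration = iteration))
  check_number(K, "K", lower = 1, integer = TRUE)
  run <- function() {
    cand <- pool_ids[!vapply(pool_ids, oracle_is_charged, logical(1),
                             oracle = oracle)]
    if (length(cand)) cand <- sample(cand)
    take <- utils::head(cand, K)
    labs <- vapply(take, annotate, integer(1), oracle = oracle,
                   iteration = iteration, source = "pool")
    res <- structure(list(ids = take, labels = unname(labs),
                          charged_ids = take,
                          n_annotated = length(take), surplus_used = 0L,
                          fallback_triggered = FALSE),
                     class = "query_result")
    if (length(take) < K)
      exhaustion_error(res, sprintf("pool exhausted: %d of %d drawn",
                                    length(take), K))
    res
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf(
    "<query_result> batch %d (%d minority / %d majority), N_t = %d, cache used = %d%s\n",
    length(x$ids), sum(x$labels == 1L), sum(x$labels == 0L), x$n_annotated,
    x$surplus_used, if (x$fallback_triggered) ", fallback" else ""))
  invisible(x)
}
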