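#' Negative-binomial annotation-cost probability
#'
#' Annotating randomly drawn samples is a sequence of Bernoulli trials in
#' which "success" is observing a minority-class sample (probability `p`).
#' The number of annotations needed to collect `k1_hat` minority samples is
#' therefore negative-binomial: the probability that the `k1_hat`-th minority
#' sample arrives exactly on the `n`-th annotation is
#' `choose(n-1, k1_hat-1) p^k1_hat (1-p)^(n-k1_hat)`.
#' With `cumulative = TRUE` the function returns the probability of seeing at
#' least `k1_hat` minority samples within `n` annotations.
#'
#' @param k1_hat number of minority samples sought (>= 1).
#' @param n number of annotations (vectorized).
#' @param p probability of observing a minority sample, in \[0, 1\].
#' @param cumulative return `P(cost <= n)` instead of the pmf.
#' @return numeric vector of probabilities; 0 for `n < k1_hat`.
#' @export
negbin_prob <- function(k1_hat, n, p, cumulative = FALSE) {
  check_number(k1_hat, "k1_hat", lower = 1, integer = TRUE)
  check_number(p, "p", lower = 0, upper = 1)
  stopifnot(is.numeric(n), all(n == round(n)))
  if (p == 0) return(rep(0, length(n)))
  out <- if (cumulative) stats::pnbinom(n - k1_hat, size = k1_hat, prob = p)
         else stats::dnbinom(n - k1_hat, size = k1_hat, prob = p)
  out[n < k1_hat] <- 0
  out
}

#' Predict the number of annotations needed for the minority quota
#'
#' Cost prediction at model confidence `p_delta`: the default `quantile` mode
#' returns the smallest `N` such that at least `k1_hat` minority samples are
#' observed within `N` annotations with probability `>= p_delta` (the CDF
#' quantile of the negative binomial). The `as_printed` mode instead returns
#' the `x` in `[k1_hat, pool_size]` whose pmf value is closest to `p_delta`
#' (smallest-x tie-break), the literal matching rule of the printed
#' formulation. Either way the result is clamped to `[k1_hat, pool_size]`:
#' the best case needs exactly `k1_hat` annotations, the worst annotates the
#' whole pool.
#'
#' @param p minority-observation probability.
#' @param k1_hat minority quota (>= 1).
#' @param p_delta model confidence in (0, 1); default 0.95.
#' @param pool_size size of the unlabeled pool (upper bound).
#' @param mode `"quantile"` (default) or `"as_printed"`.
#' @return integer number of annotations.
#' @export
predict_annotations <- function(p, k1_hat, p_delta = 0.95, pool_size,
                                mode = c("quantile", "as_printed")) {
  mode <- match.arg(mode)
  check_number(p, "p", lower = 0, upper = 1)
  check_number(k1_hat, "k1_hat", lower = 1, integer = TRUE)
  check_number(p_delta, "p_delta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(pool_size, "pool_size", lower = 1, integer = TRUE)
  if (pool_size < k1_hat)
    stop("infeasible: pool_size < k1_hat", call. = FALSE)
  if (p == 0) {
    warning("p = 0: minority samples unobservable; returning pool_size",
            call. = FALSE)
    return(as.integer(pool_size))
  }
  n <- if (mode == "quantile") {
    k1_hat + stats::qnbinom(p_delta, size = k1_hat, prob = p)
  } else {
    xs <- seq.int(k1_hat, pool_size)
    xs[which.min(abs(p_delta - negbin_prob(k1_hat, xs, p)))]
  }
  as.integer(min(max(n, k1_hat), pool_size))
}

#' Update the minority-observation probability between iterations
#'
#' After an iteration that spent `n_t` annotations and moved `k1_hat`
#' minority samples into the training set, the probability of observing a
#' minority sample among the remaining candidates is
#' `(k1_t - k1_hat) / (k1_t + k2_t - n_t)`, where `k1_t`/`k2_t` are the
#' minority/majority counts among the candidates at the start of the
#' iteration. When the minority class is exhausted (`k1_t == k1_hat`) the
#' probability is 0; when the whole candidate set was annotated the update is
#' undefined and an error is raised.
#'
#' @param k1_t,k2_t class counts among the candidates at iteration t.
#' @param k1_hat minority quota removed at iteration t.
#' @param n_t annotations spent at iteration t.
#' @return updated probability in \[0, 1\].
#' @export
update_probability <- function(k1_t, k2_t, k1_hat, n_t) {
  check_number(k1_t, "k1_t", lower = 0)
  check_number(k2_t, "k2_t", lower = 0)
  check_number(k1_hat, "k1_hat", lower = 0)
  check_number(n_t, "n_t", lower = 0)
  if (k1_t < k1_hat)
    stop("k1_t < k1_hat: more minority samples removed than available",
         call. = FALSE)
  denom <- k1_t + k2_t - n_t
  if (denom <= 0)
    stop("undefined probability: candidate set fully annotated ",
         "(k1_t + k2_t <= n_t)", call. = FALSE)
  pr <- (k1_t - k1_hat) / denom
  if (pr > 1)
    stop("model inconsistency: updated probability exceeds 1", call. = FALSE)
  pr
}

#' Total training cost
#'
#' Sum of the per-iteration annotation counts `N_t`.
#'
#' @param trace numeric vector of per-iteration annotation counts.
#' @return total cost L.
#' @export
total_cost <- function(trace) {
  stopifnot(is.numeric(trace))
  if (any(trace < 0)) stop("negative per-iteration cost", call. = FALSE)
  sum(trace)
}

#' Predicted per-iteration cost curve
#'
#' Iterates the cost prediction and the probability update for `T`
#' iterations, modeling a class-balancing run on a finite pool. Two
#' prediction statistics are available: `"mean"` reports the expected
#' per-iteration cost `k1_hat / p_t` (the negative-binomial mean), the right
#' quantity to compare with trial-averaged observed costs; `"quantile"`
#' reports [predict_annotations()] at confidence `p_delta`, an upper
#' percentile suitable for budgeting. With
#' `update_source = "oracle_counts"` the class counts entering the update
#' are the true remaining pool composition (simulation mode, requiring
#' `n1_0`); with `"running_estimate"` they are estimated from the current
#' probability itself (deployment mode, where true counts are unobservable).
#'
#' @param p0 initial minority-observation probability.
#' @param k1_hat,k2_hat per-iteration class quotas.
#' @param T number of iterations.
#' @param pool_size initial unlabeled pool size.
#' @param p_delta model confidence for the quantile statistic.
#' @param statistic `"mean"` or `"quantile"`.
#' @param mode passed to [predict_annotations()] for the quantile statistic.
#' @param update_source `"oracle_counts"` or `"running_estimate"`.
#' @param n1_0 true initial minority count (defaults to
#'   `round(p0 * pool_size)`).
#' @return object of class `cost_curve`: data.frame with columns `t`, `p_t`,
#'   `predicted_n`, `cumulative`.
#' @export
predict_cost_curve <- function(p0, k1_hat, k2_hat, T, pool_size,
                               p_delta = 0.95,
                               statistic = c("mean", "quantile"),
                               mode = "quantile",
                               update_source = c("oracle_counts",
                                                 "running_estimate"),
                               n1_0 = round(p0 * pool_size)) {
  statistic <- match.arg(statistic)
  update_source <- match.arg(update_source)
  check_number(p0, "p0", lower = 0, upper = 1)
  check_number(T, "T", lower = 1, integer = TRUE)
  check_number(pool_size, "pool_size", lower = 1, integer = TRUE)

  p <- p0
  n1 <- n1_0
  remaining <- pool_size
  rows <- vector("list", T)
  cum <- 0
  for (t in seq_len(T)) {
    pred <- if (p == 0) {
      remaining
    } else if (statistic == "mean") {
      k1_hat / p
    } else {
      predict_annotations(p, k1_hat, p_delta, max(remaining, k1_hat),
                          mode = mode)
    }
    # an iteration can never need fewer annotations than its batch size
    pred <- min(max(pred, k1_hat + k2_hat), remaining)
    cum <- cum + pred
    rows[[t]] <- data.frame(t = t, p_t = p, predicted_n = pred,
                            cumulative = cum)
    # advance the modeled pool: k1_hat minority leave, plus as many of the
    # predicted surplus annotations as the majority class can supply
    k1_t <- if (update_source == "oracle_counts") n1 else p * remaining
    k2_t <- remaining - k1_t
    removed <- k1_hat + min(pred - k1_hat, k2_t)
    if (k1_t < k1_hat || k1_t + k2_t - removed <= 0) {
      rows <- rows[seq_len(t)]
      break
    }
    p <- update_probability(k1_t, k2_t, k1_hat, removed)
    n1 <- n1 - k1_hat
    remaining <- remaining - removed
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' @export
plot.cost_curve <- function(x, observed = NULL, ...) {
  graphics::plot(x$t, x$predicted_n, type = "l", lwd = 2,
                 xlab = "iteration t", ylab = expression(N[t]),
                 main = "Predicted annotation cost per iteration", ...)
  if (!is.null(observed)) {
    graphics::lines(seq_along(observed), observed, col = 2, lty = 2)
    graphics::legend("topleft", c("predicted", "observed"),
                     col = c(1, 2), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
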