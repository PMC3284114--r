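# brute-force oracle: probability that the k-th minority arrives exactly on
# annotation n, by enumerating every binary annotation sequence of length n
enumerate_negbin <- function(k, n, p) {
  if (n < k) return(0)
  if (n == 1) return(if (k == 1) p else 0)
  grid <- as.matrix(expand.grid(rep(list(0:1), n - 1)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    seqn <- c(grid[r, ], 1)                     # last draw is the k-th success
    if (sum(seqn) == k)
      total <- total + prod(ifelse(seqn == 1, p, 1 - p))
  }
  total
}

test_that("negbin_prob matches exhaustive sequence enumeration", {
  for (p in c(0.3, 0.5)) for (k in c(1, 2, 3)) for (n in k:10) {
    expect_equal(negbin_prob(k, n, p), enumerate_negbin(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("negbin_prob handles boundary cases", {
  expect_equal(negbin_prob(1, 1, 0.25), 0.25)
  expect_equal(negbin_prob(3, 3, 1), 1)          # certain success at n = k
  expect_equal(negbin_prob(3, 5, 1), 0)
  expect_equal(negbin_prob(2, 1, 0.5), 0)        # n < k impossible
  expect_equal(negbin_prob(1, 5, 0), 0)
  expect_error(negbin_prob(1, 1, 1.5), "p")
  expect_error(negbin_prob(0, 1, 0.5), "k1_hat")
  # pmf sums to 1: partial sums converge by n = k + 50/p
  for (p in c(0.1, 0.3)) for (k in c(1, 4)) {
    ns <- k:(k + ceiling(50 / p))
    expect_equal(sum(negbin_prob(k, ns, p)), 1, tolerance = 1e-9)
  }
  # cumulative form agrees with summed pmf
  expect_equal(negbin_prob(2, 10, 0.3, cumulative = TRUE),
               sum(negbin_prob(2, 2:10, 0.3)), tolerance = 1e-12)
})

test_that("quantile predictions equal the closed form for a single success", {
  for (p in c(0.02, 0.04, 0.1, 0.3)) for (pd in c(0.5, 0.8, 0.95, 0.99)) {
    expect_equal(predict_annotations(p, 1, pd, 10^6),
                 ceiling(log(1 - pd) / log(1 - p)))
  }
  expect_equal(predict_annotations(0.04, 1, 0.95, 10^6), 74)
})

test_that("predictions respect bounds, monotonicity and degenerate inputs", {
  expect_equal(predict_annotations(1, 3, 0.99, 100), 3)   # lower bound
  expect_equal(predict_annotations(0.001, 1, 0.999, 50), 50)  # clamped
  expect_warning(n0 <- predict_annotations(0, 1, 0.95, 80), "p = 0")
  expect_equal(n0, 80)
  expect_error(predict_annotations(0.5, 10, 0.95, 5), "infeasible")
  ps <- seq(0.05, 0.5, by = 0.05)
  np <- vapply(ps, predict_annotations, numeric(1), k1_hat = 2,
               p_delta = 0.9, pool_size = 10^6)
  expect_true(all(diff(np) <= 0))               # nonincreasing in p
  ks <- 1:6
  nk <- vapply(ks, function(k) predict_annotations(0.1, k, 0.9, 10^6),
               numeric(1))
  expect_true(all(diff(nk) >= 0))               # nondecreasing in k1_hat
  pds <- c(0.5, 0.7, 0.9, 0.99)
  nd <- vapply(pds, function(pd) predict_annotations(0.1, 2, pd, 10^6),
               numeric(1))
  expect_true(all(diff(nd) >= 0))               # nondecreasing in p_delta
})

test_that("the literal pmf-matching mode minimizes |P_delta - pmf|", {
  p <- 0.2; k <- 2; pd <- 0.1; pool <- 200
  xs <- k:pool
  target <- xs[which.min(abs(pd - negbin_prob(k, xs, p)))]
  expect_equal(predict_annotations(p, k, pd, pool, mode = "as_printed"),
               target)
})

test_that("probability updates follow the remaining-pool arithmetic", {
  expect_equal(update_probability(10, 90, 5, 50), 0.1)
  expect_equal(update_probability(5, 90, 5, 20), 0)   # minority exhausted
  expect_error(update_probability(10, 40, 5, 50), "undefined")
  expect_error(update_probability(3, 90, 5, 10), "k1_t")
})

test_that("total cost sums iteration costs and validates", {
  expect_equal(total_cost(c(2, 2, 2)), 6)
  expect_equal(total_cost(numeric(0)), 0)
  expect_error(total_cost(c(2, -1)), "negative")
})

test_that("cost curves are stationary, bounded and ratio-monotone", {
  # certain balance: every iteration predicted at the batch size
  flat <- predict_cost_curve(1, 1, 1, T = 5, pool_size = 100)
  expect_equal(flat$predicted_n, rep(2, 5))
  # near-constant p on a huge pool: constant quantile predictions
  const <- predict_cost_curve(0.04, 1, 1, T = 40, pool_size = 10^6,
                              statistic = "quantile", p_delta = 0.95)
  expect_equal(unique(const$predicted_n), 74)
  expect_equal(const$cumulative, cumsum(const$predicted_n))
  # richer minority quotas cost more at every iteration (20% vs 80% of K=10)
  lo <- predict_cost_curve(0.04, 2, 8, T = 20, pool_size = 11242,
                           statistic = "quantile")
  hi <- predict_cost_curve(0.04, 8, 2, T = 20, pool_size = 11242,
                           statistic = "quantile")
  expect_true(all(hi$predicted_n >= lo$predicted_n))
  expect_true(all(flat$predicted_n >= 2 &
                    const$predicted_n <= 10^6))
})

test_that("mean-statistic predictions recover simulated balancing costs", {
  # E[N_t] = k1_hat / p for the minority-quota negative binomial
  curve <- predict_cost_curve(0.5, 1, 1, T = 1, pool_size = 10^6,
                              statistic = "mean")
  expect_equal(curve$predicted_n[1], 2)          # max(1/0.5, K = 2)
  curve2 <- predict_cost_curve(0.04, 1, 1, T = 1, pool_size = 10^6,
                               statistic = "mean")
  expect_equal(curve2$predicted_n[1], 25)
})
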