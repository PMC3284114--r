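test_that("bootstrap initialization guarantees both classes and charges cost", {
  pool <- tiny_pool(n = 300, frac = 0.04, seed = 3)   # 12 minority
  oracle <- annotation_oracle(pool)
  boot <- bootstrap_init(pool, oracle, size = 10, seed = 21)
  expect_gte(boot$n_annotated, 10)
  expect_true(all(c(0L, 1L) %in% boot$labels))
  expect_equal(oracle$calls, boot$n_annotated)
  expect_equal(boot$p0_hat, mean(boot$labels == 1L))
  # single-class pool cannot initialize
  mono <- pool
  mono$labels <- rep(0L, length(mono$labels))
  expect_error(bootstrap_init(mono, annotation_oracle(mono), 10, 1),
               "single class")
})

test_that("run_config validates strategy-specific constraints", {
  expect_s3_class(run_config("cbal", T = 5), "run_config")
  expect_error(run_config("cbal", K = 5, k1_hat = 1, k2_hat = 1), "K must")
  expect_error(run_config("ubrl", T = 0), "T")
  expect_error(run_config("cbal", tau = 0.7), "tau")
})

test_that("balanced strategies keep the added class ratio exact every iteration", {
  for (s in c("cbal", "cbrl")) {
    pool <- tiny_pool(n = 400, frac = 0.1, seed = 17)
    run <- run_strategy(pool, run_config(s, T = 8, k1_hat = 1, k2_hat = 1,
                                         seed = 5))
    tr <- run$trace
    expect_equal(tr$n_minority, tr$t * 1L)
    expect_equal(tr$n_majority, tr$t * 1L)
    expect_equal(tr$n_train,
                 run$bootstrap$n_annotated + tr$t * 2L)
    expect_equal(tr$L, cumsum(tr$N_t))
  }
})

test_that("runs are deterministic end to end under a shared seed", {
  pool <- tiny_pool(n = 300, frac = 0.1, seed = 23)
  cfg <- run_config("cbal", T = 6, seed = 31)
  r1 <- run_strategy(pool, cfg)
  r2 <- run_strategy(pool, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$labeled_ids, r2$labeled_ids)
  expect_identical(annotation_log(r1$oracle), annotation_log(r2$oracle))
})

test_that("tau = 0.5 makes CBAL identical to CBRL under shared seeds", {
  pool <- tiny_pool(n = 500, frac = 0.08, seed = 2)
  a <- run_strategy(pool, run_config("cbal", T = 6, tau = 0.5, seed = 42))
  b <- run_strategy(pool, run_config("cbrl", T = 6, seed = 42))
  la <- annotation_log(a$oracle); lb <- annotation_log(b$oracle)
  expect_identical(la$sample_id, lb$sample_id)
  expect_identical(a$labeled_ids, b$labeled_ids)
  expect_identical(a$trace$N_t, b$trace$N_t)
})

test_that("unbalanced strategies charge exactly K per iteration", {
  pool <- tiny_pool(n = 300, frac = 0.1, seed = 11)
  for (s in c("ubal", "ubrl")) {
    run <- run_strategy(pool, run_config(s, T = 5, K = 2, seed = 7))
    expect_equal(run$trace$N_t, rep(2L, 5))
    expect_equal(run$trace$n_minority + run$trace$n_majority,
                 run$trace$t * 2L)
  }
})

test_that("the full strategy annotates the whole pool at cost |pool|", {
  pool <- tiny_pool(n = 120, frac = 0.2, seed = 13)
  run <- run_strategy(pool, run_config("full", seed = 1))
  expect_setequal(run$labeled_ids, pool$ids)
  expect_equal(run$trace$L, 120L)
  expect_equal(run$oracle$calls, 120L)
})

test_that("cost conservation links trace totals to oracle calls", {
  for (s in c("cbal", "cbrl", "ubal", "ubrl")) {
    pool <- tiny_pool(n = 400, frac = 0.1, seed = 29)
    run <- run_strategy(pool, run_config(s, T = 6, seed = 3))
    expect_equal(run$oracle$calls,
                 run$bootstrap$n_annotated + sum(run$trace$N_t))
    log <- annotation_log(run$oracle)
    charged <- log$sample_id[log$charged]
    expect_false(anyDuplicated(charged) > 0)
    expect_equal(length(charged), run$oracle$calls)
    # training set and unlabeled pool never overlap
    expect_false(anyDuplicated(run$labeled_ids) > 0)
  }
})

test_that("pool exhaustion truncates the trace instead of failing", {
  pool <- tiny_pool(n = 40, frac = 0.25, seed = 7)
  run <- run_strategy(pool, run_config("cbrl", T = 50, seed = 9))
  expect_true(run$truncated)
  expect_lt(nrow(run$trace), 50)
  expect_lte(run$oracle$calls, 40)
})

test_that("the stopping criterion finds the first stable iteration", {
  expect_equal(stopping_iteration(c(0.50, 0.70, 0.71), 0.02), 2)
  expect_equal(stopping_iteration(rep(0.8, 5), 0), 1)
  expect_equal(stopping_iteration(c(0.1, 0.3, 0.5, 0.7), 0.05), 4)
  expect_error(stopping_iteration(0.5, 0.1), "length")
})

test_that("compare_strategies replicates trials in long format", {
  spec <- pool_spec(200, 0.1, 2, dim = 4, seed = 1)
  cmp <- compare_strategies(spec, strategies = c("cbrl", "ubrl", "full"),
                            n_trials = 2, test_fraction = 0.25,
                            config_args = list(T = 3, bootstrap_size = 6),
                            seed = 77)
  df <- as.data.frame(cmp)
  expect_equal(sort(unique(df$trial)), 1:2)
  expect_equal(nrow(df[df$strategy == "cbrl", ]), 2 * 3)
  # the full baseline has a fixed training set: one constant row per trial
  full <- df[df$strategy == "full", ]
  expect_equal(nrow(full), 2)
  expect_true(all(full$N_t == full$n_train))
  s <- summary(cmp)
  expect_true(all(c("strategy", "t", "mean_N_t") %in% names(s)))
  expect_true(all(!is.na(s$mean_auc[s$strategy == "full"])))
})
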