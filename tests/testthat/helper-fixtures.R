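# shared fixtures, all generated in code

tiny_pool <- function(n = 400, frac = 0.1, sep = 2, dim = 6, seed = 1L) {
  make_feature_pool(pool_spec(n, frac, sep, dim, seed = seed))
}

# a committee whose member j is a stump voting minority iff f1 > threshold[j];
# confidence of a sample at x is then #(thresholds < x) / m exactly
stump_committee <- function(thresholds) {
  members <- lapply(thresholds, function(th) {
    df <- data.frame(.y = factor(c(0L, 1L), levels = c(0L, 1L)),
                     f1 = c(th - 0.05, th + 0.05))
    rpart::rpart(.y ~ f1, data = df, method = "class",
                 control = rpart::rpart.control(xval = 0, cp = 0,
                                                minsplit = 2))
  })
  structure(list(members = members, m = length(thresholds), seed = 0L,
                 n_features = 1L, trained_on = "synthetic stumps",
                 feature_names = "f1"),
            class = "committee")
}

# labeled pool wrapped as matrix + labels for classifier helpers
pool_xy <- function(pool) list(x = pool$features, y = pool$labels)

# Mann-Whitney pairwise AUC oracle: P(score_pos > score_neg) + 0.5 ties
mw_auc <- function(scores, truth) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
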