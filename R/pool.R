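#' Specification for a synthetic two-class feature pool
#'
#' Describes an imbalanced two-class sample pool in feature space. Minority
#' (class 1, the target class) and majority (class 0) samples are drawn from
#' multivariate Gaussians with identity covariance whose means are separated
#' by `class_separation` along a random unit direction. The minority count is
#' deterministic: exactly `round(n_total * minority_fraction)` samples.
#'
#' @param n_total total number of samples (>= 2).
#' @param minority_fraction fraction of minority-class samples, in (0, 1).
#'   The default 0.04 mirrors a heavily imbalanced histopathology pool where
#'   roughly 1 region in 25 belongs to the target (cancer) class.
#' @param class_separation Euclidean distance between the class means, in
#'   units of the (unit) within-class standard deviation. 0 makes the classes
#'   indistinguishable.
#' @param dim feature dimensionality.
#' @param seed integer seed; the same spec always generates the same pool.
#' @return An object of class `pool_spec`.
#' @seealso [make_feature_pool()], [split_pool()]
#' @export
pool_spec <- function(n_total, minority_fraction = 0.04, class_separation = 2,
                      dim = 14, seed = 1L) {
  check_number(n_total, "n_total", lower = 2, integer = TRUE)
  check_number(minority_fraction, "minority_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(class_separation, "class_separation", lower = 0)
  check_number(dim, "dim", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_total = as.integer(n_total),
                 minority_fraction = minority_fraction,
                 class_separation = class_separation,
                 dim = as.integer(dim), seed = as.integer(seed)),
            class = "pool_spec")
}

new_pool <- function(ids, features, labels, role = "train") {
  stopifnot(length(ids) == nrow(features), length(labels) == length(ids),
            !anyDuplicated(ids), all(labels %in% c(0L, 1L)))
  structure(list(ids = as.character(ids), features = features,
                 labels = as.integer(labels), role = role),
            class = "sample_pool")
}

#' Generate a synthetic imbalanced feature pool
#'
#' Draws an unlabeled pool with hidden ground-truth labels. Minority samples
#' have feature mean `class_separation * u` (u a seeded random unit vector),
#' majority samples mean 0; both classes share identity covariance. Sample
#' order is shuffled so class membership is not positional.
#'
#' @param spec a [pool_spec()].
#' @return A `sample_pool`: list with `ids` (character), `features`
#'   (numeric matrix, columns `f1..fD`), `labels` (integer, 1 = minority /
#'   target class, 0 = majority; hidden from learners until annotated), and
#'   `role`.
#' @examples
#' pool <- make_feature_pool(pool_spec(1000, 0.04, 2, dim = 14, seed = 7))
#' table(pool$labels)  # exactly 40 minority samples
#' @export
make_feature_pool <- function(spec) {
  stopifnot(inherits(spec, "pool_spec"))
  with_seed(spec$seed, {
    n  <- spec$n_total
    n1 <- as.integer(round(n * spec$minority_fraction))
    n0 <- n - n1
    d  <- spec$dim
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    x1 <- matrix(stats::rnorm(n1 * d), n1, d)
    x1 <- sweep(x1, 2L, spec$class_separation * u, "+")
    x0 <- matrix(stats::rnorm(n0 * d), n0, d)
    feats <- rbind(x1, x0)
    labels <- c(rep(1L, n1), rep(0L, n0))
    ord <- sample.int(n)
    feats <- feats[ord, , drop = FALSE]
    labels <- labels[ord]
    colnames(feats) <- paste0("f", seq_len(d))
    new_pool(sprintf("s%06d", seq_len(n)), feats, labels)
  })
}

#' Randomly partition a pool into train and test pools
#'
#' Uniform random partition under `seed`. At least one sample is kept on each
#' side. Train and test pools are disjoint and cover the input.
#'
#' @param pool a `sample_pool`.
#' @param test_fraction fraction assigned to the test pool, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `sample_pool`s.
#' @export
split_pool <- function(pool, test_fraction, seed = 1L) {
  stopifnot(inherits(pool, "sample_pool"))
  n <- length(pool$ids)
  if (n < 2L) stop("pool must contain at least 2 samples to split", call. = FALSE)
  check_number(test_fraction, "test_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n_te <- min(n - 1L, max(1L, as.integer(round(n * test_fraction))))
  with_seed(seed, {
    te <- sort(sample.int(n, n_te))
    tr <- setdiff(seq_len(n), te)
    list(train = new_pool(pool$ids[tr], pool$features[tr, , drop = FALSE],
                          pool$labels[tr], "train"),
         test  = new_pool(pool$ids[te], pool$features[te, , drop = FALSE],
                          pool$labels[te], "test"))
  })
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("<sample_pool> %d samples x %d features (%s)\n",
              length(x$ids), ncol(x$features), x$role))
  cat(sprintf("  minority (class 1): %d (%.2f%%), majority (class 0): %d\n",
              sum(x$labels == 1L), 100 * mean(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Write / read a feature pool as delimited text
#'
#' CSV schema `id,f1..fD,label`, label coded 1 = minority, 0 = majority.
#'
#' @param pool a `sample_pool`.
#' @param path file path.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   `sample_pool`.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "sample_pool"))
  df <- data.frame(id = pool$ids, pool$features, label = pool$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @param role pool role recorded on read ("train" or "test").
#' @export
read_pool <- function(path, role = "train") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pool file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fcols <- setdiff(names(df), need)
  new_pool(df$id, as.matrix(df[fcols]), df$label, role)
}

# subset a pool by id, preserving order of `ids`
pool_subset <- function(pool, ids) {
  idx <- match(ids, pool$ids)
  stopifnot(!anyNA(idx))
  new_pool(pool$ids[idx], pool$features[idx, , drop = FALSE],
           pool$labels[idx], pool$role)
}
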