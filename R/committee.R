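#' Train a bagged decision-tree committee
#'
#' Query-by-committee learner: `m` binary decision trees, each fit on an
#' independent bootstrap resample (with replacement, same size as the labeled
#' set). The committee's fuzzy confidence for a sample is the fraction of
#' members voting for the minority class, so 1 means unanimous minority,
#' 0 unanimous majority, and values near 0.5 mean member disagreement —
#' the informativeness signal driving eligibility.
#'
#' Trees are grown unpruned (`cp = 0`, `minsplit = 2`) with an optional depth
#' cap; bagging, not pruning, supplies the variance that makes disagreement
#' meaningful.
#'
#' @param x numeric feature matrix of the labeled training set.
#' @param y integer labels (1 = minority, 0 = majority); both classes must be
#'   present.
#' @param m committee size (>= 2; default 10 — even, so exact 0.5
#'   disagreement is attainable).
#' @param seed integer seed; member resamples are drawn deterministically.
#' @param maxdepth optional depth cap per tree (default none).
#' @return object of class `committee`.
#' @export
train_committee <- function(x, y, m = 10, seed = 1L, maxdepth = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("labeled set contains a single class; extend the bootstrap sample ",
         "until both classes are present", call. = FALSE)
  check_number(m, "m", lower = 2, integer = TRUE)
  n <- nrow(x)
  ctrl <- rpart::rpart.control(xval = 0, cp = 0, minsplit = 2,
                               maxdepth = if (is.null(maxdepth)) 30
                                          else as.integer(maxdepth))
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x)
  members <- with_seed(seed, lapply(seq_len(m), function(j) {
    idx <- sample.int(n, n, replace = TRUE)
    # a resample missing one class yields a constant voter; redraw a few
    # times first so most members are genuine trees
    tries <- 0L
    while (length(unique(y[idx])) < 2L && tries < 25L) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- tries + 1L
    }
    if (length(unique(y[idx])) < 2L)
      return(list(constant = unique(y[idx])))
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = ctrl)
  }))
  structure(list(members = members, m = as.integer(m), seed = as.integer(seed),
                 n_features = ncol(x),
                 trained_on = sprintf("%d samples (%d minority)", n, sum(y)),
                 feature_names = colnames(x)),
            class = "committee")
}

member_votes <- function(committee, x) {
  df <- data.frame(x)
  if (!is.null(committee$feature_names)) colnames(df) <- committee$feature_names
  vapply(committee$members, function(mem) {
    if (!is.null(mem$constant)) rep(mem$constant, nrow(x))
    else as.integer(as.character(predict(mem, df, type = "class")))
  }, integer(nrow(x)))
}

#' Committee confidence that samples belong to the minority class
#'
#' Fraction of members voting for the minority class; values lie on the grid
#' `{0, 1/m, ..., 1}`. 1 indicates strong confidence in minority membership,
#' 0 strong confidence in majority membership.
#'
#' @param committee a [train_committee()] result.
#' @param x feature matrix (or a `sample_pool`).
#' @return numeric vector in \[0, 1\], one value per row.
#' @export
confidence <- function(committee, x) {
  stopifnot(inherits(committee, "committee"))
  if (inherits(x, "sample_pool")) x <- x$features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != committee$n_features)
    stop(sprintf("feature dimension mismatch: committee expects %d, got %d",
                 committee$n_features, ncol(x)), call. = FALSE)
  votes <- member_votes(committee, x)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)
}

#' @export
predict.committee <- function(object, newdata,
                              type = c("confidence", "class"), ...) {
  type <- match.arg(type)
  conf <- confidence(object, newdata)
  if (type == "confidence") conf else as.integer(conf > 0.5)
}

#' @export
print.committee <- function(x, ...) {
  cat(sprintf("<committee> %d bagged decision trees, trained on %s\n",
              x$m, x$trained_on))
  invisible(x)
}

#' Find the eligible (informative) set of a pool
#'
#' A sample is eligible for annotation when the committee's confidence lies
#' within the margin `tau` of maximal disagreement: `|T(r) - 0.5| <= tau`.
#' `tau = 0.5` makes every sample eligible (active learning degenerates to
#' random learning); `tau = 0` keeps only samples at exact 0.5 disagreement.
#' The inequality is inclusive so the `tau = 0.5` limit covers confidences 0
#' and 1 exactly.
#'
#' @param committee a [train_committee()] result.
#' @param pool a `sample_pool` (or feature matrix) of unlabeled candidates.
#' @param tau confidence margin in \[0, 0.5\].
#' @param ids candidate ids (defaults to the pool's ids).
#' @return object of class `eligible_set`: list with `ids`, `confidence`
#'   (of the eligible members, in pool order), `tau`, and oracle-visible true
#'   class counts `k1`, `k2` when the pool carries labels.
#' @export
find_eligible <- function(committee, pool, tau, ids = NULL) {
  check_number(tau, "tau", lower = 0, upper = 0.5)
  labels <- NULL
  if (inherits(pool, "sample_pool")) {
    ids <- ids %||% pool$ids
    labels <- pool$labels
    x <- pool$features
  } else {
    x <- pool
    ids <- ids %||% as.character(seq_len(nrow(x)))
  }
  if (!nrow(x))
    return(structure(list(ids = character(0), confidence = numeric(0),
                          tau = tau, k1 = 0L, k2 = 0L),
                     class = "eligible_set"))
  conf <- confidence(committee, x)
  keep <- abs(conf - 0.5) <= tau + 1e-12
  structure(list(ids = ids[keep], confidence = conf[keep], tau = tau,
                 k1 = if (is.null(labels)) NA_integer_ else
                   sum(labels[keep] == 1L),
                 k2 = if (is.null(labels)) NA_integer_ else
                   sum(labels[keep] == 0L)),
            class = "eligible_set")
}

#' @export
print.eligible_set <- function(x, ...) {
  cat(sprintf("<eligible_set> %d samples within tau = %g of 0.5",
              length(x$ids), x$tau))
  if (!is.na(x$k1)) cat(sprintf(" (true classes: %d minority / %d majority)",
                                x$k1, x$k2))
  cat("\n")
  invisible(x)
}
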