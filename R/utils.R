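# internal helpers: seeded evaluation and argument checking

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
# All user-facing randomness in the package flows through this helper so that
# seeded calls never perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically expand one root seed into a named list of sub-seed vectors.
# Layout is fixed (query seeds drawn first) so that two strategies sharing a
# root seed share their annotation-draw streams regardless of whether the
# committee stream is consumed.
derive_seeds <- function(root, n_iter) {
  with_seed(root, {
    s <- sample.int(.Machine$integer.max - 1L, 3L * n_iter + 2L)
    list(
      query     = s[seq_len(n_iter)],
      committee = s[n_iter + seq_len(n_iter)],
      eval      = s[2L * n_iter + seq_len(n_iter)],
      bootstrap = s[3L * n_iter + 1L],
      extra     = s[3L * n_iter + 2L]
    )
  })
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE,
                         strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
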