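# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_param(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop_param(sprintf("'%s' must be a single %s number", name,
                       if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed", min = 0L)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(theta) {
  theta <- (theta + pi) %% (2 * pi) - pi
  theta[theta == -pi] <- pi
  theta
}

# Vectorised two-sided Welch t-test on per-row summary statistics.
# Returns NA where the pooled standard error is zero.
welch_t_rows <- function(mean_a, var_a, n_a, mean_b, var_b, n_b) {
  se2 <- var_a / n_a + var_b / n_b
  t <- (mean_b - mean_a) / sqrt(se2)
  df <- se2^2 / ((var_a / n_a)^2 / (n_a - 1) + (var_b / n_b)^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA_real_
  list(t = t, df = df, p = p)
}
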