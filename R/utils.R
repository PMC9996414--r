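# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. All user-facing sampling in
# the package goes through this so that seeds are honored without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Draw a vector of derived sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
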