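# Internal helpers shared across the package.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict && x <= lower) stop_(sprintf("'%s' must be > %g", name, lower))
  if (!strict && x < lower) stop_(sprintf("'%s' must be >= %g", name, lower))
  invisible(x)
}

# Expand a scalar-or-vector parameter to length n (per-gene values).
expand_per_gene <- function(x, n, name) {
  if (length(x) == 1L) x <- rep(as.numeric(x), n)
  if (length(x) != n)
    stop_(sprintf("'%s' must have length 1 or %d, got %d", name, n, length(x)))
  as.numeric(x)
}
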