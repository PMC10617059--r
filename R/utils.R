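## Internal helpers: seed fan-out and scoped RNG state.

# Deterministic integer seed derived from a master seed and a string tag.
# Polynomial string hash folded into [0, 2^31 - 2] so derived streams for
# different (stage, combination) tags never collide by construction order:
# adding a combination to a sweep cannot perturb another combination's seed.
derive_seed <- function(master, ...) {
  tag <- paste(c(format(master), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ceiling-based "top percent" count: a nonzero percent never selects zero.
top_n_by_percent <- function(n, percent) {
  stopifnot(percent > 0, percent <= 1)
  as.integer(ceiling(percent * n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
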