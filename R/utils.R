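# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log2 <-> natural-log coefficient scale. All model fitting is done on the
# natural-log scale; everything user-facing is base 2.
ln_to_log2 <- function(x) x / log(2)
log2_to_ln <- function(x) x * log(2)

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
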