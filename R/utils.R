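# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed so independent generators fed the same
# user seed do not share RNG streams. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103L + stream * 12347L) %% 2147483647
}

msg <- function(...) message("[ppmkit] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_character_seq <- function(x, what = "sequence") {
  if (!is.character(x) || anyNA(x))
    stop(what, " must be a character vector without NAs", call. = FALSE)
}
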