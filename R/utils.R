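# Small internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state; the caller's state is restored.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derived stream seed for (class_id, draw_index) pairs, kept within 32-bit
# integer range so independent per-image streams survive reordering.
stream_seed <- function(master, a, b = 0L) {
  s <- (as.double(master) * 2654435.0 + as.double(a) * 97561.0 +
          as.double(b) * 1013.0) %% 2147483629
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
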