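# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# match.arg-like check that reports the offending value
check_choice <- function(x, choices, what) {
  bad <- setdiff(unique(x), choices)
  if (length(bad) > 0) {
    stop_fmt("invalid %s: %s (expected one of %s)",
             what, paste(bad, collapse = ", "), paste(choices, collapse = ", "))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
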