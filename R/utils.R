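# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Period label with an en dash (U+2013), e.g. "1971-1975".
.period_label <- function(start, end) sprintf("%d\u2013%d", start, end)
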