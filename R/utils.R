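# internal helpers

# Evaluate `code` with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so generator sub-streams never perturb user code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds derived from one global seed; kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emaqc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
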