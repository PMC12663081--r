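# Internal helpers: seed handling and argument checks.

# All randomness in the package flows from one integer seed through this
# splitting scheme: stream s of seed x is (x mod 599479)*3581 + 613*s + 1,
# reduced mod 2^31 - 1 so derived seeds stay valid 32-bit integers.
derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  stream <- as.integer(stream)
  as.integer(((seed %% 599479L) * 3581 + 613 * stream + 1) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

check_probability <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

default_node_labels <- function(n) sprintf("n%02d", seq_len(n))
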