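# Internal helpers: validation, seeded RNG scoping, stable seed derivation.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_finite_params <- function(params) {
  nm <- names(params)
  for (i in seq_along(params)) {
    v <- params[[i]]
    if (is.numeric(v) && any(!is.finite(v))) {
      abort(sprintf("parameter '%s' must be finite", nm[i] %||% as.character(i)))
    }
  }
  invisible(TRUE)
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
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
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Stable substream derivation: polynomial string hash folded into the master
# seed, mod (2^31 - 1). Adding a batch/stage never shifts another's stream.
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(labels)) h <- (h * 131 + code) %% m
  as.integer((as.numeric(master) %% m + h) %% m)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
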