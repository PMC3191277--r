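# internal helpers ----------------------------------------------------------

`%||%` <- function(x, y) if (is.null(x)) y else x

# One root seed -> named reproducible substreams, all < 2^31.
# Keeps stochastic stages (cohort, permutations, pre-image restarts)
# independently auditable without consuming the caller's RNG state.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483563) + 1L
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ocb_validation_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "ocb_validation_error")
  }
  invisible(x)
}

stop_shape <- function(msg) abort(msg, class = c("ocb_shape_error", "ocb_validation_error"))
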