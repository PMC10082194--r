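#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent error class for user-facing validation failures
hrd_stop <- function(..., class = "hrdkit_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Derive a reproducible child seed from a root seed and a stream label, so the
# generator's named substreams (profiles, growth, foci, variants, ...) can be
# regenerated independently.  Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is_count(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((seed * 48271 + h * 9973) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
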