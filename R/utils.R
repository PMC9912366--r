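#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic steps in the package route through this so that a single
# user-visible `seed` argument makes a whole run reproducible.
with_local_seed <- function(seed, expr) {
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
  force(expr)
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tfmapr <- function(...) stop(..., call. = FALSE)

# Fixed float formatting used in every written artifact: 6 significant
# digits, "." decimal, so outputs diff cleanly across platforms.
format_score <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop_tfmapr(sprintf("'%s' must be a single finite number >= %s", name, min))
  }
  invisible(x)
}
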