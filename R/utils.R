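#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. All stochastic entry points funnel through
# this so that a single seed argument makes a whole run reproducible without
# clobbering the user's session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a base seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stop_input <- function(msg, class = "synconsol_input_error") {
  stop(errorCondition(msg, class = c(class, "synconsol_error")))
}

stop_format <- function(msg) stop_input(msg, class = "synconsol_format_error")

row_max <- function(m) {
  # pmax-based row maximum; avoids apply() overhead on wide matrices
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) out <- pmax(out, m[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
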