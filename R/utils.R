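# Internal helpers shared across modules.

# Stop unless every element of x is a finite number satisfying `ok`.
check_number <- function(x, name, ok = function(v) TRUE, msg = "invalid") {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || !all(ok(x))) {
    stop(sprintf("`%s` is %s", name, msg), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name, function(v) v > 0, "not a positive finite number")
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Centered moving average with symmetric window shrinking at the edges,
# so the output has no leading/trailing NA and a flat input stays flat.
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  s <- cumsum(c(0, x))
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frame-loop helper: collect garbage periodically so per-frame temporaries
# don't accumulate between automatic collections on multi-GB videos.
gc_every <- function(i, every = 150L) {
  if (i %% every == 0L) invisible(gc(FALSE))
}
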