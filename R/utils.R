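# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic package functions route through this so that a
# given seed is bit-reproducible regardless of what the session did before.
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

check_positive <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (allow_zero) all(x >= 0) else all(x > 0)
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s, got %s", name,
      if (allow_zero) "non-negative and finite" else "positive and finite",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

# angular spatial frequencies (rad/um) of an M-point DFT over extent L (um),
# in native FFT ordering (DC first)
fft_k <- function(M, L) 2 * pi * c(0:floor(M / 2), -(ceiling(M / 2) - 1):-1)[seq_len(M)] / L

# centre the zero-frequency / zero-lag element of a matrix (fftshift)
fftshift2 <- function(x) {
  M <- nrow(x)
  N <- ncol(x)
  i <- c((floor(M / 2) + 1):M, 1:floor(M / 2))
  j <- c((floor(N / 2) + 1):N, 1:floor(N / 2))
  x[i, j]
}
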