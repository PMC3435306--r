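# Internal numerical helpers shared across modules.

# Largest seed value handed to set.seed(); R integers are 32-bit.
.seed_max <- 2147483646L

#' Derive a fixed number of child seeds from one master seed
#'
#' All randomness in the package flows from a single recorded seed; stages
#' and repetitions receive child seeds drawn here so that adding draws in one
#' stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.seed_max, n)
}

# Window width in Da -> odd number of grid points (>= 3).
window_points <- function(width_Da, step) {
  max(3L, 2L * as.integer(floor(width_Da / (2 * step))) + 1L)
}

# Rolling minimum with centered window of k points; edge windows shrink.
roll_min <- function(x, k) {
  n <- length(x)
  h <- min(k %/% 2L, n - 1L)
  out <- x
  for (d in seq_len(h)) {
    fwd <- c(x[-seq_len(d)], rep(x[n], d))
    bwd <- c(rep(x[1L], d), x[seq_len(n - d)])
    out <- pmin(out, fwd, bwd)
  }
  out
}

# Centered moving average over k points; edge windows shrink symmetrically
# on the available side (truncated-window mean).
moving_average <- function(x, k) {
  n <- length(x)
  h <- min(k %/% 2L, n - 1L)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# FNV-1a 32-bit hash of a character scalar, as an 8-digit hex string.
# Used only for the run-report provenance stamp. All arithmetic is kept
# below 2^53 so it stays exact in doubles.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  hash <- 2166136261
  for (b in bytes) {
    low <- hash %% 65536
    hash <- hash - low + bitwXor(as.integer(low), b)
    h1 <- hash %/% 65536
    h0 <- hash %% 65536
    hash <- ((h0 * 16777619) + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(hash %/% 65536), as.integer(hash %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
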