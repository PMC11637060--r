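# Internal helpers: seeded substreams and small numeric utilities.

#' Derive a reproducible substream seed from a top-level seed
#'
#' All randomness in the package flows from a single top-level seed through
#' named substreams, so that e.g. phantom geometry and scatterer placement can
#' be varied independently while keeping whole-dataset builds reproducible.
#'
#' @param seed integer top-level seed.
#' @param name character substream name (e.g. `"geometry"`, `"scatterers"`).
#' @return An integer seed derived deterministically from `seed` and `name`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

# Analytic signal magnitude of a real vector via the frequency domain.
envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Arrival time of a pulse in a recorded trace
#'
#' Estimates the arrival time of a pulse as the first crossing of a fraction
#' of the peak of the analytic-signal envelope (linearly interpolated between
#' samples), or as the parabolic-interpolated envelope peak.
#'
#' @param trace numeric vector, one recorded channel.
#' @param fs sampling rate in Hz.
#' @param method `"threshold"` (default) or `"peak"`.
#' @param frac fraction of the envelope peak defining the threshold crossing.
#' @return Arrival time in seconds.
#' @export
arrival_time <- function(trace, fs, method = c("threshold", "peak"),
                         frac = 0.5) {
  method <- match.arg(method)
  env <- envelope(trace)
  ipk <- which.max(env)
  if (method == "peak") {
    if (ipk > 1L && ipk < length(env)) {
      y1 <- env[ipk - 1L]; y2 <- env[ipk]; y3 <- env[ipk + 1L]
      d <- (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
      return((ipk - 1 + d) / fs)
    }
    return((ipk - 1) / fs)
  }
  thr <- frac * env[ipk]
  above <- which(env[seq_len(ipk)] >= thr)
  i <- above[1]
  if (i == 1L) return(0)
  t0 <- (i - 2) + (thr - env[i - 1]) / (env[i] - env[i - 1])
  t0 / fs
}

# round-half-away-from-zero used for grid snapping
rnd <- function(x) trunc(x + sign(x) * 0.5)
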