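#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every stochastic operation in the package is a pure
#' function of its inputs and its seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of sub-seeds from a master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Root-mean-square amplitude of a signal
#' @param x numeric vector.
#' @return scalar rms.
#' @export
rms <- function(x) sqrt(mean(x^2))

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# Raised-cosine on/off ramps applied in place; `ramp_s` seconds each side.
apply_ramps <- function(x, sample_rate, ramp_s = 0.005) {
  n <- length(x)
  nr <- min(floor(ramp_s * sample_rate), floor(n / 2))
  if (nr > 0) {
    w <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * w
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(w)
  }
  x
}

# FFT-peak fundamental-frequency estimate on a windowed chunk; used both by
# internal checks and tests as a model-independent oracle.
#' Estimate the dominant fundamental frequency of a signal by FFT peak
#'
#' @param x numeric waveform.
#' @param sample_rate Hz.
#' @param fmin,fmax search band in Hz.
#' @return estimated frequency of the largest spectral peak in the band, Hz
#'   (parabolic interpolation around the FFT bin).
#' @export
estimate_f0 <- function(x, sample_rate, fmin = 50, fmax = 4000) {
  n <- length(x)
  if (n < 32) stop("signal too short for F0 estimation", call. = FALSE)
  w <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))
  nfft <- 2^ceiling(log2(n))
  sp <- Mod(stats::fft(c(w, rep(0, nfft - n))))[1:(nfft %/% 2)]
  freqs <- (seq_along(sp) - 1) * sample_rate / nfft
  band <- which(freqs >= fmin & freqs <= fmax)
  i <- band[which.max(sp[band])]
  # parabolic interpolation for sub-bin accuracy
  if (i > 1 && i < length(sp)) {
    a <- sp[i - 1]; b <- sp[i]; cc <- sp[i + 1]
    denom <- a - 2 * b + cc
    delta <- if (abs(denom) > 1e-12) 0.5 * (a - cc) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  (i - 1 + delta) * sample_rate / nfft
}

# Spectral centroid in Hz (long-term magnitude spectrum).
spectral_centroid <- function(x, sample_rate) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  sp <- Mod(stats::fft(c(x, rep(0, nfft - n))))[1:(nfft %/% 2)]
  freqs <- (seq_along(sp) - 1) * sample_rate / nfft
  sum(freqs * sp) / sum(sp)
}
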