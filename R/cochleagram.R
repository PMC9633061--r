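# Spectrotemporal representation layer: waveform -> CF x time rate matrix.
# The front end is a gammatone-style bandpass filterbank (Slaney-type ERB
# design) with half-wave rectification, low-pass envelope extraction,
# optional power-law compression and frame averaging to the target frame
# rate. It is pluggable: compute_cochleagram() accepts any front-end
# function with the same signature, so a biophysical periphery model can be
# substituted without touching the feature layer.

#' Cochleagram parameters
#'
#' @param n_channels number of characteristic frequencies (default 67).
#' @param f_min,f_max CF grid endpoints in Hz (defaults 200 and 20000).
#' @param frame_rate output frame rate in Hz (default 1000).
#' @param compression power-law exponent applied to channel envelopes
#'   (default 0.3); `NULL` or 1 for none.
#' @param env_cutoff_hz envelope low-pass cutoff, Hz.
#' @param front_end front-end identifier; `"gammatone"` is built in. A
#'   function `(samples, sample_rate, cfs) -> channels x samples matrix`
#'   may be supplied for a custom periphery.
#' @return a `cochleagram_params` object.
#' @export
cochleagram_params <- function(n_channels = 67, f_min = 200, f_max = 20000,
                               frame_rate = 1000, compression = 0.3,
                               env_cutoff_hz = 300,
                               front_end = "gammatone") {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), f_min = f_min,
                 f_max = f_max, frame_rate = frame_rate,
                 compression = compression, env_cutoff_hz = env_cutoff_hz,
                 front_end = front_end),
            class = "cochleagram_params")
}

#' Logarithmically spaced characteristic-frequency grid
#'
#' Geometric spacing with exact endpoints.
#'
#' @param params a [cochleagram_params()] object.
#' @return numeric vector of CFs in Hz, ascending.
#' @export
make_cf_grid <- function(params) {
  n <- params$n_channels
  params$f_min * (params$f_max / params$f_min)^((seq_len(n) - 1) / (n - 1))
}

# One direct-form-II-style biquad: y[n] = b0 x + b1 x- + b2 x-- - a1 y- - a2 y--
# MA part vectorized, AR part via stats::filter (C loop).
biquad <- function(x, b, a) {
  n <- length(x)
  v <- b[1] * x
  if (n > 1) v[-1] <- v[-1] + b[2] * x[-n]
  if (n > 2) v[-(1:2)] <- v[-(1:2)] + b[3] * x[-((n - 1):n)]
  as.numeric(stats::filter(v, -a, method = "recursive"))
}

# Slaney-type 4th-order gammatone as a cascade of four 2nd-order sections.
gammatone_channel <- function(x, sample_rate, cf) {
  T <- 1 / sample_rate
  erb <- 24.7 * (4.37 * cf / 1000 + 1)
  B <- 1.019 * 2 * pi * erb
  ct <- cos(2 * cf * pi * T); st <- sin(2 * cf * pi * T)
  eB <- exp(B * T)
  B1 <- -2 * ct / eB
  B2 <- exp(-2 * B * T)
  sq_p <- sqrt(3 + 2^1.5); sq_m <- sqrt(3 - 2^1.5)
  A11 <- -(2 * T * ct / eB + 2 * sq_p * T * st / eB) / 2
  A12 <- -(2 * T * ct / eB - 2 * sq_p * T * st / eB) / 2
  A13 <- -(2 * T * ct / eB + 2 * sq_m * T * st / eB) / 2
  A14 <- -(2 * T * ct / eB - 2 * sq_m * T * st / eB) / 2
  z <- exp(4i * cf * pi * T)
  w <- exp(-(B * T) + 2i * cf * pi * T)
  gain <- abs(
    (-2 * z * T + 2 * w * T * (ct - sq_m * st)) *
    (-2 * z * T + 2 * w * T * (ct + sq_m * st)) *
    (-2 * z * T + 2 * w * T * (ct - sq_p * st)) *
    (-2 * z * T + 2 * w * T * (ct + sq_p * st)) /
    (-2 / exp(2 * B * T) - 2 * z + 2 * (1 + z) / eB)^4)
  a <- c(B1, B2)
  y <- biquad(x, c(T / gain, A11 / gain, 0), a)
  y <- biquad(y, c(T, A12, 0), a)
  y <- biquad(y, c(T, A13, 0), a)
  biquad(y, c(T, A14, 0), a)
}

# 2nd-order Butterworth low-pass biquad coefficients (bilinear transform).
butter2_lp <- function(cutoff_hz, sample_rate) {
  K <- tan(pi * cutoff_hz / sample_rate)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(2 * (K^2 - 1), (1 - sqrt(2) * K + K^2)) * norm)
}

# Built-in front end: gammatone filterbank -> half-wave rectified band
# signals at audio rate (channels x samples).
front_end_gammatone <- function(samples, sample_rate, cfs) {
  out <- matrix(0, length(cfs), length(samples))
  for (i in seq_along(cfs)) {
    y <- gammatone_channel(samples, sample_rate, cfs[i])
    out[i, ] <- pmax(y, 0)
  }
  out
}

#' Compute a cochleagram
#'
#' @param call an [annotated_call()] or a numeric waveform.
#' @param params a [cochleagram_params()] object.
#' @param sample_rate Hz; ignored when `call` is an annotated_call.
#' @param source_id identifier stored on the result.
#' @return a `cochleagram`: list with `values` (channels x frames,
#'   nonnegative, rows in ascending CF order), `cfs`, `frame_rate`,
#'   `source_id`, `params`.
#' @export
compute_cochleagram <- function(call, params = cochleagram_params(),
                                sample_rate = 48000, source_id = NULL) {
  if (inherits(call, "annotated_call")) {
    if (is.null(source_id)) source_id <- call$exemplar_id
    sample_rate <- call$sample_rate
    samples <- call$samples
  } else samples <- as.numeric(call)
  if (sample_rate < 2 * params$f_max) {
    stop(sprintf("sample_rate %g too low for f_max %g (need >= 2*f_max)",
                 sample_rate, params$f_max), call. = FALSE)
  }
  cfs <- make_cf_grid(params)
  fe <- if (is.function(params$front_end)) params$front_end
        else switch(params$front_end,
                    gammatone = front_end_gammatone,
                    stop("unknown front_end: ", params$front_end, call. = FALSE))
  band <- fe(samples, sample_rate, cfs)

  # envelope: low-pass then average within half-open 1/frame_rate frames
  lp <- butter2_lp(params$env_cutoff_hz, sample_rate)
  hop <- sample_rate / params$frame_rate
  n_frames <- floor(ncol(band) / hop)
  vals <- matrix(0, length(cfs), n_frames)
  edges <- round((0:n_frames) * hop)
  for (i in seq_along(cfs)) {
    env <- pmax(biquad(band[i, ], lp$b, lp$a), 0)
    cs <- c(0, cumsum(env))
    vals[i, ] <- (cs[edges[-1] + 1] - cs[edges[-(n_frames + 1)] + 1]) /
      diff(edges)
  }
  if (!is.null(params$compression) && params$compression != 1) {
    vals <- vals^params$compression
  }
  structure(list(values = vals, cfs = cfs, frame_rate = params$frame_rate,
                 source_id = source_id, params = params),
            class = "cochleagram")
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram> %s: %d CFs (%.0f-%.0f Hz) x %d frames @ %g Hz\n",
              if (is.null(x$source_id)) "?" else x$source_id,
              nrow(x$values), min(x$cfs), max(x$cfs), ncol(x$values),
              x$frame_rate))
  invisible(x)
}

#' Normalize cochleagram rows to unit maximum
#'
#' Display/inspection helper only — never used in training or detection.
#' All-zero rows are left unchanged. Idempotent.
#'
#' @param c a `cochleagram`.
#' @return a `cochleagram` with each nonzero row scaled to max 1.
#' @export
normalize_rows <- function(c) {
  eps <- 1e-12
  mx <- apply(c$values, 1, max)
  scale <- ifelse(mx > eps, mx, 1)
  c$values <- c$values / scale
  c
}

#' Serialize / deserialize a cochleagram as JSON
#'
#' Portable text container: a JSON object holding the CF grid, frame rate
#' and the value matrix (row-major list of rows).
#'
#' @param c a `cochleagram`.
#' @param path file path.
#' @return `save_cochleagram()`: path invisibly; `load_cochleagram()`: a
#'   `cochleagram`.
#' @export
save_cochleagram <- function(c, path) {
  obj <- list(cfs = c$cfs, frame_rate = c$frame_rate,
              source_id = c$source_id,
              n_channels = nrow(c$values), n_frames = ncol(c$values),
              values = lapply(seq_len(nrow(c$values)),
                              function(i) c$values[i, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cochleagram
#' @export
load_cochleagram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vals <- do.call(rbind, lapply(obj$values, function(r) unlist(r)))
  structure(list(values = vals, cfs = unlist(obj$cfs),
                 frame_rate = obj$frame_rate,
                 source_id = obj$source_id, params = NULL),
            class = "cochleagram")
}
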