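# Stimulus manipulations applied to calls before model evaluation:
# noise mixing at fixed SNR, onset-aligned truncation, tempo change
# (phase-vocoder time stretch), fundamental-frequency shift
# (stretch-then-resample, duration preserving), temporal reversal,
# FIR low-pass filtering, and ISI rearrangement / chimeric construction.

#' Mix gated white noise into a call at a fixed SNR
#'
#' White Gaussian noise of exactly the call's duration is scaled so that
#' `20*log10(rms(signal)/rms(noise)) == snr_db` and added to the signal.
#' The rms is computed over the whole call, including ISIs.
#'
#' @param call an [annotated_call()].
#' @param snr_db target SNR in dB; `Inf` returns the call unchanged.
#' @param seed integer seed for the noise realization.
#' @return an [annotated_call()] (not re-normalized after mixing).
#' @export
mix_noise_snr <- function(call, snr_db, seed = 1) {
  if (!is.finite(snr_db)) {
    if (snr_db == Inf) return(call)
    stop("snr_db must be finite or +Inf", call. = FALSE)
  }
  noise <- with_seed(seed, stats::rnorm(length(call$samples)))
  target_rms <- rms(call$samples) / 10^(snr_db / 20)
  noise <- noise * (target_rms / rms(noise))
  call$samples <- call$samples + noise
  call
}

#' Truncate a call to its first `length_ms` milliseconds
#'
#' @param call an [annotated_call()].
#' @param length_ms segment length from call onset, ms.
#' @return an [annotated_call()]; the annotation is clipped to the kept
#'   window. Lengths at or beyond the call duration return the whole call.
#' @export
truncate_segment <- function(call, length_ms) {
  if (length_ms <= 0) stop("length_ms must be positive", call. = FALSE)
  n_keep <- round(length_ms / 1000 * call$sample_rate)
  if (n_keep >= length(call$samples)) return(call)
  end_s <- n_keep / call$sample_rate
  call$samples <- call$samples[seq_len(n_keep)]
  s <- call$syllables
  if (nrow(s) > 0) {
    s[, 2] <- pmin(s[, 2], end_s)
    s <- s[s[, 1] < end_s & s[, 2] > s[, 1], , drop = FALSE]
  }
  call$syllables <- s
  call
}

# Hann-window STFT phase vocoder. Output has exactly round(n * hs / ha)
# samples, so the realized stretch factor is hs/ha (hs = round(rate * ha)).
phase_vocoder <- function(x, rate, win = 1024, ha = 128) {
  n <- length(x)
  hs <- max(1L, as.integer(round(rate * ha)))
  target_len <- as.integer(round(n * hs / ha))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  n_frames <- max(2L, 1L + ceiling((n - win) / ha) + 1L)
  xp <- c(x, numeric((n_frames - 1) * ha + win - n))
  omega <- 2 * pi * (0:(win - 1)) / win

  out <- numeric((n_frames - 1) * hs + win)
  wsum <- numeric(length(out))
  phase_prev <- NULL
  phase_out <- NULL
  for (t in seq_len(n_frames)) {
    frame <- xp[((t - 1) * ha + 1):((t - 1) * ha + win)] * w
    spec <- stats::fft(frame)
    mag <- Mod(spec); phase <- Arg(spec)
    if (t == 1) {
      phase_out <- phase
    } else {
      dphi <- phase - phase_prev - omega * ha
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      true_freq <- omega + dphi / ha
      phase_out <- phase_out + true_freq * hs
    }
    phase_prev <- phase
    synth <- Re(stats::fft(mag * exp(1i * phase_out), inverse = TRUE)) / win
    idx <- ((t - 1) * hs + 1):((t - 1) * hs + win)
    out[idx] <- out[idx] + synth * w
    wsum[idx] <- wsum[idx] + w^2
  }
  out <- out / pmax(wsum, 1e-8)
  length(out) <- target_len          # pads with NA if short
  out[is.na(out)] <- 0
  out
}

#' Change call tempo without altering the long-term spectrum
#'
#' The tempo parameter `t_percent` maps to a duration factor
#' `100 / (100 - t_percent)`: +80 gives 5x the original length, -100 gives
#' 0.5x. Implemented as a phase-vocoder time stretch; the syllable
#' annotation is scaled by the realized factor.
#'
#' @param call an [annotated_call()].
#' @param t_percent tempo change in percent; must be < 100.
#' @return an [annotated_call()].
#' @export
change_tempo <- function(call, t_percent) {
  if (t_percent >= 100) stop("t_percent must be < 100 (infinite stretch)",
                             call. = FALSE)
  if (t_percent == 0) return(call)
  r <- 100 / (100 - t_percent)
  n <- length(call$samples)
  y <- phase_vocoder(call$samples, r)
  r_eff <- length(y) / n
  call$samples <- y
  call$syllables <- call$syllables * r_eff
  call
}

#' Shift the fundamental frequency of a call, preserving duration and tempo
#'
#' A shift of `p_percent` multiplies all frequencies by `1 + p_percent/100`
#' (+100 is one octave up). Implemented as a phase-vocoder time stretch by
#' the pitch factor followed by resampling back to the original number of
#' samples, so call length is preserved exactly.
#'
#' @param call an [annotated_call()].
#' @param p_percent pitch change in percent; must be > -100.
#' @return an [annotated_call()] of identical duration and annotation.
#' @export
shift_f0 <- function(call, p_percent) {
  if (p_percent <= -100) stop("p_percent must be > -100", call. = FALSE)
  if (p_percent == 0) return(call)
  s <- 1 + p_percent / 100
  n <- length(call$samples)
  y <- phase_vocoder(call$samples, s)
  m <- length(y)
  pos <- seq(1, m, length.out = n)
  call$samples <- stats::approx(seq_len(m), y, xout = pos)$y
  call
}

#' Temporally reverse a call
#'
#' @param call an [annotated_call()].
#' @return an [annotated_call()] with reversed samples and mirrored,
#'   re-ordered syllable annotation.
#' @export
reverse_call <- function(call) {
  dur <- length(call$samples) / call$sample_rate
  call$samples <- rev(call$samples)
  s <- call$syllables
  if (nrow(s) > 0) {
    s2 <- cbind(dur - s[, 2], dur - s[, 1])
    call$syllables <- s2[rev(seq_len(nrow(s2))), , drop = FALSE]
    colnames(call$syllables) <- c("onset", "offset")
  }
  call
}

# Linear-phase windowed-sinc (Hamming) low-pass FIR kernel, unit DC gain.
fir_lowpass_kernel <- function(cutoff_hz, sample_rate, n_taps) {
  k <- 0:(n_taps - 1)
  m <- (n_taps - 1) / 2
  fc <- cutoff_hz / sample_rate
  h <- ifelse(abs(k - m) < 1e-9, 2 * fc,
              sin(2 * pi * fc * (k - m)) / (pi * (k - m)))
  h <- h * (0.54 - 0.46 * cos(2 * pi * k / (n_taps - 1)))
  h / sum(h)
}

#' Low-pass filter a call with a linear-phase FIR filter
#'
#' Windowed-sinc design; group delay is compensated so the output stays
#' aligned with the annotation and has the input's length.
#'
#' @param call an [annotated_call()].
#' @param cutoff_hz cutoff frequency (default 3000 Hz).
#' @param n_taps filter length (default 256).
#' @return an [annotated_call()].
#' @export
lowpass_call <- function(call, cutoff_hz = 3000, n_taps = 256) {
  if (cutoff_hz <= 0 || cutoff_hz >= call$sample_rate / 2) {
    stop("cutoff_hz must lie in (0, Nyquist)", call. = FALSE)
  }
  h <- fir_lowpass_kernel(cutoff_hz, call$sample_rate, n_taps)
  n <- length(call$samples)
  nfft <- 2^ceiling(log2(n + n_taps))
  X <- stats::fft(c(call$samples, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - n_taps)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  delay <- round((n_taps - 1) / 2)
  call$samples <- y[(delay + 1):(delay + n)]
  call
}

# Extract syllable audio chunks (sample-exact) from an annotated call.
syllable_chunks <- function(call) {
  lapply(seq_len(nrow(call$syllables)), function(i) {
    a <- max(1L, round(call$syllables[i, 1] * call$sample_rate) + 1L)
    b <- min(length(call$samples), round(call$syllables[i, 2] * call$sample_rate))
    call$samples[a:b]
  })
}

#' Rearrange the inter-syllable intervals of a call
#'
#' Three modes following the control/rearrangement designs used with
#' multi-syllable calls: `"silent"` zeroes every sample outside the
#' annotated syllables (one output); `"random"` rebuilds the call with ISI
#' durations drawn with replacement from `donor_isis` (normally the same
#' category's pooled empirical ISI set); `"chimeric"` is the same
#' construction with the other category's ISI set as donor — the output
#' keeps the syllable-donor's category label. Syllable audio is preserved
#' sample-exact in all modes; rebuilt calls have no lead/tail padding.
#'
#' @param call an [annotated_call()] with at least one annotated syllable.
#' @param mode `"silent"`, `"random"` or `"chimeric"`.
#' @param donor_isis numeric vector of donor ISI values in seconds
#'   (required for random/chimeric; see [isi_values()]).
#' @param n_variants number of rebuilt calls for random/chimeric
#'   (default 5).
#' @param seed integer seed.
#' @return list of [annotated_call()] (length 1 for silent mode).
#' @export
manipulate_isi <- function(call, mode = c("silent", "random", "chimeric"),
                           donor_isis = NULL, n_variants = 5, seed = 1) {
  mode <- match.arg(mode)
  if (nrow(call$syllables) < 1) {
    stop("call has no annotated syllables", call. = FALSE)
  }
  if (mode == "silent") {
    keep <- rep(FALSE, length(call$samples))
    for (i in seq_len(nrow(call$syllables))) {
      a <- max(1L, round(call$syllables[i, 1] * call$sample_rate) + 1L)
      b <- min(length(call$samples), round(call$syllables[i, 2] * call$sample_rate))
      keep[a:b] <- TRUE
    }
    call$samples[!keep] <- 0
    call$exemplar_id <- paste0(call$exemplar_id, "_silentISI")
    return(list(call))
  }
  if (is.null(donor_isis) || length(donor_isis) == 0) {
    stop("random/chimeric modes need a non-empty donor ISI set", call. = FALSE)
  }
  chunks <- syllable_chunks(call)
  n_syl <- length(chunks)
  seeds <- derive_seeds(seed, n_variants)
  lapply(seq_len(n_variants), function(v) {
    isis <- if (n_syl > 1) {
      with_seed(seeds[v],
                donor_isis[sample.int(length(donor_isis), n_syl - 1,
                                      replace = TRUE)])
    } else numeric(0)
    pieces <- list(); onsets <- numeric(n_syl); offsets <- numeric(n_syl)
    t_cur <- 0
    for (i in seq_len(n_syl)) {
      onsets[i] <- t_cur
      pieces <- c(pieces, list(chunks[[i]]))
      t_cur <- t_cur + length(chunks[[i]]) / call$sample_rate
      offsets[i] <- t_cur
      if (i < n_syl) {
        gap <- round(isis[i] * call$sample_rate)
        pieces <- c(pieces, list(numeric(gap)))
        t_cur <- t_cur + gap / call$sample_rate
      }
    }
    annotated_call(unlist(pieces), call$sample_rate, cbind(onsets, offsets),
                   call$category,
                   sprintf("%s_%sISI_%d", call$exemplar_id, mode, v))
  })
}

#' Describe a stimulus manipulation
#'
#' A small record used by the paradigm layer to apply manipulations
#' uniformly; `kind = "none"` is the unmanipulated stimulus.
#'
#' @param kind one of "none", "snr", "segment", "tempo", "f0", "reverse",
#'   "lowpass", "isi".
#' @param parameter scalar (dB, ms, percent, Hz) or a mode string for
#'   `kind = "isi"` ("silent", "random", "chimeric").
#' @param seed integer seed for stochastic kinds.
#' @param variant which rebuilt variant to use for isi random/chimeric.
#' @return a `manipulation_spec`.
#' @export
manipulation_spec <- function(kind, parameter = NA, seed = 1, variant = 1) {
  kind <- match.arg(kind, c("none", "snr", "segment", "tempo", "f0",
                            "reverse", "lowpass", "isi"))
  structure(list(kind = kind, parameter = parameter, seed = seed,
                 variant = variant),
            class = "manipulation_spec")
}

#' Apply a manipulation spec to a call
#'
#' @param call an [annotated_call()].
#' @param spec a [manipulation_spec()].
#' @param donor_isis donor ISI set for isi random/chimeric modes.
#' @return an [annotated_call()].
#' @export
apply_manipulation <- function(call, spec, donor_isis = NULL) {
  switch(spec$kind,
    none    = call,
    snr     = mix_noise_snr(call, spec$parameter, seed = spec$seed),
    segment = truncate_segment(call, spec$parameter),
    tempo   = change_tempo(call, spec$parameter),
    f0      = shift_f0(call, spec$parameter),
    reverse = reverse_call(call),
    lowpass = lowpass_call(call, spec$parameter),
    isi     = {
      out <- manipulate_isi(call, spec$parameter, donor_isis = donor_isis,
                            n_variants = max(spec$variant, 1),
                            seed = spec$seed)
      out[[min(spec$variant, length(out))]]
    })
}

# Stable signature for caching manipulated stimuli.
manipulation_key <- function(exemplar_id, spec) {
  paste(exemplar_id, spec$kind, format(spec$parameter), spec$seed,
        spec$variant, sep = "|")
}
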