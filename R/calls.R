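# Synthetic vocalization corpus: harmonic-stack syllable trains with
# per-exemplar jitter in fundamental frequency, syllable durations and
# inter-syllable intervals (ISIs). Four default archetypes emulate the task
# structure of rodent affiliative/alarm calls: two categories share long-term
# spectra but differ in temporal (syllable/ISI) structure, and two share
# envelopes but differ in spectral content, including harmonics above 3 kHz.

#' Specify a bounded uniform distribution for call timing parameters
#'
#' @param min,max bounds (must be finite, `0 < min <= max`).
#' @return a distribution spec usable in [call_category_spec()].
#' @export
unif_ms <- function(min, max) {
  if (!is.finite(min) || !is.finite(max) || min <= 0 || max < min) {
    stop("distribution must have finite positive support with min <= max",
         call. = FALSE)
  }
  structure(list(min = min, max = max), class = "callcat_unif")
}

draw_unif <- function(d, n = 1) stats::runif(n, d$min, d$max)

#' Define a call category
#'
#' A category is a recipe for harmonic-stack syllable trains. Syllables are
#' synthesized with raised-cosine 5 ms on/off ramps; exemplars of the same
#' category differ through jittered F0, syllable durations and ISIs.
#'
#' @param name category label.
#' @param f0_base base fundamental frequency, Hz.
#' @param f0_jitter fractional range of per-exemplar F0 jitter (e.g. 0.05
#'   draws the exemplar F0 multiplier uniformly from 0.95–1.05).
#' @param f0_contour `"flat"`, `"rising"` or `"falling"` within-syllable
#'   F0 trajectory.
#' @param contour_depth fractional F0 excursion of a rising/falling contour.
#' @param n_harmonics number of harmonics in the stack.
#' @param harmonic_rolloff amplitude decay per harmonic, dB.
#' @param syllable_dur per-syllable duration distribution, ms ([unif_ms()]).
#' @param isi_dur ISI duration distribution, ms ([unif_ms()]).
#' @param n_syllables integer range `c(min, max)` of syllables per call.
#' @param spectral_emphasis `c(lo, hi)` band in Hz whose harmonics are
#'   boosted by `emphasis_db`, or NULL.
#' @param emphasis_db boost applied inside the emphasis band, dB.
#' @return a `call_category_spec` object.
#' @export
call_category_spec <- function(name, f0_base, f0_jitter = 0.05,
                               f0_contour = c("flat", "rising", "falling"),
                               contour_depth = 0.2,
                               n_harmonics = 8, harmonic_rolloff = 4,
                               syllable_dur = unif_ms(80, 120),
                               isi_dur = unif_ms(80, 140),
                               n_syllables = c(4, 6),
                               spectral_emphasis = NULL,
                               emphasis_db = 6) {
  f0_contour <- match.arg(f0_contour)
  assert_scalar(f0_base, "f0_base", lower = 1e-9)
  assert_scalar(f0_jitter, "f0_jitter", lower = 0, upper = 0.99)
  assert_scalar(n_harmonics, "n_harmonics", lower = 1)
  if (!inherits(syllable_dur, "callcat_unif") || !inherits(isi_dur, "callcat_unif")) {
    stop("syllable_dur and isi_dur must be unif_ms() distributions", call. = FALSE)
  }
  n_syllables <- as.integer(round(n_syllables))
  if (length(n_syllables) == 1L) n_syllables <- rep(n_syllables, 2L)
  if (any(n_syllables < 1L) || n_syllables[2] < n_syllables[1]) {
    stop("n_syllables must be an integer range with min >= 1", call. = FALSE)
  }
  structure(list(name = name, f0_base = f0_base, f0_jitter = f0_jitter,
                 f0_contour = f0_contour, contour_depth = contour_depth,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_rolloff = harmonic_rolloff,
                 syllable_dur = syllable_dur, isi_dur = isi_dur,
                 n_syllables = n_syllables,
                 spectral_emphasis = spectral_emphasis,
                 emphasis_db = emphasis_db),
            class = "call_category_spec")
}

#' Default four-category call archetypes
#'
#' Two low-frequency categories ("chut"-like and "purr"-like) share the same
#' harmonic spectrum but differ in syllable rate and ISI structure; two
#' longer-syllable categories ("wheek"-like and "whine"-like) share envelope
#' statistics but differ in spectral content — the wheek-like category
#' carries substantial energy above 3 kHz, the whine-like one does not.
#'
#' @return named list of four [call_category_spec()] objects.
#' @export
default_call_specs <- function() {
  list(
    chut = call_category_spec(
      "chut", f0_base = 500, f0_jitter = 0.05, f0_contour = "flat",
      n_harmonics = 8, harmonic_rolloff = 4,
      syllable_dur = unif_ms(90, 130), isi_dur = unif_ms(100, 150),
      n_syllables = c(5, 6)),
    purr = call_category_spec(
      "purr", f0_base = 500, f0_jitter = 0.05, f0_contour = "flat",
      n_harmonics = 8, harmonic_rolloff = 4,
      syllable_dur = unif_ms(35, 50), isi_dur = unif_ms(20, 35),
      n_syllables = c(15, 18)),
    wheek = call_category_spec(
      "wheek", f0_base = 900, f0_jitter = 0.06, f0_contour = "rising",
      contour_depth = 0.35, n_harmonics = 10, harmonic_rolloff = 2.5,
      syllable_dur = unif_ms(360, 460), isi_dur = unif_ms(80, 140),
      n_syllables = c(2, 2), spectral_emphasis = c(3000, 10000),
      emphasis_db = 8),
    whine = call_category_spec(
      "whine", f0_base = 450, f0_jitter = 0.06, f0_contour = "rising",
      contour_depth = 0.15, n_harmonics = 6, harmonic_rolloff = 5,
      syllable_dur = unif_ms(360, 460), isi_dur = unif_ms(80, 140),
      n_syllables = c(2, 2))
  )
}

#' Construct an annotated call
#'
#' @param samples numeric waveform.
#' @param sample_rate Hz.
#' @param syllables two-column matrix of (onset, offset) in seconds.
#' @param category category label.
#' @param exemplar_id identifier.
#' @return an `annotated_call`.
#' @export
annotated_call <- function(samples, sample_rate, syllables, category,
                           exemplar_id = NA_character_) {
  syllables <- as.matrix(syllables)
  if (ncol(syllables) != 2 && nrow(syllables) > 0) {
    stop("syllables must be a 2-column (onset, offset) matrix", call. = FALSE)
  }
  colnames(syllables) <- c("onset", "offset")
  dur <- length(samples) / sample_rate
  if (nrow(syllables) > 0) {
    if (any(syllables[, 2] <= syllables[, 1]) ||
        any(syllables < -1e-9) || any(syllables > dur + 1e-9)) {
      stop("syllable intervals must lie within [0, duration]", call. = FALSE)
    }
    if (nrow(syllables) > 1 &&
        any(syllables[-1, 1] < syllables[-nrow(syllables), 2] - 1e-9)) {
      stop("syllable intervals must be disjoint and ordered", call. = FALSE)
    }
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 syllables = syllables, category = category,
                 exemplar_id = exemplar_id),
            class = "annotated_call")
}

#' @export
print.annotated_call <- function(x, ...) {
  cat(sprintf("<annotated_call> %s [%s]: %.3f s @ %d Hz, %d syllable(s), rms %.4g\n",
              x$exemplar_id, x$category,
              length(x$samples) / x$sample_rate, x$sample_rate,
              nrow(x$syllables), rms(x$samples)))
  invisible(x)
}

call_duration <- function(call) length(call$samples) / call$sample_rate

# Synthesize one harmonic-stack syllable. F0 follows a linear glide for
# rising/falling contours; harmonics above Nyquist are dropped.
synth_syllable <- function(spec, f0, dur_s, sample_rate) {
  n <- max(2L, round(dur_s * sample_rate))
  tfrac <- seq(0, 1, length.out = n)
  f0_t <- switch(spec$f0_contour,
    flat    = rep(f0, n),
    rising  = f0 * (1 + spec$contour_depth * tfrac),
    falling = f0 * (1 + spec$contour_depth * (1 - tfrac)))
  phase0 <- 2 * pi * cumsum(f0_t) / sample_rate
  x <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    fh <- h * f0
    if (fh >= sample_rate / 2 * 0.95) break
    amp_db <- -(h - 1) * spec$harmonic_rolloff
    if (!is.null(spec$spectral_emphasis) &&
        fh >= spec$spectral_emphasis[1] && fh <= spec$spectral_emphasis[2]) {
      amp_db <- amp_db + spec$emphasis_db
    }
    x <- x + 10^(amp_db / 20) * sin(h * phase0)
  }
  apply_ramps(x, sample_rate)
}

#' Generate one synthetic call
#'
#' Draws the number of syllables, per-syllable durations, ISIs and an
#' exemplar-level F0 multiplier, synthesizes harmonic-stack syllables with
#' 5 ms raised-cosine ramps, concatenates them with silent ISIs and a short
#' 20 ms lead/tail, and normalizes the whole call to `ref_rms`. The returned
#' annotation reflects the synthesis exactly. Deterministic given `seed`.
#'
#' @param spec a [call_category_spec()].
#' @param seed integer seed.
#' @param sample_rate Hz (default 48000).
#' @param ref_rms target rms of the whole call (default 0.1).
#' @param exemplar_id identifier stored on the call.
#' @return an [annotated_call()].
#' @export
generate_call <- function(spec, seed, sample_rate = 48000, ref_rms = 0.1,
                          exemplar_id = NA_character_) {
  if (!inherits(spec, "call_category_spec")) {
    stop("`spec` must be a call_category_spec", call. = FALSE)
  }
  with_seed(seed, {
    n_syl <- if (spec$n_syllables[1] == spec$n_syllables[2]) spec$n_syllables[1]
             else sample(spec$n_syllables[1]:spec$n_syllables[2], 1)
    f0 <- spec$f0_base *
      stats::runif(1, 1 - spec$f0_jitter, 1 + spec$f0_jitter)
    durs <- draw_unif(spec$syllable_dur, n_syl) / 1000
    isis <- if (n_syl > 1) draw_unif(spec$isi_dur, n_syl - 1) / 1000 else numeric(0)
    lead <- 0.02
    pieces <- list(numeric(round(lead * sample_rate)))
    onsets <- numeric(n_syl); offsets <- numeric(n_syl)
    t_cur <- lead
    for (i in seq_len(n_syl)) {
      syl <- synth_syllable(spec, f0, durs[i], sample_rate)
      onsets[i] <- t_cur
      offsets[i] <- t_cur + length(syl) / sample_rate
      pieces <- c(pieces, list(syl))
      t_cur <- offsets[i]
      if (i < n_syl) {
        gap <- round(isis[i] * sample_rate)
        pieces <- c(pieces, list(numeric(gap)))
        t_cur <- t_cur + gap / sample_rate
      }
    }
    pieces <- c(pieces, list(numeric(round(0.02 * sample_rate))))
    x <- unlist(pieces)
    x <- x * (ref_rms / rms(x))
    annotated_call(x, sample_rate, cbind(onsets, offsets), spec$name,
                   exemplar_id)
  })
}

#' Generate a labelled train/holdout corpus
#'
#' @param specs list of [call_category_spec()] (>= 2 categories).
#' @param n_train,n_holdout exemplars per category and split (>= 1).
#' @param seed master seed; per-exemplar sub-seeds are derived from it.
#' @param sample_rate,ref_rms forwarded to [generate_call()].
#' @return a `call_corpus`: list with `calls` (list of annotated_call) and
#'   `split` (character vector, "train"/"holdout").
#' @export
generate_corpus <- function(specs, n_train = 8, n_holdout = 8, seed = 1,
                            sample_rate = 48000, ref_rms = 0.1) {
  if (length(specs) < 2) stop("need at least 2 category specs", call. = FALSE)
  if (n_train < 1 || n_holdout < 1) {
    stop("n_train and n_holdout must be >= 1", call. = FALSE)
  }
  n_per <- n_train + n_holdout
  seeds <- derive_seeds(seed, length(specs) * n_per)
  calls <- list(); split <- character(0); k <- 0
  for (spec in specs) {
    for (i in seq_len(n_per)) {
      k <- k + 1
      sp <- if (i <= n_train) "train" else "holdout"
      id <- sprintf("%s_%s_%02d", spec$name, sp,
                    if (i <= n_train) i else i - n_train)
      calls[[k]] <- generate_call(spec, seeds[k], sample_rate, ref_rms, id)
      split[k] <- sp
    }
  }
  structure(list(calls = calls, split = split, seed = seed),
            class = "call_corpus")
}

#' @export
print.call_corpus <- function(x, ...) {
  cats <- vapply(x$calls, function(cl) cl$category, "")
  cat(sprintf("<call_corpus> %d calls, %d categories (%s); %d train / %d holdout\n",
              length(x$calls), length(unique(cats)),
              paste(unique(cats), collapse = ", "),
              sum(x$split == "train"), sum(x$split == "holdout")))
  invisible(x)
}

#' Subset a corpus
#' @param corpus a `call_corpus`.
#' @param categories optional category labels to keep.
#' @param split optional `"train"` or `"holdout"`.
#' @return list of annotated_call.
#' @export
corpus_calls <- function(corpus, categories = NULL, split = NULL) {
  keep <- rep(TRUE, length(corpus$calls))
  if (!is.null(split)) keep <- keep & corpus$split %in% split
  if (!is.null(categories)) {
    cats <- vapply(corpus$calls, function(cl) cl$category, "")
    keep <- keep & cats %in% categories
  }
  corpus$calls[keep]
}

#' Segment a waveform into syllables by short-time energy
#'
#' Automated stand-in for manual syllable marking: frames of `frame_ms` are
#' scored by rms energy, frames above `energy_threshold` times the peak
#' frame energy are voiced, runs separated by gaps shorter than `min_gap`
#' are merged, and runs shorter than `min_dur_ms` are dropped.
#'
#' @param samples numeric waveform (or an [annotated_call()]).
#' @param sample_rate Hz (ignored when `samples` is an annotated_call).
#' @param energy_threshold fraction of peak frame energy (default 0.05).
#' @param min_gap minimum silent gap kept as a separator, ms (default 20).
#' @param frame_ms analysis frame, ms.
#' @param min_dur_ms minimum syllable duration kept, ms.
#' @return two-column matrix of (onset, offset) in seconds; zero rows for
#'   silent input.
#' @export
segment_syllables <- function(samples, sample_rate = 48000,
                              energy_threshold = 0.05, min_gap = 20,
                              frame_ms = 5, min_dur_ms = 10) {
  if (inherits(samples, "annotated_call")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  if (!all(is.finite(samples))) stop("signal must be finite", call. = FALSE)
  hop <- max(1L, round(frame_ms / 1000 * sample_rate))
  n_frames <- floor(length(samples) / hop)
  if (n_frames == 0) return(matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("onset", "offset"))))
  e <- vapply(seq_len(n_frames), function(i) {
    seg <- samples[((i - 1) * hop + 1):(i * hop)]
    sqrt(mean(seg^2))
  }, 0)
  peak <- max(e)
  voiced <- if (peak <= 0) rep(FALSE, n_frames) else e > energy_threshold * peak
  if (!any(voiced)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("onset", "offset"))))
  r <- rle(voiced)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by short gaps
  if (nrow(iv) > 1) {
    merged <- iv[1, , drop = FALSE]
    gap_frames <- min_gap / frame_ms
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - merged[nrow(merged), 2] - 1 < gap_frames) {
        merged[nrow(merged), 2] <- iv[i, 2]
      } else merged <- rbind(merged, iv[i, ])
    }
    iv <- merged
  }
  keep <- (iv[, 2] - iv[, 1] + 1) * frame_ms >= min_dur_ms
  iv <- iv[keep, , drop = FALSE]
  out <- cbind(onset = (iv[, 1] - 1) * hop / sample_rate,
               offset = iv[, 2] * hop / sample_rate)
  out
}

#' Write / read an annotated call as WAV plus CSV annotation sidecar
#'
#' `write_call()` writes `<path>` (WAV) and `<path>.syl.csv` (columns
#' onset_s, offset_s). `read_call()` reads them back; the sidecar is
#' optional (missing sidecar gives an empty annotation).
#'
#' @param call an [annotated_call()].
#' @param path WAV path.
#' @param bits WAV encoding, see [write_wav()]. Float32 round-trips samples
#'   to container precision; 16/24-bit quantize.
#' @return `write_call()`: `path` invisibly. `read_call()`: an
#'   [annotated_call()].
#' @export
write_call <- function(call, path, bits = 32) {
  write_wav(call$samples, call$sample_rate, path, bits = bits)
  sidecar <- paste0(path, ".syl.csv")
  utils::write.csv(data.frame(onset_s = call$syllables[, 1],
                              offset_s = call$syllables[, 2]),
                   sidecar, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call
#' @param category,exemplar_id metadata attached on read.
#' @export
read_call <- function(path, category = NA_character_,
                      exemplar_id = NA_character_) {
  w <- read_wav(path)
  sidecar <- paste0(path, ".syl.csv")
  syl <- if (file.exists(sidecar)) {
    d <- utils::read.csv(sidecar)
    cbind(d$onset_s, d$offset_s)
  } else matrix(numeric(0), 0, 2)
  annotated_call(w$samples, w$sample_rate, syl, category, exemplar_id)
}

#' Write a corpus to a directory with a JSON manifest
#'
#' @param corpus a `call_corpus`.
#' @param dir output directory (created if needed).
#' @param bits WAV encoding.
#' @return manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir, bits = 32) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(corpus$calls, function(cl) {
    f <- paste0(cl$exemplar_id, ".wav")
    write_call(cl, file.path(dir, f), bits = bits)
    list(file = f, category = cl$category, exemplar_id = cl$exemplar_id)
  })
  manifest <- list(seed = corpus$seed, split = corpus$split, calls = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  calls <- lapply(manifest$calls, function(e) {
    read_call(file.path(dir, e$file), category = e$category,
              exemplar_id = e$exemplar_id)
  })
  structure(list(calls = calls,
                 split = unlist(manifest$split),
                 seed = manifest$seed),
            class = "call_corpus")
}

#' Pooled empirical ISI values of a set of annotated calls
#'
#' @param calls list of [annotated_call()].
#' @return numeric vector of ISI durations in seconds.
#' @export
isi_values <- function(calls) {
  unlist(lapply(calls, function(cl) {
    s <- cl$syllables
    if (nrow(s) < 2) return(numeric(0))
    s[-1, 1] - s[-nrow(s), 2]
  }))
}
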