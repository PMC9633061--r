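test_that("generate_call honors syllable counts, rms target and determinism", {
  spec3 <- call_category_spec("tri", f0_base = 500, n_syllables = 3)
  cl <- generate_call(spec3, seed = 4)
  expect_equal(nrow(cl$syllables), 3)

  for (spec in default_call_specs()) {
    cl <- generate_call(spec, seed = 12)
    expect_equal(rms(cl$samples), 0.1, tolerance = 1e-6)
  }

  a <- generate_call(spec3, seed = 9)
  b <- generate_call(spec3, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_identical(a$syllables, b$syllables)
})

test_that("jitter-free wheek-like call has its F0 at the requested value", {
  spec <- call_category_spec("w", f0_base = 600, f0_jitter = 0,
                             f0_contour = "flat", n_harmonics = 6,
                             syllable_dur = unif_ms(300, 300),
                             isi_dur = unif_ms(80, 80), n_syllables = 2,
                             spectral_emphasis = c(3000, 10000))
  cl <- generate_call(spec, seed = 2)
  # FFT-peak oracle, computed here rather than via package helpers
  a <- round(cl$syllables[1, 1] * cl$sample_rate) + 300
  b <- round(cl$syllables[1, 2] * cl$sample_rate) - 300
  x <- cl$samples[a:b]
  nfft <- 2^16
  sp <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))[1:(nfft / 2)]
  freqs <- (seq_along(sp) - 1) * cl$sample_rate / nfft
  band <- freqs > 50 & freqs < 1200
  peak <- freqs[band][which.max(sp[band])]
  bin <- cl$sample_rate / nfft
  expect_lt(abs(peak - 600), 600 * 0.01 + bin)
})

test_that("generate_corpus counts, determinism and exemplar variability", {
  specs <- default_call_specs()
  corpus <- generate_corpus(specs, n_train = 8, n_holdout = 8, seed = 3)
  expect_length(corpus$calls, 64)
  expect_equal(sum(corpus$split == "train"), 32)

  corpus2 <- generate_corpus(specs, n_train = 8, n_holdout = 8, seed = 3)
  expect_identical(lapply(corpus$calls, `[[`, "samples"),
                   lapply(corpus2$calls, `[[`, "samples"))

  chuts <- corpus_calls(corpus, "chut", "train")
  expect_false(identical(chuts[[1]]$samples, chuts[[2]]$samples))

  expect_error(generate_corpus(specs, n_train = 0), "n_train")
  expect_error(generate_corpus(specs[1], 8, 8), "2 category")
})

test_that("every generated call satisfies the annotation invariants", {
  corpus <- fx_corpus()
  for (cl in corpus$calls) {
    s <- cl$syllables
    expect_gte(nrow(s), 1)
    expect_true(all(s[, 2] > s[, 1]))
    expect_true(all(s >= 0 & s <= length(cl$samples) / cl$sample_rate + 1e-9))
    if (nrow(s) > 1) expect_true(all(s[-1, 1] >= s[-nrow(s), 2] - 1e-9))
    expect_equal(rms(cl$samples), 0.1, tolerance = 1e-6)
    expect_gte(length(cl$samples) / cl$sample_rate, 0.8)
  }
})

test_that("segment_syllables recovers synthesis annotation and handles edge cases", {
  spec <- call_category_spec("tri", f0_base = 500, n_syllables = 3,
                             syllable_dur = unif_ms(100, 140),
                             isi_dur = unif_ms(100, 150))
  cl <- generate_call(spec, seed = 6)
  seg <- segment_syllables(cl)
  expect_equal(nrow(seg), 3)
  expect_lt(max(abs(as.numeric(seg) - as.numeric(cl$syllables))), 0.005)

  expect_identical(nrow(segment_syllables(numeric(4800), 48000)), 0L)

  tone <- sin(2 * pi * 440 * (1:48000) / 48000)
  seg1 <- segment_syllables(tone, 48000)
  expect_equal(nrow(seg1), 1)
  expect_lt(seg1[1, 1], 0.02)
  expect_gt(seg1[1, 2], 0.98)
})

test_that("WAV and annotation round trips preserve content; stereo is rejected", {
  cl <- generate_call(default_call_specs()$chut, seed = 5)
  tmp <- tempfile(fileext = ".wav")
  write_call(cl, tmp, bits = 32)
  back <- read_call(tmp, category = "chut")
  expect_length(back$samples, length(cl$samples))
  expect_equal(back$samples, cl$samples, tolerance = 1e-7)
  expect_equal(back$sample_rate, 48000)
  expect_equal(unname(back$syllables), unname(cl$syllables))

  # 16-bit round trip at container precision
  tmp16 <- tempfile(fileext = ".wav")
  write_wav(cl$samples, 48000, tmp16, bits = 16)
  w16 <- read_wav(tmp16)
  expect_lt(max(abs(w16$samples - cl$samples)), 1 / 32768)

  # hand-build a 2-channel PCM16 file and expect rejection
  stereo <- tempfile(fileext = ".wav")
  con <- file(stereo, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L), con, 2, endian = "little")   # PCM
  writeBin(c(2L), con, 2, endian = "little")   # 2 channels
  writeBin(48000L, con, 4, endian = "little")
  writeBin(192000L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, 4, endian = "little")
  writeBin(integer(4), con, 2, endian = "little")
  close(con)
  expect_error(read_wav(stereo), "stereo|multichannel")
})

test_that("corpus manifest round trip preserves calls, labels and splits", {
  corpus <- generate_corpus(default_call_specs()[c("chut", "purr")],
                            n_train = 2, n_holdout = 1, seed = 8)
  dir <- tempfile()
  write_corpus(corpus, dir)
  back <- read_corpus(dir)
  expect_equal(back$split, corpus$split)
  expect_equal(vapply(back$calls, `[[`, "", "category"),
               vapply(corpus$calls, `[[`, "", "category"))
  expect_equal(back$calls[[1]]$samples, corpus$calls[[1]]$samples,
               tolerance = 1e-7)
})

test_that("category design: spectra align chut/purr, timing aligns wheek/whine", {
  corpus <- fx_corpus()
  # long-term magnitude spectra via plain periodograms (model-independent)
  mean_spec <- function(cat) {
    calls <- corpus_calls(corpus, cat, "train")
    sp <- sapply(calls, function(cl) {
      x <- cl$samples[1:(2^15)]
      Mod(stats::fft(x))[1:4096]
    })
    rowMeans(sp)
  }
  cosdist <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  d_cp <- cosdist(mean_spec("chut"), mean_spec("purr"))
  d_ww <- cosdist(mean_spec("wheek"), mean_spec("whine"))
  expect_lt(d_cp, d_ww)

  isi_dist <- function(c1, c2) {
    abs(mean(isi_values(corpus_calls(corpus, c1, "train"))) -
        mean(isi_values(corpus_calls(corpus, c2, "train"))))
  }
  expect_gt(isi_dist("chut", "purr"), isi_dist("wheek", "whine"))
})
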