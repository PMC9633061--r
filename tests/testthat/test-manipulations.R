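chut1 <- function() generate_call(default_call_specs()$chut, seed = 41)

test_that("noise mixing hits the requested SNR exactly", {
  cl <- chut1()
  for (snr in c(-18, -6, 0, 12)) {
    mixed <- mix_noise_snr(cl, snr, seed = 3)
    noise <- mixed$samples - cl$samples
    expect_length(noise, length(cl$samples))
    expect_equal(20 * log10(rms(cl$samples) / rms(noise)), snr,
                 tolerance = 0.01)
  }
  expect_identical(mix_noise_snr(cl, Inf), cl)
  m1 <- mix_noise_snr(cl, -6, seed = 9)
  m2 <- mix_noise_snr(cl, -6, seed = 9)
  expect_identical(m1$samples, m2$samples)
})

test_that("truncation keeps the onset-aligned segment and clips annotation", {
  cl <- chut1()
  seg <- truncate_segment(cl, 800)
  expect_equal(length(seg$samples), round(0.8 * 48000))
  expect_identical(seg$samples, cl$samples[1:38400])
  expect_true(all(seg$syllables <= 0.8 + 1e-9))

  expect_identical(truncate_segment(cl, 10000)$samples, cl$samples)
  expect_length(truncate_segment(cl, 50)$samples, 2400)
})

test_that("tempo mapping reproduces the printed duration factors", {
  cl <- chut1()
  n <- length(cl$samples)
  expect_equal(length(change_tempo(cl, 80)$samples) / n, 5, tolerance = 0.01)
  expect_equal(length(change_tempo(cl, -100)$samples) / n, 0.5,
               tolerance = 0.01)
  expect_equal(length(change_tempo(cl, -120)$samples) / n, 1 / 2.2,
               tolerance = 0.01)
  expect_identical(change_tempo(cl, 0), cl)
  expect_error(change_tempo(cl, 100), "t_percent")

  # long-term spectrum preserved: spectral centroid within 5%
  cent <- function(x) {
    sp <- Mod(stats::fft(x))[1:(length(x) %/% 2)]
    f <- (seq_along(sp) - 1) * 48000 / length(x)
    sum(f * sp) / sum(sp)
  }
  st <- change_tempo(cl, 60)
  expect_equal(cent(st$samples), cent(cl$samples), tolerance = 0.05)
})

test_that("F0 shift scales pitch and preserves duration", {
  spec <- call_category_spec("t", f0_base = 500, f0_jitter = 0,
                             f0_contour = "flat", n_harmonics = 5,
                             syllable_dur = unif_ms(400, 400),
                             n_syllables = 1)
  cl <- generate_call(spec, seed = 2)
  f0 <- function(x) estimate_f0(x, 48000, fmin = 100, fmax = 2500)
  seg <- function(c2) {
    a <- round(c2$syllables[1, 1] * 48000) + 480
    b <- round(c2$syllables[1, 2] * 48000) - 480
    c2$samples[a:b]
  }
  up <- shift_f0(cl, 100)
  expect_length(up$samples, length(cl$samples))
  expect_equal(f0(seg(up)) / f0(seg(cl)), 2, tolerance = 0.03)

  dn <- shift_f0(cl, -50)
  expect_equal(f0(seg(dn)) / f0(seg(cl)), 0.5, tolerance = 0.03)

  expect_identical(shift_f0(cl, 0), cl)
  expect_error(shift_f0(cl, -100), "p_percent")
})

test_that("reversal is an involution that mirrors annotations", {
  cl <- chut1()
  rv <- reverse_call(cl)
  expect_length(rv$samples, length(cl$samples))
  expect_identical(reverse_call(rv)$samples, cl$samples)
  expect_equal(unname(reverse_call(rv)$syllables), unname(cl$syllables))
  expect_equal(Mod(stats::fft(rv$samples)), Mod(stats::fft(cl$samples)),
               tolerance = 1e-8)
  # first reversed syllable is the mirrored last original one
  dur <- length(cl$samples) / 48000
  expect_equal(unname(rv$syllables[1, 1]),
               unname(dur - cl$syllables[nrow(cl$syllables), 2]))
})

test_that("low-pass filter meets its passband/stopband contract", {
  tone <- function(f) {
    annotated_call(sin(2 * pi * f * (1:48000) / 48000), 48000,
                   cbind(0.01, 0.99), "tone")
  }
  mid <- 10000:38000   # steady-state region
  lp1 <- lowpass_call(tone(1000))
  gain_db <- 20 * log10(rms(lp1$samples[mid]) / rms(tone(1000)$samples[mid]))
  expect_lt(abs(gain_db), 0.5)

  lp8 <- lowpass_call(tone(8000))
  att_db <- 20 * log10(rms(tone(8000)$samples[mid]) / rms(lp8$samples[mid]))
  expect_gt(att_db, 40)

  expect_error(lowpass_call(tone(1000), cutoff_hz = 30000), "Nyquist")
  expect_identical(formals(lowpass_call)$cutoff_hz, 3000)
  expect_identical(formals(lowpass_call)$n_taps, 256)
})

test_that("ISI manipulations preserve syllables and draw from the donor set", {
  cl <- chut1()
  fs <- cl$sample_rate
  sil <- manipulate_isi(cl, "silent")[[1]]
  in_syl <- rep(FALSE, length(sil$samples))
  for (i in seq_len(nrow(cl$syllables))) {
    a <- round(cl$syllables[i, 1] * fs) + 1
    b <- round(cl$syllables[i, 2] * fs)
    in_syl[a:b] <- TRUE
    expect_identical(sil$samples[a:b], cl$samples[a:b])
  }
  expect_true(all(sil$samples[!in_syl] == 0))

  donor <- c(0.05, 0.08, 0.11)
  variants <- manipulate_isi(cl, "random", donor_isis = donor,
                             n_variants = 5, seed = 13)
  expect_length(variants, 5)
  for (v in variants) {
    expect_equal(nrow(v$syllables), nrow(cl$syllables))
    # syllable audio preserved sample-exact
    for (i in seq_len(nrow(v$syllables))) {
      a0 <- round(cl$syllables[i, 1] * fs) + 1
      b0 <- round(cl$syllables[i, 2] * fs)
      a1 <- round(v$syllables[i, 1] * fs) + 1
      expect_identical(v$samples[a1:(a1 + (b0 - a0))], cl$samples[a0:b0])
    }
    # every realized gap is a member of the donor set (in samples)
    gaps <- round((v$syllables[-1, 1] - v$syllables[-nrow(v$syllables), 2]) * fs)
    expect_true(all(gaps %in% round(donor * fs)))
  }

  one <- annotated_call(cl$samples, fs, cl$syllables[1, , drop = FALSE],
                        "chut", "one")
  out1 <- manipulate_isi(one, "random", donor_isis = donor)[[1]]
  a <- round(one$syllables[1, 1] * fs) + 1
  b <- round(one$syllables[1, 2] * fs)
  expect_identical(out1$samples, cl$samples[a:b])

  expect_error(manipulate_isi(cl, "random"), "donor")
  noann <- annotated_call(cl$samples, fs, matrix(numeric(0), 0, 2), "x")
  expect_error(manipulate_isi(noann, "silent"), "syllable")
})

test_that("manipulations compose sanely and are deterministic", {
  cl <- chut1()
  a <- truncate_segment(reverse_call(cl), 400)
  b <- truncate_segment(cl, 400)
  expect_length(a$samples, length(b$samples))

  v1 <- manipulate_isi(cl, "random", donor_isis = c(0.05, 0.1), seed = 4)
  v2 <- manipulate_isi(cl, "random", donor_isis = c(0.05, 0.1), seed = 4)
  expect_identical(lapply(v1, `[[`, "samples"), lapply(v2, `[[`, "samples"))
})
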