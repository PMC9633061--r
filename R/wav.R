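# Minimal RIFF/WAVE reader and writer over base R connections.
# Supports mono PCM 16/24-bit and IEEE float32. Stereo files are rejected
# (explicit contract) rather than silently down-mixed.

#' Read a mono WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in [-1, 1] for PCM, raw floats for
#'   float32) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$n_channels != 1L) {
        stop("stereo/multichannel WAV not supported; supply mono input",
             call. = FALSE)
      }
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2, 2, signed = TRUE, endian = "little")
        samples <- x / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        b <- readBin(con, "raw", sz)
        n <- length(b) %/% 3
        m <- matrix(as.integer(b[seq_len(3 * n)]), nrow = 3)
        v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d-bit)",
                     fmt$audio_format, fmt$bits), call. = FALSE)
      }
      break
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric vector; values outside [-1, 1] are clipped for
#'   integer encodings.
#' @param sample_rate Hz.
#' @param path output path.
#' @param bits 16, 24 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  stopifnot(bits %in% c(16, 24, 32))
  n <- length(samples)
  bytes_per <- bits / 8
  data_sz <- n * bytes_per
  fmt_tag <- if (bits == 32) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_u32(36 + data_sz)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_u32(16)
  wr_u16(fmt_tag); wr_u16(1); wr_u32(sample_rate)
  wr_u32(sample_rate * bytes_per); wr_u16(bytes_per); wr_u16(bits)
  writeChar("data", con, eos = NULL); wr_u32(data_sz)
  if (bits == 16) {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else if (bits == 24) {
    x <- pmax(-1, pmin(1, samples))
    v <- as.integer(round(x * 8388607))
    v <- ifelse(v < 0, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
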