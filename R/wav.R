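# RIFF/WAVE I/O for the two encodings the package supports: 16-bit PCM and
# 32-bit IEEE float. No R audio package is required at run time; the chunk
# layout here is the plain canonical RIFF form.

#' Read a WAV file into an audio signal
#'
#' Accepts 16-bit PCM and 32-bit IEEE-float RIFF/WAVE files. Multi-channel
#' audio is averaged to mono; samples are scaled to \[-1, 1\]. Other
#' container formats (MP3, FLAC, ...) are rejected: convert them externally
#' (e.g. with FFmpeg) before use.
#'
#' @param path Path to a WAV file.
#' @param target_rate Optional target sample rate in Hz; when given and
#'   different from the file's rate, the signal is resampled (polyphase,
#'   via \pkg{signal}).
#' @param normalize If `TRUE` (default) and the decoded peak exceeds 1
#'   (possible for float files), the signal is rescaled to peak 1.
#' @return An [audio_signal()]; `source_id` is set to the file path.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, target_rate = NULL, normalize = TRUE) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stopf("'%s' is not a RIFF/WAVE file (expected 'RIFF' header); convert non-WAV audio externally", path)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("'%s' is not a WAVE file", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits_per_sample = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stopf("'%s': missing 'fmt ' chunk", path)
  if (is.null(data_raw)) stopf("'%s': missing 'data' chunk", path)

  x <- decode_wav_data(data_raw, fmt, path)
  if (length(x) == 0) stopf("'%s' contains zero-length audio", path)

  if (fmt$n_channels > 1) {
    m <- matrix(x, nrow = fmt$n_channels)
    x <- colMeans(m)
  }
  if (normalize) {
    peak <- max(abs(x))
    if (peak > 1) x <- x / peak
  }
  sig <- audio_signal(x, fmt$sample_rate, source_id = path)
  if (!is.null(target_rate) && target_rate != fmt$sample_rate) {
    sig <- resample_signal(sig, target_rate)
    sig$source_id <- path
  }
  sig
}

decode_wav_data <- function(raw, fmt, path) {
  if (fmt$audio_format == 1L && fmt$bits_per_sample == 16L) {
    ints <- readBin(raw, "integer", length(raw) %/% 2, size = 2,
                    endian = "little", signed = TRUE)
    ints / 32768
  } else if (fmt$audio_format == 3L && fmt$bits_per_sample == 32L) {
    readBin(raw, "numeric", length(raw) %/% 4, size = 4, endian = "little")
  } else {
    stopf("'%s': unsupported WAV encoding (format %d, %d bits); only 16-bit PCM and 32-bit float are read",
          path, fmt$audio_format, fmt$bits_per_sample)
  }
}

#' Write an audio signal to a WAV file
#'
#' @param signal A non-empty [audio_signal()].
#' @param path Output file path.
#' @param bit_depth `16` for 16-bit PCM or `"float32"` for 32-bit IEEE
#'   float. On the 16-bit path, samples outside \[-1, 1\] are clamped with
#'   a warning (augmentation can overshoot slightly).
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (length(x) == 0) stopf("refusing to write an empty signal")
  depth <- as.character(bit_depth)
  if (!depth %in% c("16", "float32")) {
    stopf("`bit_depth` must be 16 or \"float32\", got '%s'", depth)
  }

  if (depth == "16") {
    if (max(abs(x)) > 1) {
      warnf("samples outside [-1, 1] clamped for 16-bit output (peak %.4f)", max(abs(x)))
      x <- pmin(pmax(x, -1), 1)
    }
    payload_n <- length(x) * 2L
    audio_format <- 1L; bits <- 16L
  } else {
    payload_n <- length(x) * 4L
    audio_format <- 3L; bits <- 32L
  }

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))

  sr <- signal$sample_rate
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, size = 4, endian = "little")
  if (depth == "16") {
    q <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

# Polyphase resampling to an integer target rate.
resample_signal <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  p <- as.integer(round(target_rate))
  q <- signal$sample_rate
  g <- gcd_int(p, q)
  y <- signal::resample(signal$samples, p %/% g, q %/% g)
  audio_signal(as.numeric(y), p, source_id = signal$source_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
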