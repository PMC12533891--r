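#' Construct an audio signal object
#'
#' The universal carrier between processing stages: a mono sequence of
#' amplitude samples (dimensionless, nominally in \[-1, 1\]) plus its sample
#' rate in Hz and a free-text provenance label.
#'
#' @param samples Numeric vector of amplitude samples.
#' @param sample_rate Sample rate in Hz (positive integer-valued scalar).
#' @param source_id Free-text provenance label.
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `source_id`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(x)
#' @export
audio_signal <- function(samples, sample_rate, source_id = "") {
  if (!is.numeric(samples)) stopf("`samples` must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stopf("`sample_rate` must be a positive scalar, got %s", format(sample_rate))
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = as.integer(round(sample_rate)),
      source_id = as.character(source_id)
    ),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %d Hz (%.3f s)%s\n",
    length(x$samples), x$sample_rate, duration(x),
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#'
#' @param signal An [audio_signal()].
#' @return Duration in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate
}

#' Framing and windowing parameters
#'
#' Shared short-time analysis configuration. Defaults (1024-sample frames,
#' 512-sample hop, Hann window, centered frames) are standard bioacoustics
#' settings at the package's default 22050 Hz working rate; every analysis
#' function takes its own `params` so other configurations can be pinned.
#'
#' @param frame_length Frame length in samples (positive integer).
#' @param hop_length Hop between consecutive frames in samples
#'   (positive integer, at most `frame_length`).
#' @param window Window name: `"hann"`, `"hamming"` or `"rectangular"`.
#' @param center If `TRUE`, the signal is zero-padded by half a frame on
#'   both sides so frame `t` is centered on sample `t * hop_length`.
#' @return An object of class `frame_params`.
#' @export
frame_params <- function(frame_length = 1024L, hop_length = 512L,
                         window = "hann", center = TRUE) {
  if (!is_count(frame_length)) stopf("`frame_length` must be a positive integer")
  if (!is_count(hop_length)) stopf("`hop_length` must be a positive integer")
  if (hop_length > frame_length) {
    stopf("`hop_length` (%d) must not exceed `frame_length` (%d)",
          hop_length, frame_length)
  }
  window <- match.arg(window, c("hann", "hamming", "rectangular"))
  structure(
    list(
      frame_length = as.integer(frame_length),
      hop_length = as.integer(hop_length),
      window = window,
      center = isTRUE(center)
    ),
    class = "frame_params"
  )
}

# Periodic window of length n (periodic forms satisfy constant-overlap-add
# at hop = n/2, which the overlap-add resynthesis relies on).
window_vector <- function(name, n) {
  k <- 0:(n - 1)
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    rectangular = rep(1, n),
    stopf("unknown window '%s'", name)
  )
}

# Zero-pad half a frame on each side (the `center = TRUE` convention).
pad_for_center <- function(x, frame_length) {
  p <- frame_length %/% 2
  c(numeric(p), x, numeric(p))
}

#' Slice a signal into (possibly overlapping) analysis frames
#'
#' With `center = FALSE` the frame count is
#' `1 + floor((L - frame_length) / hop_length)` for signals of length
#' `L >= frame_length`, and zero frames otherwise. With `center = TRUE` the
#' signal is zero-padded by `floor(frame_length / 2)` on each side first, so
#' frame `t` (0-based) is centered on sample `t * hop_length`.
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()] object.
#' @return A numeric matrix with one row per frame and `frame_length`
#'   columns; row `t` holds the samples of frame `t - 1`.
#' @export
frame_signal <- function(signal, params = frame_params()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "frame_params"))
  x <- signal$samples
  if (length(x) < 1) stopf("cannot frame an empty signal")
  n <- params$frame_length
  h <- params$hop_length
  if (params$center) x <- pad_for_center(x, n)
  L <- length(x)
  if (L < n) {
    return(matrix(numeric(0), nrow = 0, ncol = n))
  }
  n_frames <- 1L + (L - n) %/% h
  starts <- (seq_len(n_frames) - 1L) * h
  idx <- outer(starts, seq_len(n) - 1L, `+`) + 1L
  out <- x[idx]
  dim(out) <- dim(idx)
  out
}

# Sample-domain support of frame f (0-based), as 0-based half-open [lo, hi)
# in original-signal coordinates.
frame_support <- function(f, params) {
  n <- params$frame_length
  h <- params$hop_length
  off <- if (params$center) n %/% 2 else 0L
  lo <- f * h - off
  c(lo, lo + n)
}
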