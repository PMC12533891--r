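# Short-time Fourier analysis/synthesis. The complex transform and the
# weighted overlap-add inverse are internal; user code sees stft_magnitude().

# Complex STFT: (frame_length/2 + 1) bins x n_frames.
stft_complex <- function(signal, params = frame_params()) {
  frames <- frame_signal(signal, params)
  n <- params$frame_length
  if (nrow(frames) == 0) stopf("signal too short for even one frame")
  w <- window_vector(params$window, n)
  X <- stats::mvfft(t(frames) * w)
  n_bins <- n %/% 2 + 1L
  X[seq_len(n_bins), , drop = FALSE]
}

# Inverse STFT by weighted overlap-add with the analysis window reused for
# synthesis and division by the accumulated squared window; this
# reconstructs exactly (up to floating point) wherever the window coverage
# is nonzero, for any hop.
istft <- function(X, params, length_out) {
  n <- params$frame_length
  h <- params$hop_length
  n_bins <- nrow(X)
  if (n_bins != n %/% 2 + 1L) {
    stopf("spectrum has %d bins but frame_length %d implies %d", n_bins, n, n %/% 2 + 1L)
  }
  mirror <- if (n %% 2 == 0) seq(n %/% 2, 2) else seq((n + 1) %/% 2, 2)
  full <- rbind(X, Conj(X[mirror, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n  # n x T
  w <- window_vector(params$window, n)
  frames <- frames * w
  T_ <- ncol(frames)
  total <- (T_ - 1L) * h + n
  y <- numeric(total)
  wsum <- numeric(total)
  w2 <- w * w
  for (t in seq_len(T_)) {
    i <- (t - 1L) * h + seq_len(n)
    y[i] <- y[i] + frames[, t]
    wsum[i] <- wsum[i] + w2
  }
  y <- y / pmax(wsum, .Machine$double.eps)
  if (params$center) {
    off <- n %/% 2
    y <- y[(off + 1):min(length(y), off + length_out)]
  } else {
    y <- y[seq_len(min(length(y), length_out))]
  }
  if (length(y) < length_out) y <- c(y, numeric(length_out - length(y)))
  y
}

#' Magnitude spectrogram of a signal
#'
#' Windowed short-time Fourier transform, returning per-frame magnitudes
#' `sqrt(Re^2 + Im^2)` for the non-negative frequency bins.
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()] object.
#' @return An object of class `spectrogram` with fields `magnitude`
#'   (`n_bins x n_frames`, `n_bins = frame_length / 2 + 1`), `bin_freqs`
#'   (Hz per bin, 0 to Nyquist), `frame_times` (seconds at each frame
#'   center), `params` and `sample_rate`.
#' @examples
#' sp <- stft_magnitude(gen_tone(1000, 0.5, 22050))
#' dim(sp$magnitude)
#' @export
stft_magnitude <- function(signal, params = frame_params()) {
  X <- stft_complex(signal, params)
  n <- params$frame_length
  sr <- signal$sample_rate
  n_bins <- nrow(X)
  t_idx <- seq_len(ncol(X)) - 1L
  centers <- if (params$center) t_idx * params$hop_length else t_idx * params$hop_length + n / 2
  structure(
    list(
      magnitude = Mod(X),
      bin_freqs = (seq_len(n_bins) - 1L) * sr / n,
      frame_times = centers / sr,
      params = params,
      sample_rate = sr
    ),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, %d Hz, frame %d / hop %d (%s)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$sample_rate,
              x$params$frame_length, x$params$hop_length, x$params$window))
  invisible(x)
}

# Number of leading/trailing frames whose window overlaps the center
# padding (used to trim edge transients from index aggregates).
n_edge_frames <- function(params) {
  if (!params$center) return(0L)
  as.integer(ceiling((params$frame_length %/% 2) / params$hop_length))
}
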