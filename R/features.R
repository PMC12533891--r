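# Spectral features: Mel filterbank, Log-Mel spectrogram, MFCC with
# delta / delta-delta coefficients.
#
# Two distinct logarithms are used deliberately: the Log-Mel representation
# is log(1 + E) (bounded below by 0, feeding the Log-Mel ACI), while the
# MFCC cepstrum uses log(E + eps) as in the standard DCT-II cepstrum.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with apexes equally spaced on the Mel scale
#' (HTK form, `mel(f) = 2595 log10(1 + f/700)`) between `fmin_hz` and
#' `fmax_hz`, evaluated at the FFT bin frequencies. Filters have unit apex
#' by default; `norm = "area"` rescales each row to unit area instead.
#'
#' @param n_mels Number of filters (default 20).
#' @param n_fft FFT length the filterbank will be applied to.
#' @param sample_rate Sample rate in Hz.
#' @param fmin_hz,fmax_hz Band edges in Hz; defaults 0 and Nyquist.
#' @param norm `"none"` (unit apex, default) or `"area"`.
#' @return An object of class `mel_filterbank` with fields `weights`
#'   (`n_mels x n_bins`), `n_mels`, `fmin_hz`, `fmax_hz`,
#'   `center_freqs_hz`, `sample_rate`, `n_fft`.
#' @export
mel_filterbank <- function(n_mels = 20L, n_fft = 1024L, sample_rate = 22050L,
                           fmin_hz = 0, fmax_hz = NULL, norm = c("none", "area")) {
  norm <- match.arg(norm)
  if (is.null(fmax_hz)) fmax_hz <- sample_rate / 2
  if (!(fmin_hz >= 0 && fmin_hz < fmax_hz && fmax_hz <= sample_rate / 2)) {
    stopf("need 0 <= fmin_hz < fmax_hz <= sample_rate/2 (got %g, %g)", fmin_hz, fmax_hz)
  }
  if (!is_count(n_mels) || n_mels < 2) stopf("`n_mels` must be an integer >= 2")

  n_bins <- n_fft %/% 2 + 1L
  bin_freqs <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(fmin_hz), hz_to_mel(fmax_hz), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)

  w <- matrix(0, n_mels, n_bins)
  for (k in seq_len(n_mels)) {
    lo <- hz_pts[k]; ce <- hz_pts[k + 1]; hi <- hz_pts[k + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    w[k, ] <- pmax(0, pmin(up, down))
  }
  if (norm == "area") {
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  structure(
    list(weights = w, n_mels = as.integer(n_mels), fmin_hz = fmin_hz,
         fmax_hz = fmax_hz, center_freqs_hz = hz_pts[2:(n_mels + 1)],
         sample_rate = sample_rate, n_fft = as.integer(n_fft)),
    class = "mel_filterbank"
  )
}

#' @export
print.mel_filterbank <- function(x, ...) {
  cat(sprintf("<mel_filterbank> %d filters over %g-%g Hz (%d bins @ %d Hz)\n",
              x$n_mels, x$fmin_hz, x$fmax_hz, ncol(x$weights), x$sample_rate))
  invisible(x)
}

#' Project a magnitude spectrogram onto a Mel filterbank
#'
#' The Mel spectrum is the matrix product of the filter weights with the
#' magnitude spectrogram.
#'
#' @param spec A `spectrogram` from [stft_magnitude()], or a plain
#'   non-negative magnitude matrix (bins x frames).
#' @param fb A [mel_filterbank()] with a matching bin count.
#' @return Non-negative `n_mels x n_frames` matrix.
#' @export
mel_spectrogram <- function(spec, fb) {
  stopifnot(inherits(fb, "mel_filterbank"))
  mag <- if (inherits(spec, "spectrogram")) spec$magnitude else spec
  if (!is.matrix(mag)) stopf("`spec` must be a spectrogram or a magnitude matrix")
  if (ncol(fb$weights) != nrow(mag)) {
    stopf("filterbank expects %d bins but spectrogram has %d",
          ncol(fb$weights), nrow(mag))
  }
  fb$weights %*% mag
}

#' Log compression of a Mel spectrum
#'
#' Entrywise `log(1 + x)` (natural log by default), which balances the
#' dynamic range while keeping every value non-negative. The base is
#' configurable; because the Log-Mel ACI is a ratio of same-base sums, a
#' base change rescales its numerator and denominator identically per
#' entry but the compression shape itself is base-independent only up to
#' that constant, so the base is pinned in one place here.
#'
#' @param mel Non-negative matrix (e.g. from [mel_spectrogram()]).
#' @param base Logarithm base (default `exp(1)`).
#' @return Matrix of the same shape, entries `>= 0`.
#' @export
log_compress <- function(mel, base = exp(1)) {
  if (!is.matrix(mel)) mel <- as.matrix(mel)
  if (any(mel < 0)) stopf("negative Mel-spectrum entries; upstream invariant violated")
  log1p(mel) / log(base)
}

#' Mel-frequency cepstral coefficients
#'
#' DCT-II of the log filterbank energies:
#' `C_n(t) = sum_{m=0}^{M-1} log(E_m(t) + eps) * cos(n (m + 0.5) pi / M)`
#' for `n = 0 .. n_coeffs - 1`, where `M` is the number of Mel bands.
#'
#' @param mel Non-negative `M x n_frames` Mel-spectrum matrix.
#' @param n_coeffs Number of cepstral coefficients (default 13; at most `M`).
#' @param log_floor_eps Floor added inside the log (default 1e-10).
#' @return `n_coeffs x n_frames` coefficient matrix.
#' @export
mfcc <- function(mel, n_coeffs = 13L, log_floor_eps = 1e-10) {
  if (!is.matrix(mel)) mel <- as.matrix(mel)
  M <- nrow(mel)
  if (n_coeffs > M) stopf("n_coeffs (%d) exceeds the number of Mel bands (%d)", n_coeffs, M)
  logE <- log(mel + log_floor_eps)
  n <- seq_len(n_coeffs) - 1L
  m <- seq_len(M) - 1L
  D <- cos(outer(n, m + 0.5) * pi / M)  # n_coeffs x M
  D %*% logE
}

#' Regression delta coefficients
#'
#' Windowed slope estimate
#' `delta_t = sum_{n=-N}^{N} n * C_{t+n} / (2 * sum_{n=1}^{N} n^2)`
#' applied along time, with replicate-padded edges so the output has the
#' input's shape. `N` is typically 1 (central difference) or 2. Applying
#' it twice yields the delta-delta (second-order) coefficients.
#'
#' @param coeffs Coefficient matrix (rows = coefficients, cols = frames),
#'   with at least 2 frames.
#' @param N Half-window width, 1 or 2 (default 2).
#' @return Matrix of the same shape.
#' @export
delta_coeffs <- function(coeffs, N = 2L) {
  if (!is.matrix(coeffs)) coeffs <- as.matrix(coeffs)
  if (!N %in% c(1L, 2L)) stopf("`N` must be 1 or 2")
  T_ <- ncol(coeffs)
  if (T_ < 2) stopf("need at least 2 frames for delta coefficients")
  pad <- coeffs[, c(rep(1L, N), seq_len(T_), rep(T_, N)), drop = FALSE]
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, nrow(coeffs), T_)
  for (n in seq_len(N)) {
    out <- out + n * (pad[, seq_len(T_) + N + n, drop = FALSE] -
                        pad[, seq_len(T_) + N - n, drop = FALSE])
  }
  out / denom
}

#' Second-order MFCC feature stack
#'
#' Runs the full feature chain STFT magnitude -> Mel projection -> MFCC ->
#' delta -> delta-delta and returns all three matrices.
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()] object.
#' @param n_mels Number of Mel filters (default 20).
#' @param n_coeffs Number of cepstral coefficients (default 13).
#' @param fmin_hz,fmax_hz Filterbank band edges (defaults 0 and Nyquist).
#' @param delta_width Half-window `N` for the delta operator (default 2).
#' @return An object of class `mfcc_matrix` with fields `coeffs`, `delta`,
#'   `delta2` (all `n_coeffs x n_frames`), `delta_width_N` and
#'   `frame_times`.
#' @export
second_order_mfcc <- function(signal, params = frame_params(), n_mels = 20L,
                              n_coeffs = 13L, fmin_hz = 0, fmax_hz = NULL,
                              delta_width = 2L) {
  sp <- stft_magnitude(signal, params)
  fb <- mel_filterbank(n_mels, params$frame_length, signal$sample_rate,
                       fmin_hz, fmax_hz)
  mel <- mel_spectrogram(sp, fb)
  c0 <- mfcc(mel, n_coeffs)
  d1 <- delta_coeffs(c0, delta_width)
  d2 <- delta_coeffs(d1, delta_width)
  structure(
    list(coeffs = c0, delta = d1, delta2 = d2,
         delta_width_N = as.integer(delta_width), frame_times = sp$frame_times),
    class = "mfcc_matrix"
  )
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d coefficients x %d frames (+ delta, delta2; N = %d)\n",
              nrow(x$coeffs), ncol(x$coeffs), x$delta_width_N))
  invisible(x)
}
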