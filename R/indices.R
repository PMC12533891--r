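# Acoustic complexity indices.
#
# The traditional Acoustic Complexity Index (Pieretti ratio form) sums, per
# frequency bin, the absolute frame-to-frame intensity differences
# normalized by that bin's total intensity within a clump of frames. The
# Log-Mel variant computes the analogous difference-to-sum ratio per time
# frame on a log(1 + x)-compressed 20-band Mel spectrogram, making it
# sensitive to vocal rhythm (syllable rate, call intervals) rather than raw
# intensity fluctuation.

new_aci_series <- function(per_frame, index_kind, aggregation, n_frames,
                           silent_frames = NA_integer_, clump_frames = NA_integer_) {
  aggregate <- switch(aggregation,
    mean = if (length(per_frame)) mean(per_frame) else 0,
    sum = sum(per_frame)
  )
  structure(
    list(per_frame = per_frame, aggregate = aggregate, index_kind = index_kind,
         aggregation = aggregation, n_frames = as.integer(n_frames),
         silent_frames = as.integer(silent_frames),
         clump_frames = clump_frames),
    class = "aci_series"
  )
}

#' @export
print.aci_series <- function(x, ...) {
  cat(sprintf("<aci_series> %s ACI: aggregate (%s) = %.6g over %d value(s)%s\n",
              x$index_kind, x$aggregation, x$aggregate, length(x$per_frame),
              if (!is.na(x$silent_frames) && x$silent_frames > 0)
                sprintf(" [%d silent frame(s)]", x$silent_frames) else ""))
  invisible(x)
}

#' Tidy an ACI series into a tibble
#'
#' @param x An `aci_series`.
#' @param ... Unused.
#' @return A tibble with one row per per-frame (or per-clump) value.
#' @export
tidy.aci_series <- function(x, ...) {
  tibble::tibble(
    index_kind = x$index_kind,
    step = seq_along(x$per_frame),
    value = as.numeric(x$per_frame)
  )
}

#' One-row summary of an ACI series
#'
#' @param x An `aci_series`.
#' @param ... Unused.
#' @return A one-row tibble with the aggregate and bookkeeping counts.
#' @export
glance.aci_series <- function(x, ...) {
  tibble::tibble(
    index_kind = x$index_kind, aggregate = x$aggregate,
    aggregation = x$aggregation, n_frames = x$n_frames,
    silent_frames = x$silent_frames
  )
}

#' Traditional Acoustic Complexity Index
#'
#' For each clump of consecutive frames and each frequency bin `b`,
#' `D_b = sum_t |I_b(t+1) - I_b(t)|` and the clump's index is
#' `sum_b D_b / sum_t I_b(t)` (bins whose intensity sum is zero contribute
#' 0). The ratio makes the index invariant to global amplitude scaling.
#' The default clump is the whole recording, which suits short single
#' vocalizations; pass `clump_frames` to window longer material.
#'
#' `literal_eq9 = TRUE` switches to the non-normalized product form
#' `D * sum I` sometimes printed for this index; it is provided for
#' auditability only and is not scale-invariant.
#'
#' @param spec A `spectrogram` from [stft_magnitude()] or a non-negative
#'   intensity matrix (bins x frames) with at least 2 frames.
#' @param clump_frames Frames per clump (`NULL` = all frames, else >= 2;
#'   a trailing partial clump is kept if it spans at least 2 frames).
#' @param aggregation `"mean"` (default) or `"sum"` over clump values.
#' @param literal_eq9 Use the product form (default `FALSE`).
#' @return An `aci_series` with one `per_frame` value per clump and the
#'   aggregated recording-level value in `aggregate`.
#' @export
aci_traditional <- function(spec, clump_frames = NULL,
                            aggregation = c("mean", "sum"),
                            literal_eq9 = FALSE) {
  aggregation <- match.arg(aggregation)
  I <- if (inherits(spec, "spectrogram")) spec$magnitude else spec
  if (!is.matrix(I)) stopf("`spec` must be a spectrogram or an intensity matrix")
  T_ <- ncol(I)
  if (T_ < 2) stopf("need at least 2 frames to compute intensity differences")
  if (is.null(clump_frames)) clump_frames <- T_
  if (!is_count(clump_frames) || clump_frames < 2) {
    stopf("`clump_frames` must be an integer >= 2")
  }
  starts <- seq(1L, T_, by = clump_frames)
  vals <- numeric(0)
  for (s in starts) {
    e <- min(s + clump_frames - 1L, T_)
    if (e - s + 1L < 2L) next  # a 1-frame tail has no differences
    sub <- I[, s:e, drop = FALSE]
    D_b <- rowSums(abs(sub[, -1, drop = FALSE] - sub[, -ncol(sub), drop = FALSE]))
    S_b <- rowSums(sub)
    vals <- c(vals, if (literal_eq9) sum(D_b) * sum(S_b)
              else sum(ifelse(S_b > 0, D_b / S_b, 0)))
  }
  new_aci_series(vals, "traditional", aggregation, T_,
                 clump_frames = clump_frames)
}

#' Per-frame Log-Mel ACI values
#'
#' For each frame transition `t -> t+1`, the per-band absolute differences
#' `d_k(t) = |LogMel(k, t+1) - LogMel(k, t)|` are summed over the Mel
#' bands `k` and normalized by the frame's band sum:
#' `ACI(t) = sum_k d_k(t) / sum_k LogMel(k, t)`. Frames whose band sum is
#' below `eps` (silence) yield 0 and are counted in `silent_frames`
#' rather than dividing by a vanishing denominator.
#'
#' @param lm Log-Mel matrix (`n_mels x n_frames`, entries >= 0, at least
#'   2 frames), e.g. from [log_compress()].
#' @param eps Silence guard on the denominator (default 1e-12).
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @return An `aci_series` with `T - 1` per-frame values.
#' @export
logmel_aci_frames <- function(lm, eps = 1e-12, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  if (!is.matrix(lm)) lm <- as.matrix(lm)
  T_ <- ncol(lm)
  if (T_ < 2) stopf("need at least 2 frames to compute frame differences")
  d <- abs(lm[, -1, drop = FALSE] - lm[, -T_, drop = FALSE])
  num <- colSums(d)
  den <- colSums(lm[, -T_, drop = FALSE])
  silent <- den < eps
  vals <- ifelse(silent, 0, num / den)
  new_aci_series(vals, "logmel", aggregation, T_, silent_frames = sum(silent))
}

#' Log-Mel ACI of a recording
#'
#' Full chain: STFT magnitude -> 20-band triangular Mel filterbank ->
#' `log(1 + x)` compression -> per-frame difference-to-sum ratio ->
#' recording-level aggregate. The mean aggregation (default) is
#' duration-invariant, which cross-period comparisons require.
#'
#' With centered frames the half-frame zero padding creates onset/offset
#' transients at the first and last frames; `trim_edges = TRUE` (default)
#' excludes those frames from the index so a steady tone scores ~0.
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()] object.
#' @param n_mels Number of Mel filters (default 20).
#' @param fmin_hz,fmax_hz Filterbank band (defaults 0 and Nyquist).
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @param trim_edges Drop frames whose window overlaps the center padding
#'   (default `TRUE`; only applies when `params$center`).
#' @param log_base Base of the compression log (default natural).
#' @return An `aci_series` with `index_kind = "logmel"`.
#' @export
logmel_aci <- function(signal, params = frame_params(), n_mels = 20L,
                       fmin_hz = 0, fmax_hz = NULL,
                       aggregation = c("mean", "sum"), trim_edges = TRUE,
                       log_base = exp(1)) {
  aggregation <- match.arg(aggregation)
  sp <- stft_magnitude(signal, params)
  fb <- mel_filterbank(n_mels, params$frame_length, signal$sample_rate,
                       fmin_hz, fmax_hz)
  lm <- log_compress(mel_spectrogram(sp, fb), base = log_base)
  if (trim_edges && params$center) {
    k <- n_edge_frames(params)
    if (ncol(lm) > 2 * k + 1) {
      lm <- lm[, (k + 1):(ncol(lm) - k), drop = FALSE]
    }
  }
  logmel_aci_frames(lm, aggregation = aggregation)
}
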