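# Diel-period comparison of acoustic indices (the dawn / noon / night
# analysis).

DIEL_PERIODS <- c("dawn", "noon", "night")

#' Compare an acoustic index across diel periods
#'
#' Computes the recording-level index aggregate for every labeled
#' recording, then summarizes mean, standard deviation and count per
#' (species, period) group and orders the periods by mean within each
#' species.
#'
#' @param recordings A tibble/data.frame with a list-column `signal` of
#'   [audio_signal()]s and character columns `species` and `period`
#'   (levels among `"dawn"`, `"noon"`, `"night"`), e.g. the `recordings`
#'   element of [gen_diel_dataset()].
#' @param index_kind `"logmel"` (default) or `"traditional"`.
#' @param params A [frame_params()] object used for both indices.
#' @param n_mels Mel bands for the Log-Mel index (default 20).
#' @param aggregation Recording-level aggregation, `"mean"` (default,
#'   duration-invariant) or `"sum"`.
#' @param ... Further arguments passed to [logmel_aci()] or
#'   [aci_traditional()].
#' @return An object of class `diel_comparison`: a list with
#'   `per_recording` (tibble: species, period, aggregate, n_frames,
#'   silent_frames), `per_group` (tibble: species, period, mean_index,
#'   sd_index, n), `orderings` (named list, species -> periods in
#'   descending mean order) and `index_kind`.
#' @export
compare_periods <- function(recordings, index_kind = c("logmel", "traditional"),
                            params = frame_params(), n_mels = 20L,
                            aggregation = c("mean", "sum"), ...) {
  index_kind <- match.arg(index_kind)
  aggregation <- match.arg(aggregation)
  recordings <- tibble::as_tibble(recordings)
  stopifnot(all(c("signal", "species", "period") %in% names(recordings)))
  bad <- setdiff(unique(recordings$period), DIEL_PERIODS)
  if (length(bad)) stopf("unknown period label(s): %s", paste(bad, collapse = ", "))

  rows <- lapply(seq_len(nrow(recordings)), function(i) {
    sig <- recordings$signal[[i]]
    series <- if (index_kind == "logmel") {
      logmel_aci(sig, params = params, n_mels = n_mels,
                 aggregation = aggregation, ...)
    } else {
      aci_traditional(stft_magnitude(sig, params), aggregation = aggregation, ...)
    }
    tibble::tibble(
      species = recordings$species[i], period = recordings$period[i],
      aggregate = series$aggregate, n_frames = series$n_frames,
      silent_frames = series$silent_frames
    )
  })
  per_recording <- dplyr::bind_rows(rows)

  per_group <- per_recording |>
    dplyr::group_by(.data$species, .data$period) |>
    dplyr::summarise(
      mean_index = mean(.data$aggregate),
      sd_index = stats::sd(.data$aggregate),
      n = dplyr::n(),
      .groups = "drop"
    )
  empty <- setdiff(
    as.vector(outer(unique(per_recording$species), DIEL_PERIODS, paste)),
    paste(per_group$species, per_group$period)
  )
  if (length(empty)) {
    warnf("excluded empty group(s): %s", paste(empty, collapse = "; "))
  }

  orderings <- lapply(split(per_group, per_group$species), function(g) {
    g$period[order(-g$mean_index)]
  })

  structure(
    list(per_recording = per_recording, per_group = per_group,
         orderings = orderings, index_kind = index_kind),
    class = "diel_comparison"
  )
}

#' @export
print.diel_comparison <- function(x, ...) {
  cat(sprintf("<diel_comparison> %s ACI over %d recordings, %d species\n",
              x$index_kind, nrow(x$per_recording), length(x$orderings)))
  print(x$per_group)
  for (sp in names(x$orderings)) {
    cat(sprintf("  %s: %s\n", sp, paste(x$orderings[[sp]], collapse = " > ")))
  }
  invisible(x)
}

#' Tidy a diel comparison
#'
#' @param x A `diel_comparison`.
#' @param ... Unused.
#' @return The per-group summary tibble with the index kind attached.
#' @export
tidy.diel_comparison <- function(x, ...) {
  dplyr::mutate(x$per_group, index_kind = x$index_kind, .before = 1)
}

#' Normalized between-period spread per species
#'
#' Effect-size style contrast: for each species,
#' `(max period mean - min period mean) / pooled within-group sd`. Larger
#' values mean the index separates the diel periods more cleanly relative
#' to its within-period variability.
#'
#' @param comparison A `diel_comparison` from [compare_periods()].
#' @return A tibble with `species` and `spread`.
#' @export
diel_spread <- function(comparison) {
  stopifnot(inherits(comparison, "diel_comparison"))
  comparison$per_group |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      spread = {
        pooled <- sqrt(sum((.data$n - 1) * .data$sd_index^2) / sum(.data$n - 1))
        if (pooled > 0) (max(.data$mean_index) - min(.data$mean_index)) / pooled else Inf
      },
      .groups = "drop"
    )
}

#' Bar chart of per-group index means
#'
#' Grouped bar chart (one bar per diel period within each species) with
#' one-standard-deviation error bars, in the style used to contrast the
#' traditional and Log-Mel indices across the diel cycle.
#'
#' @param object A `diel_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diel_comparison <- function(object, ...) {
  d <- dplyr::mutate(object$per_group,
                     period = factor(.data$period, levels = DIEL_PERIODS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$mean_index,
                                  fill = .data$period)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_index - .data$sd_index,
                   ymax = .data$mean_index + .data$sd_index),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(
      y = sprintf("%s ACI (recording mean)", object$index_kind),
      x = NULL, fill = "period",
      title = sprintf("Diel comparison of the %s ACI", object$index_kind)
    ) +
    ggplot2::theme_minimal()
}
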