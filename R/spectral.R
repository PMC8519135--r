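#' Per-night amplitude spectrum of a nocturnal glucose window
#'
#' Removes the window mean, applies the discrete Fourier transform and
#' converts bin moduli to sinusoid amplitudes as `2 * |X_k| / n` for bins
#' `k = 1 .. n/2` (the same factor is used at the Nyquist bin). Bin `k`
#' corresponds to `k` cycles per window, i.e. a frequency of
#' `k / window_hours` cycles per hour: a bin-aligned sinusoid of amplitude
#' `A` is recovered as exactly `A` in its bin and 0 elsewhere. No taper is
#' applied by default (`taper = "none"`); a Hann taper (amplitude-corrected)
#' is available for leakage-heavy inputs.
#'
#' @param x A numeric vector of glucose values on a uniform grid, or a CGM
#'   trace/tibble with a `glucose` column.
#' @param cadence_min Sampling interval in minutes (taken from the trace when
#'   available).
#' @param taper `"none"` (default) or `"hann"`.
#' @return A tibble with one row per bin `k = 1 .. floor(n/2)`: `k`
#'   (cycles per window), `frequency_cph` (cycles/hour), `amplitude`
#'   (mmol/L). Attributes `n`, `cadence_min`, `window_hours`.
#' @examples
#' t <- seq(0, 4, by = 5 / 60)[1:48]
#' sp <- amplitude_spectrum(5 + sin(2 * pi * t), cadence_min = 5)
#' sp[sp$amplitude > 0.5, ] # one component: 1 cycle/h, amplitude 1
#' @export
amplitude_spectrum <- function(x, cadence_min = NULL, taper = c("none", "hann")) {
  taper <- match.arg(taper)
  if (is.data.frame(x) && is.null(cadence_min)) cadence_min <- trace_cadence(x)
  if (is.null(cadence_min)) cadence_min <- 5
  v <- glucose_values(x)
  n <- length(v)
  if (n < 8) stop("window too short for spectral analysis (n < 8)", call. = FALSE)

  centred <- v - mean(v)
  if (taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    centred <- centred * w / mean(w) # amplitude correction
  }
  X <- stats::fft(centred)
  half <- floor(n / 2)
  k <- seq_len(half)
  window_hours <- n * cadence_min / 60

  out <- tibble::tibble(
    k = k,
    frequency_cph = k / window_hours,
    amplitude = 2 * Mod(X[k + 1]) / n
  )
  attr(out, "n") <- n
  attr(out, "cadence_min") <- cadence_min
  attr(out, "window_hours") <- window_hours
  out
}

#' Detect frequency components in an amplitude spectrum
#'
#' A component is a local maximum of the amplitude vector at or above the
#' detection threshold; the local-maximum requirement stops spectral-leakage
#' side lobes of a non-bin-aligned component from being counted as extra
#' frequencies. The dominant component is the one of maximal amplitude, ties
#' broken toward the lower frequency. Raising the threshold never increases
#' the number of components.
#'
#' @param spectrum Output of [amplitude_spectrum()].
#' @param threshold Detection threshold, mmol/L. Default
#'   `max(0.2, 0.2 * peak amplitude)`.
#' @return The component rows of the spectrum with an added `cycles_per_night`
#'   column and a logical `dominant` flag; zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_components <- function(spectrum, threshold = NULL) {
  amp <- spectrum$amplitude
  if (is.null(threshold)) threshold <- max(0.2, 0.2 * max(amp, 0))
  n <- length(amp)
  left <- c(-Inf, amp[-n])
  right <- c(amp[-1], -Inf)
  is_peak <- amp >= left & amp >= right & amp >= threshold
  out <- spectrum[is_peak, ]
  wh <- attr(spectrum, "window_hours")
  out$cycles_per_night <- out$frequency_cph * wh
  if (nrow(out) > 0) {
    best <- which(out$amplitude == max(out$amplitude))[1] # lower freq on ties
    out$dominant <- seq_len(nrow(out)) == best
  } else {
    out$dominant <- logical(0)
  }
  attr(out, "threshold") <- threshold
  attr(out, "window_hours") <- wh
  out
}

#' Night-by-night spectrogram of the nocturnal window
#'
#' Stacks the per-night amplitude spectra of the clock window across all
#' nights in the trace: the data product behind a waterfall spectrogram in
#' which good glucose management shows as low dominant frequency, few
#' components and small amplitude. Nights failing the completeness policy
#' (see [nights_of()]) are excluded and listed in the `excluded` attribute.
#'
#' @param trace A CGM trace.
#' @param window Nocturnal [clock_window()].
#' @param threshold Component-detection threshold passed to
#'   [detect_components()].
#' @param min_completeness Minimum fraction of expected samples per night.
#' @param taper Passed to [amplitude_spectrum()].
#' @return A `cgm_spectrogram` tibble in long format: `night`, `k`,
#'   `frequency_cph`, `amplitude`, plus logical `component` and `dominant`
#'   flags on detected bins.
#' @export
build_spectrogram <- function(trace, window = clock_window(), threshold = NULL,
                              min_completeness = 0.8, taper = "none") {
  nights <- nights_of(trace, window, min_completeness)
  excluded <- nights[!nights$complete, c("night", "n", "expected")]
  if (nrow(excluded) > 0) {
    message(
      nrow(excluded), " night(s) excluded as incomplete: ",
      paste(format(excluded$night), collapse = ", ")
    )
  }
  keep <- nights[nights$complete, ]
  rows <- purrr::map2(keep$night, keep$data, function(d, tr) {
    sp <- amplitude_spectrum(tr, taper = taper)
    comp <- detect_components(sp, threshold)
    sp$night <- d
    sp$component <- sp$k %in% comp$k
    sp$dominant <- sp$k %in% comp$k[comp$dominant]
    sp
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("no eligible nights; empty spectrogram", call. = FALSE)
    out <- tibble::tibble(
      night = as.Date(character(0)), k = integer(0),
      frequency_cph = numeric(0), amplitude = numeric(0),
      component = logical(0), dominant = logical(0)
    )
  } else {
    out <- dplyr::relocate(out, "night")
  }
  structure(out,
    class = c("cgm_spectrogram", class(tibble::tibble())),
    window = window, threshold = threshold, excluded = excluded
  )
}

#' Per-night stability summary
#'
#' The three spectral outcome parameters per night: the dominant frequency
#' (cycles/hour and cycles per night), the number of detected frequency
#' components, and the dominant amplitude. No composite score is formed.
#'
#' @param spectrogram Output of [build_spectrogram()].
#' @return A tibble with one row per night: `night`, `dominant_frequency_cph`,
#'   `dominant_cycles_per_night`, `n_frequencies`, `dominant_amplitude`.
#'   Nights with no detected component carry `NA` frequency/amplitude and
#'   `n_frequencies = 0`.
#' @export
stability_summary <- function(spectrogram) {
  if (nrow(spectrogram) == 0) {
    stop("empty spectrogram", call. = FALSE)
  }
  win <- attr(spectrogram, "window")
  wh <- ((win$end_min - win$start_min) %% (24 * 60)) / 60
  tibble::as_tibble(spectrogram) |>
    dplyr::group_by(.data$night) |>
    dplyr::summarise(
      dominant_frequency_cph = if (any(.data$dominant)) {
        .data$frequency_cph[.data$dominant][1]
      } else {
        NA_real_
      },
      n_frequencies = sum(.data$component),
      dominant_amplitude = if (any(.data$dominant)) {
        .data$amplitude[.data$dominant][1]
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dominant_cycles_per_night = .data$dominant_frequency_cph * wh,
      .after = "dominant_frequency_cph"
    )
}

#' Plot a spectrogram
#'
#' Waterfall-style tile plot: nights on the x axis, frequency (cycles/hour)
#' on the y axis, colour encoding amplitude.
#'
#' @param object A `cgm_spectrogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cgm_spectrogram <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$night, y = .data$frequency_cph, fill = .data$amplitude)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "turbo", name = "amplitude\n(mmol/L)") +
    ggplot2::labs(x = "night", y = "frequency (cycles/hour)")
}
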