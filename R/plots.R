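#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_ribbon
#'   geom_hline geom_point geom_col scale_fill_viridis_c labs theme_minimal
#'   facet_wrap coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a spectrogram as a time-frequency heat map
#'
#' @param object A `spectral_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time, y = .data$freq,
                           fill = .data$power_db)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Power (dB)") +
    labs(x = "Time (s)", y = "Frequency (Hz)",
         title = if (object$n_subjects > 1)
           paste0("Group-median spectrogram (n = ", object$n_subjects, ")")
         else "Multitaper spectrogram") +
    theme_minimal()
}

#' Plot a coherogram
#'
#' @param object A `coherogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coherogram <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time, y = .data$freq,
                           fill = .data$coherence)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Coherence", limits = c(0, 1)) +
    labs(x = "Time (s)", y = "Frequency (Hz)") +
    theme_minimal()
}

#' Plot a group-median power spectrum with its IQR envelope
#'
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$freq)) +
    geom_ribbon(aes(ymin = .data$p25_db, ymax = .data$p75_db),
                alpha = 0.3, fill = "steelblue") +
    geom_line(aes(y = .data$median_db), color = "steelblue") +
    labs(x = "Frequency (Hz)", y = "Power (dB)",
         title = paste0("Group-median spectrum",
                        if (!is.na(attr(object, "group") %||% NA))
                          paste0(" (", attr(object, "group"), ")") else "")) +
    theme_minimal()
}

#' Plot a bootstrap difference with its confidence envelope
#'
#' @param object A `bootstrap_ci`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_ci <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot(object, aes(x = .data$freq)) +
    geom_ribbon(aes(ymin = .data$lower_db, ymax = .data$upper_db),
                alpha = 0.3, fill = "firebrick") +
    geom_line(aes(y = .data$observed_db)) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "Frequency (Hz)", y = "Difference (dB)",
         title = paste0("Bootstrap ", cfg$ci_level, "% CI (",
                        cfg$n_replicates, " replicates",
                        if (cfg$paired) ", paired" else "", ")")) +
    theme_minimal()
}

#' Plot a global coherence spectrum
#'
#' @param object A `global_coherence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.global_coherence <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$freq, y = .data$c_global)) +
    geom_line() +
    labs(x = "Frequency (Hz)", y = expression(C[global])) +
    theme_minimal()
}

#' Scalp map of a per-electrode table
#'
#' Plots electrode values at azimuthal-equidistant projected positions
#' (nose up), one panel per selected column — a numeric stand-in for 3-D
#' interpolated scalp maps.
#'
#' @param values Tibble with an `electrode` column plus numeric columns
#'   (e.g. [band_power_topography()] or [spatial_coherence_map()] output).
#' @param montage The montage giving electrode positions.
#' @param bands Columns to plot (default: all numeric columns).
#' @return A ggplot.
#' @export
plot_topography <- function(values, montage = default_montage(),
                            bands = NULL) {
  if (is.null(bands)) {
    bands <- setdiff(names(values)[vapply(values, is.numeric, TRUE)],
                     "electrode")
  }
  pos <- montage$positions
  idx <- match(values$electrode, pos$label)
  xy <- project_azimuthal(pos[idx, ])
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(values, tibble::tibble(px = xy[, 1], py = xy[, 2])),
    cols = dplyr::all_of(bands), names_to = "band", values_to = "value")
  long$band <- factor(long$band, levels = bands)
  ggplot(long, aes(x = .data$px, y = .data$py, color = .data$value)) +
    geom_point(size = 5) +
    scale_fill_viridis_c() +
    ggplot2::scale_color_viridis_c(name = "value") +
    facet_wrap(~band) +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot emergence band power and movement fraction by concentration bin
#'
#' @param band_power `group_median` tibble from [band_power_by_bin()].
#' @param movement Output of [movement_fraction_by_bin()] (optional).
#' @param bands Band columns to draw.
#' @return A ggplot.
#' @export
plot_emergence <- function(band_power, movement = NULL,
                           bands = c("slow", "delta", "theta", "alpha")) {
  mid <- (band_power$lo + band_power$hi) / 2
  long <- tidyr::pivot_longer(
    dplyr::mutate(band_power, conc = mid),
    cols = dplyr::all_of(bands), names_to = "band", values_to = "power_db")
  p <- ggplot(long, aes(x = .data$conc, y = .data$power_db,
                        color = .data$band)) +
    geom_line() + geom_point() +
    labs(x = "End-tidal sevoflurane (%)", y = "Median band power (dB)") +
    theme_minimal()
  if (!is.null(movement)) {
    sc <- diff(range(long$power_db, na.rm = TRUE))
    base <- min(long$power_db, na.rm = TRUE)
    mv <- dplyr::mutate(movement, conc = (movement$lo + movement$hi) / 2)
    p <- p + geom_col(data = mv,
                      aes(x = .data$conc,
                          y = base + .data$movement_fraction * sc),
                      inherit.aes = FALSE, alpha = 0.2, width = 0.25)
  }
  p
}
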