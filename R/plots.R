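#' Plot methods
#'
#' `autoplot()` methods for the package's result types: the RR tachogram of
#' a beat series (artifact-flagged beats highlighted), the stylized
#' action-potential waveform, variability sweeps, averaged power spectra
#' with the LF/HF bands shaded, and the band-power summary of an
#' [hrv_spectral()] fit.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name hrvmech-autoplot
NULL

#' @rdname hrvmech-autoplot
#' @export
autoplot.beat_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$rr_ms)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$valid), size = 0.6,
                        show.legend = !all(object$valid)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 name = "normal beat") +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)",
                  title = "RR tachogram") +
    ggplot2::theme_minimal()
}

#' @rdname hrvmech-autoplot
#' @export
autoplot.ap_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$vm_mv,
                                       colour = .data$phase,
                                       group = .data$beat)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  title = "Sinoatrial action-potential model",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname hrvmech-autoplot
#' @export
autoplot.hrv_sweep <- function(object, ...) {
  vary <- attr(object, "vary")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("dhp_ms", "dhr_bpm"),
                              names_to = "measure", values_to = "value")
  labs <- c(dhp_ms = "ΔHP (ms)", dhr_bpm = "ΔHR (bpm)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[vary]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(
      x = if (vary == "dm") "Δm (mV/ms)" else "ΔMP (mV)",
      y = NULL, title = "Peak-to-trough variability sweep") +
    ggplot2::theme_minimal()
}

#' @rdname hrvmech-autoplot
#' @param bands Shade the LF/HF bands (default TRUE).
#' @param max_freq Truncate the frequency axis (Hz, default 0.5).
#' @export
autoplot.hrv_psd <- function(object, bands = TRUE, max_freq = 0.5, ...) {
  rep <- attr(object, "representation") %||% "hp"
  unit <- if (rep == "hr") "bpm²/Hz" else "ms²/Hz"
  df <- dplyr::filter(tibble::as_tibble(object), .data$freq_hz <= max_freq)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power))
  if (bands) {
    shade <- tibble::tibble(band = c("LF", "HF"),
                            xmin = c(0.04, 0.15), xmax = c(0.15, 0.40))
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$band))
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = paste0("PSD (", unit, ")"),
                  title = sprintf("Averaged power spectrum (%s series)",
                                  toupper(rep)), fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname hrvmech-autoplot
#' @export
autoplot.hrv_spectral <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(label = paste0(toupper(.data$band), "_",
                                 toupper(.data$representation)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$power,
                                   fill = .data$representation)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~representation, scales = "free",
                        labeller = ggplot2::as_labeller(
                          c(hp = "heart period (ms²)",
                            hr = "heart rate (bpm²)"))) +
    ggplot2::labs(x = NULL, y = "band power",
                  title = "LF/HF band powers by series representation") +
    ggplot2::theme_minimal()
}
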