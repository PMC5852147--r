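#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_hline
#'   geom_vline scale_fill_gradient2 coord_equal labs theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Plot a field-map frame
#'
#' Raster map of one field component at one time frame, on a diverging
#' scale centred at zero.
#'
#' @param object An `ms_field_map`.
#' @param component `"bx_nT"`, `"by_nT"`, `"bz_nT"` or `"phi_mV"`.
#' @param frame Time-frame index (default: peak |B_X| frame).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_field_map <- function(object, component = "bx_nT", frame = NULL, ...) {
  df <- tidy(object, frame = frame)
  ggplot(df, aes(.data$x_um, .data$y_um, fill = .data[[component]])) +
    geom_raster() +
    scale_fill_gradient2() +
    coord_equal() +
    labs(
      x = "x (µm)", y = "y (µm)", fill = component,
      title = sprintf("%s at t = %.2f ms", component, df$time_ms[1])
    ) +
    theme_minimal()
}

#' Plot a reconstruction point-spread function
#'
#' @param object An `ms_reconstruction`.
#' @param ... Unused.
#' @return A ggplot raster of the PSF with its FWHM annotated.
#' @export
autoplot.ms_reconstruction <- function(object, ...) {
  M <- object$pixels
  x <- (seq_len(M) - (floor(M / 2) + 1)) * object$delta_um
  df <- tibble(
    x_um = rep(x, times = M), y_um = rep(x, each = M),
    j = as.vector(object$psf)
  )
  ggplot(df, aes(.data$x_um, .data$y_um, fill = .data$j)) +
    geom_raster() +
    scale_fill_gradient2() +
    coord_equal() +
    labs(
      x = "x (µm)", y = "y (µm)", fill = "j (nA/µm²)",
      title = sprintf("PSF: FWHM %.3g µm, pSNR %.3g",
                      object$fwhm_um, object$psnr)
    ) +
    theme_minimal()
}

#' Plot a cumulative power spectrum
#'
#' @param object An `ms_spectrum`.
#' @param threshold Power-fraction threshold to annotate.
#' @param ... Unused.
#' @return A ggplot of cumulative power fraction vs frequency.
#' @export
autoplot.ms_spectrum <- function(object, threshold = 0.95, ...) {
  fc <- f_cutoff(object, threshold)
  ggplot(as_tibble(object), aes(.data$frequency_hz, .data$cumulative_fraction)) +
    geom_line() +
    geom_hline(yintercept = threshold, linetype = 2) +
    geom_vline(xintercept = fc, linetype = 3) +
    labs(
      x = "frequency (Hz)", y = "cumulative power fraction",
      title = sprintf("%.0f%% of power below %.3g Hz", 100 * threshold, fc)
    ) +
    theme_minimal()
}

#' Plot a resolution scan
#'
#' FWHM (or pSNR) versus pixel size, one curve per noise level.
#'
#' @param scan A [resolution_scan()] tibble.
#' @param metric `"fwhm_um"` or `"psnr"`.
#' @return A ggplot.
#' @export
plot_resolution_scan <- function(scan, metric = c("fwhm_um", "psnr")) {
  metric <- match.arg(metric)
  ggplot(scan, aes(.data$delta_um, .data[[metric]],
                   colour = factor(.data$eta), group = .data$eta)) +
    geom_line() +
    labs(
      x = "pixel size Δ (µm)",
      y = if (metric == "fwhm_um") "PSF FWHM (µm)" else "pSNR",
      colour = "η (nT·µm)"
    ) +
    theme_minimal()
}
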