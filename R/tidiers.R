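#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reconstruction result
#'
#' @param x An `ms_reconstruction`.
#' @param ... Unused.
#' @return One-row tibble with the scalar characterisation of the
#'   reconstruction (pixel size, noise level, FWHM, pSNR, peak, noise std).
#' @export
tidy.ms_reconstruction <- function(x, ...) {
  tibble(
    delta_um = x$delta_um, eta = x$noise$eta, fwhm_um = x$fwhm_um,
    psnr = x$psnr, peak = x$peak, noise_std = x$noise_std,
    z0_um = x$source$z0, d_um = x$source$d, sigma_j = x$source$sigma_j
  )
}

#' @rdname tidy.ms_reconstruction
#' @export
glance.ms_reconstruction <- tidy.ms_reconstruction

#' Tidy an equivalent-current-dipole series
#'
#' @param x An `ms_ecd`.
#' @param ... Unused.
#' @return Tibble with time (if available), dipole components (pA·m) and
#'   magnitude.
#' @export
tidy.ms_ecd <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$Q))
  out$magnitude <- x$magnitude
  if (!is.null(x$time_ms)) out <- dplyr::bind_cols(tibble(time_ms = x$time_ms), out)
  out
}

#' Tidy per-compartment activity into long format
#'
#' @param x An `ms_activity`.
#' @param ... Unused.
#' @return Long tibble with `compartment`, `time_ms`, `vm_mV`, `im_nA`,
#'   `i_axial_nA`.
#' @export
tidy.ms_activity <- function(x, ...) {
  n <- nrow(x$Vm)
  Tn <- length(x$time_ms)
  tibble(
    compartment = rep(seq_len(n), times = Tn),
    time_ms = rep(x$time_ms, each = n),
    vm_mV = as.vector(x$Vm),
    im_nA = as.vector(x$Im),
    i_axial_nA = as.vector(x$I_axial)
  )
}

#' Tidy a field map into long pixel format
#'
#' @param x An `ms_field_map`.
#' @param frame Time-frame index (default: frame of peak |B_X|).
#' @param ... Unused.
#' @return Long tibble with pixel centres, `bx_nT`, `by_nT`, `bz_nT`,
#'   `phi_mV` for the chosen frame.
#' @export
tidy.ms_field_map <- function(x, frame = NULL, ...) {
  if (is.null(frame)) frame <- which.max(apply(abs(x$BX), 3, max))
  cx <- x$grid$centers
  tibble(
    x_um = rep(cx, times = length(cx)),
    y_um = rep(cx, each = length(cx)),
    time_ms = x$time_ms[frame],
    bx_nT = as.vector(x$BX[, , frame]),
    by_nT = as.vector(x$BY[, , frame]),
    bz_nT = as.vector(x$BZ[, , frame]),
    phi_mV = as.vector(x$phi[, , frame])
  )
}

#' Summarise a scenario result
#'
#' @param x An `ms_result`.
#' @param ... Unused.
#' @return One-row tibble with the headline numbers of the run: peak |B_X|,
#'   peak population dipole, bandwidth recommendation and reconstruction
#'   characterisation.
#' @export
glance.ms_result <- function(x, ...) {
  tibble(
    n_cells = x$meta$n_cells %||% nrow(attr(x$population, "cells")),
    peak_bx_nT = x$meta$peak_bx_nT,
    peak_ecd_pAm = x$meta$peak_ecd_pAm,
    f_cutoff_hz = x$bandwidth$f_cutoff_hz,
    recommended_fs_hz = x$bandwidth$recommended_fs_hz,
    fwhm_um = x$reconstruction$fwhm_um,
    psnr = x$reconstruction$psnr
  )
}
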