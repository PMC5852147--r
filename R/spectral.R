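#' Cumulative power spectrum of a signal
#'
#' Computes a one-sided periodogram of the (demeaned, optionally
#' Hann-windowed) signal and returns the cumulative fraction of total AC
#' power below each frequency. The DC component is excluded: the cumulative
#' curves characterise signal dynamics, and any constant offset is a
#' measurement artefact, not signal. A constant input therefore has no
#' definable spectrum and raises an error.
#'
#' @param x Numeric time series (length >= 16).
#' @param fs Sampling rate of `x`, Hz.
#' @param window `"hann"` (default) or `"rect"`. The rectangular window
#'   makes the periodogram exactly Parseval-consistent with the time-domain
#'   variance.
#' @return A tibble of class `ms_spectrum` with columns `frequency_hz`,
#'   `power` (one-sided periodogram) and `cumulative_fraction`
#'   (non-decreasing, ending at 1); the total AC power is stored in the
#'   `total_power` attribute.
#' @export
cumulative_power <- function(x, fs, window = c("hann", "rect")) {
  window <- match.arg(window)
  check_positive(fs, "fs")
  n <- length(x)
  if (n < 16) abort("signal must have at least 16 samples")
  xd <- x - mean(x)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  X <- fft(xd * w)
  # two-sided power normalised so that the bins sum to the mean square of
  # the (window-compensated) signal
  p2 <- Mod(X)^2 / (n^2 * mean(w^2))
  half <- floor(n / 2)
  freq <- (0:half) * fs / n
  p1 <- p2[1:(half + 1)]
  if (n %% 2 == 0) {
    p1[2:half] <- 2 * p1[2:half] # Nyquist bin unpaired
  } else {
    p1[2:(half + 1)] <- 2 * p1[2:(half + 1)]
  }
  p1 <- p1[-1] # drop DC
  freq <- freq[-1]
  total <- sum(p1)
  if (total <= .Machine$double.eps * n * max(1, mean(x)^2)) {
    abort("signal has no AC power (constant input)")
  }
  out <- tibble(
    frequency_hz = freq,
    power = p1,
    cumulative_fraction = cumsum(p1) / total
  )
  structure(out, class = c("ms_spectrum", class(tibble())),
            total_power = total, fs = fs, window = window)
}

#' Cut-off frequency containing a given fraction of signal power
#'
#' @param spectrum An [cumulative_power()] result.
#' @param threshold Power fraction in (0, 1); default 0.95 defines "most of
#'   the signal power".
#' @return The smallest frequency (Hz) whose cumulative power fraction
#'   reaches the threshold.
#' @export
f_cutoff <- function(spectrum, threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  spectrum$frequency_hz[which(spectrum$cumulative_fraction >= threshold)[1]]
}

#' Nyquist sampling-rate recommendation
#'
#' Twice the cut-off frequency that retains the requested fraction of
#' signal power: e.g. a 400 Hz cut-off implies sampling at 800 Hz, a 150 Hz
#' cut-off implies 300 Hz.
#'
#' @inheritParams f_cutoff
#' @return Recommended sampling rate, Hz.
#' @export
recommended_sampling_rate <- function(spectrum, threshold = 0.95) {
  2 * f_cutoff(spectrum, threshold)
}

#' Third-order Butterworth low-pass filter
#'
#' Standard Butterworth magnitude response (maximally flat pass band, half
#' power at `fc`), applied as a causal single pass by default, matching a
#' real-time acquisition chain; `zero_phase = TRUE` uses forward-backward
#' filtering instead.
#'
#' @param x Numeric signal.
#' @param fc Cut-off (half-power) frequency, Hz; must satisfy
#'   `0 < fc < fs/2`.
#' @param fs Sampling rate, Hz.
#' @param order Filter order.
#' @param zero_phase Use `signal::filtfilt()` instead of a causal pass.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fc, fs, order = 3, zero_phase = FALSE) {
  check_positive(fs, "fs")
  if (fc <= 0 || fc >= fs / 2) {
    abort("`fc` must lie strictly between 0 and fs/2")
  }
  bt <- signal::butter(order, fc / (fs / 2), type = "low")
  if (zero_phase) {
    signal::filtfilt(bt, x)
  } else {
    as.numeric(signal::filter(bt, x))
  }
}
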