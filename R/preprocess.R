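#' Remove the mean amplitude of a signal
#'
#' @param signal non-empty numeric vector.
#' @return the signal with its arithmetic mean subtracted.
#' @export
remove_mean <- function(signal) {
  if (length(signal) == 0L) stop("signal is empty")
  signal - mean(signal)
}

# Gaussian smoothing kernel, unit area, truncated at +/- 3 sigma
gaussian_kernel <- function(sigma_s, fs) {
  half <- max(1L, round(3 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-0.5 * (t / sigma_s)^2)
  k / sum(k)
}

#' Condition one bipolar channel into a smooth activation envelope
#'
#' Replaces the complex morphology of a bipolar electrogram with a smooth,
#' nonnegative train of Gaussian-shaped pulses that mark the active
#' intervals of the channel, without extracting activation times. The
#' realization is: zero-phase band-pass (Butterworth order 3,
#' forward-backward, reflect-padded), full-wave rectification, convolution
#' with a Gaussian kernel, and per-channel peak normalization.
#'
#' @param signal single-channel amplitude series (mV).
#' @param fs sampling frequency (Hz).
#' @param band_hz band-pass corners in Hz; default `c(40, 250)` brackets the
#'   deflection energy of bipolar atrial electrograms while rejecting
#'   far-field T-wave and baseline drift.
#' @param sigma_s Gaussian kernel standard deviation in seconds (default
#'   0.02 s, i.e. one pulse lobe per local activation complex).
#' @param normalize peak-normalize the envelope to 1 (default `TRUE`).
#' @param pad_s reflect-padding length in seconds for the zero-phase filter
#'   (default 0.5 s).
#' @return An object of class `pulse_train`: list with `values` (nonnegative
#'   envelope, peak 1 for a non-silent channel), `fs`, and `silent` flag.
#' @export
condition_channel <- function(signal, fs, band_hz = c(40, 250),
                              sigma_s = 0.02, normalize = TRUE,
                              pad_s = 0.5) {
  if (fs <= 0) stop("fs must be positive")
  if (length(signal) < fs) {
    stop("signal must be at least 1 s long (", ceiling(fs), " samples)")
  }
  if (all(signal == 0)) {
    log_warn("silent channel: all-zero input, returning all-zero envelope")
    return(structure(list(values = numeric(length(signal)), fs = fs,
                          silent = TRUE), class = "pulse_train"))
  }
  nyq <- fs / 2
  bw <- signal::butter(3, c(band_hz[1L], min(band_hz[2L], 0.99 * nyq)) / nyq,
                       type = "pass")
  npad <- min(length(signal) - 1L, round(pad_s * fs))
  padded <- c(rev(signal[seq_len(npad) + 1L]), signal,
              rev(signal[length(signal) - seq_len(npad)]))
  filt <- signal::filtfilt(bw, padded)
  filt <- filt[npad + seq_along(signal)]
  env <- conv_same(abs(filt), gaussian_kernel(sigma_s, fs))
  env[env < 0] <- 0  # FFT convolution round-off can leave tiny negatives
  if (normalize) {
    peak <- max(env)
    if (peak > 0) env <- env / peak
  }
  structure(list(values = env, fs = fs, silent = FALSE),
            class = "pulse_train")
}

#' Condition every channel of a segment
#'
#' @param segment an [egm_segment].
#' @param ... passed to [condition_channel()].
#' @return list of `pulse_train`, one per channel.
#' @export
condition_segment <- function(segment, ...) {
  stopifnot(inherits(segment, "egm_segment"))
  lapply(seq_len(nrow(segment$samples)), function(k) {
    condition_channel(segment$samples[k, ], segment$fs, ...)
  })
}
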