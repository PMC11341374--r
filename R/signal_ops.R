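# Low-level signal primitives shared by all detectors. All operate
# per channel, independently, and are deterministic.

apply_channels <- function(rec, fun) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) out$data[i, ] <- fun(rec$data[i, ])
  out
}

butter_sos <- function(order, w, type) {
  signal::butter(order, w, type = type)
}

#' Zero-phase Butterworth filtering
#'
#' Forward-backward (two-pass) Butterworth filter of order 4 per pass,
#' applied independently to each channel. Zero-phase filtering avoids
#' shifting event boundaries in time.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz. For `bandpass`,
#'   `0 <= low_hz < high_hz < ` Nyquist; for `highpass`, `0 < low_hz <` Nyquist.
#' @param order Filter order per pass (default 4).
#' @return A filtered `scrub_recording`.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4) {
  nyq <- rec$sample_rate_hz / 2
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    abort("Require 0 <= low_hz < high_hz.")
  }
  if (high_hz >= nyq) {
    abort(sprintf("Band edge high_hz = %g Hz is at or above Nyquist (%g Hz).",
                  high_hz, nyq))
  }
  if (low_hz == 0) {
    flt <- butter_sos(order, high_hz / nyq, "low")
  } else {
    flt <- butter_sos(order, c(low_hz, high_hz) / nyq, "pass")
  }
  apply_channels(rec, function(x) as.numeric(signal::filtfilt(flt, x)))
}

#' @rdname bandpass
#' @export
highpass <- function(rec, low_hz, order = 4) {
  nyq <- rec$sample_rate_hz / 2
  if (!(low_hz > 0 && low_hz < nyq)) {
    abort(sprintf("Band edge low_hz = %g Hz must lie in (0, Nyquist = %g Hz).",
                  low_hz, nyq))
  }
  flt <- butter_sos(order, low_hz / nyq, "high")
  apply_channels(rec, function(x) as.numeric(signal::filtfilt(flt, x)))
}

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones, inverse-transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal, optionally smoothed with a centered
#' moving average of length `smooth_s` seconds (`0` disables smoothing).
#' The default of 1 s suppresses the sampling fluctuations of the raw
#' magnitude, so that z-score thresholds respond to sustained amplitude
#' changes (artifacts last on the order of seconds) rather than to momentary
#' envelope noise.
#'
#' @param rec A [recording()].
#' @param smooth_s Moving-average length in seconds (default 1).
#' @return A `scrub_recording` holding the envelope.
#' @export
envelope <- function(rec, smooth_s = 1) {
  k <- max(1L, round(smooth_s * rec$sample_rate_hz))
  if (smooth_s == 0) k <- 1L
  apply_channels(rec, function(x) moving_average(Mod(analytic_signal(x)), k))
}

#' Per-channel z-scoring
#'
#' Subtracts each channel's mean and divides by its population standard
#' deviation (computed over all samples of that channel). A zero-variance
#' channel yields all zeros, so no threshold can fire on it.
#'
#' @param rec A [recording()].
#' @param robust Use median / MAD (scaled for normal consistency) instead of
#'   mean / SD.
#' @return A standardized `scrub_recording`.
#' @export
zscore_per_channel <- function(rec, robust = FALSE) {
  apply_channels(rec, function(x) {
    if (robust) {
      ctr <- median(x)
      sc <- stats::mad(x, center = ctr)
    } else {
      ctr <- mean(x)
      sc <- sqrt(mean((x - ctr)^2))
    }
    if (sc == 0) return(numeric(length(x)))
    (x - ctr) / sc
  })
}

#' Absolute first difference (signal gradient)
#'
#' `|x[i+1] - x[i]|` in microvolts per sample; the final value is repeated so
#' the output length matches the input.
#'
#' @param rec A [recording()].
#' @return A `scrub_recording` of absolute gradients.
#' @export
gradient_abs <- function(rec) {
  apply_channels(rec, function(x) {
    d <- abs(diff(x))
    c(d, d[length(d)])
  })
}

#' Running median filter
#'
#' Running median of odd `order`; edges are handled with shrinking windows
#' (via `stats::runmed(endrule = "median")`). `order = 1` is the identity.
#'
#' @param rec A [recording()].
#' @param order Odd positive window length in samples.
#' @return A median-filtered `scrub_recording`.
#' @export
median_filter <- function(rec, order) {
  if (order < 1 || order %% 2 == 0) {
    abort("`order` must be an odd positive integer.")
  }
  if (order == 1) return(rec)
  apply_channels(rec, function(x) as.numeric(runmed(x, order, endrule = "median")))
}

#' Threshold crossings as time intervals
#'
#' Maximal runs of samples satisfying the comparison become half-open
#' intervals in seconds (sample `i`, 0-based, covers `[i/fs, (i+1)/fs)`).
#' Runs shorter than `min_duration_s` are discarded; with `min_duration_s = 0`
#' every qualifying run of at least one sample survives.
#'
#' @param x Numeric vector (one channel of a processed signal).
#' @param fs Sample rate in Hz.
#' @param cmp `"gt"` or `"lt"`.
#' @param threshold Finite comparison threshold.
#' @param min_duration_s Minimum run duration in seconds.
#' @return Tibble with columns `start_s`, `end_s` (sorted, disjoint).
#' @export
threshold_intervals <- function(x, fs, cmp = c("gt", "lt"), threshold,
                                min_duration_s = 0) {
  cmp <- match.arg(cmp)
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  hit <- if (cmp == "gt") x > threshold else x < threshold
  hit[is.na(hit)] <- FALSE
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= min_duration_s)
  tibble::tibble(start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}

#' Pad and merge intervals
#'
#' Each interval is extended by `padding_s` on both sides and clipped to
#' `[0, duration_s]`; intervals separated by a gap strictly smaller than
#' `merge_gap_s` are then merged. Output is sorted and disjoint.
#'
#' @param intervals Tibble with `start_s`, `end_s`.
#' @param padding_s Symmetric padding in seconds (>= 0).
#' @param merge_gap_s Gaps strictly below this merge (>= 0).
#' @param duration_s Recording duration for clipping.
#' @return Tibble with `start_s`, `end_s`.
#' @export
pad_and_merge <- function(intervals, padding_s, merge_gap_s, duration_s) {
  if (padding_s < 0 || merge_gap_s < 0) {
    abort("`padding_s` and `merge_gap_s` must be nonnegative.")
  }
  if (!nrow(intervals)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  s <- pmax(intervals$start_s - padding_s, 0)
  e <- pmin(intervals$end_s + padding_s, duration_s)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (!length(s)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  out_s <- s[1L]; out_e <- e[1L]
  res_s <- numeric(); res_e <- numeric()
  for (i in seq_along(s)[-1L]) {
    if (s[i] - out_e < merge_gap_s) {
      out_e <- max(out_e, e[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- s[i]; out_e <- e[i]
    }
  }
  tibble::tibble(start_s = c(res_s, out_s), end_s = c(res_e, out_e))
}
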