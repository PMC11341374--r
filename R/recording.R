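#' Continuous multichannel EEG recording
#'
#' Bundles a channels-by-samples numeric matrix (amplitudes in microvolts,
#' stored at 64-bit precision) with its sample rate and channel labels. Only
#' continuous signal is represented; epoching/trial structure is produced
#' downstream by [select_clean()].
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param channel_labels Character vector of unique labels, one per row.
#' @param start_time_s Recording start time in seconds (default 0). All event
#'   and scoring times are relative to this origin.
#' @param allow_na Permit NA samples (used by NaN-fill repair); by default all
#'   samples must be finite.
#'
#' @return An object of class `scrub_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(500), 2), 250, c("C3", "C4"))
#' n_samples(rec)
recording <- function(data, sample_rate_hz, channel_labels = rownames(data),
                      start_time_s = 0, allow_na = FALSE) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` must have one entry per data row.")
  }
  if (anyDuplicated(channel_labels)) {
    abort(paste0("Duplicate channel labels: ",
                 paste(unique(channel_labels[duplicated(channel_labels)]),
                       collapse = ", ")))
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a single positive number.")
  }
  if (!allow_na && !all(is.finite(data))) {
    abort("Recording data contains non-finite samples.")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sample_rate_hz = as.numeric(sample_rate_hz),
         channel_labels = channel_labels,
         start_time_s = as.numeric(start_time_s)),
    class = "scrub_recording"
  )
}

#' @export
print.scrub_recording <- function(x, ...) {
  cat(sprintf("<scrub_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz, duration_s(x)))
  cat("  channels:", paste(head(x$channel_labels, 8L), collapse = ", "),
      if (length(x$channel_labels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param x A `scrub_recording`.
#' @return Integer sample count or duration in seconds.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname n_samples
#' @export
duration_s <- function(x) ncol(x$data) / x$sample_rate_hz

#' Subset a recording by channel
#' @param x A `scrub_recording`.
#' @param channels Labels to keep (order preserved as given).
#' @return A `scrub_recording` with the selected channels.
#' @export
subset_channels <- function(x, channels) {
  missing <- setdiff(channels, x$channel_labels)
  if (length(missing)) {
    abort(paste0("Unknown channels: ", paste(missing, collapse = ", ")))
  }
  recording(x$data[channels, , drop = FALSE], x$sample_rate_hz, channels,
            x$start_time_s, allow_na = TRUE)
}

# Map a time in seconds to the 0-based index of the sample covering it.
# Sample i covers [i/fs, (i+1)/fs).
time_to_sample <- function(t_s, fs) floor(t_s * fs + 1e-9)

#' Read a recording from disk
#'
#' Supports 16-bit EDF (`format = "edf"`) and a plain-text matrix with a JSON
#' sidecar (`format = "matrix"`): a CSV with one column per channel (header =
#' channel labels, rows = samples, values in microvolts) accompanied by
#' `<path>.json` containing at least `sample_rate_hz` and optionally
#' `start_time_s`.
#'
#' @param path File path.
#' @param format `"edf"` or `"matrix"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("Matrix sidecar not found: ", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sample_rate_hz)) {
    abort("Matrix sidecar is missing required field `sample_rate_hz`.")
  }
  df <- read.csv(path, check.names = FALSE)
  recording(t(as.matrix(df)), meta$sample_rate_hz, colnames(df),
            start_time_s = meta$start_time_s %||% 0)
}

#' Write a recording as CSV matrix + JSON sidecar
#' @param x A `scrub_recording`.
#' @param path Output CSV path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(x, path) {
  df <- as.data.frame(t(x$data))
  names(df) <- x$channel_labels
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(sample_rate_hz = x$sample_rate_hz, start_time_s = x$start_time_s),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
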