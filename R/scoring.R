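#' Sleep scoring (hypnogram)
#'
#' An ordered sequence of sleep-stage labels over fixed-length scoring epochs
#' (conventionally 30 s). Epoch `e` (0-based) covers
#' `[offset_s + e * epoch_length_s, offset_s + (e + 1) * epoch_length_s)`;
#' time outside the scored range has stage `"unknown"`.
#'
#' @param stages Character vector over `W, N1, N2, N3, R, unknown`.
#' @param epoch_length_s Epoch length in seconds (default 30).
#' @param offset_s Start of the first epoch relative to the recording origin.
#' @return An object of class `scrub_scoring`.
#' @export
scoring <- function(stages, epoch_length_s = 30, offset_s = 0) {
  stages <- as.character(stages)
  if (!length(stages)) abort("`stages` must be nonempty.")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad)) {
    abort(paste0("Unknown stage labels: ", paste(bad, collapse = ", "),
                 " (expected ", paste(STAGE_LEVELS, collapse = "/"), ")"))
  }
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    abort("`epoch_length_s` must be positive.")
  }
  structure(list(stages = stages, epoch_length_s = as.numeric(epoch_length_s),
                 offset_s = as.numeric(offset_s)),
            class = "scrub_scoring")
}

#' @export
print.scrub_scoring <- function(x, ...) {
  cat(sprintf("<scrub_scoring> %d epochs x %g s (offset %g s)\n",
              length(x$stages), x$epoch_length_s, x$offset_s))
  print(table(factor(x$stages, STAGE_LEVELS)))
  invisible(x)
}

#' Default hypnogram token aliases
#'
#' Maps common scoring-file tokens (AASM and R&K numeric codes, spelled-out
#' names) onto the canonical stage labels.
#' @return Named character vector (token -> stage).
#' @export
default_stage_aliases <- function() {
  c("W" = "W", "0" = "W", "WAKE" = "W", "WK" = "W",
    "N1" = "N1", "1" = "N1", "S1" = "N1",
    "N2" = "N2", "2" = "N2", "S2" = "N2",
    "N3" = "N3", "3" = "N3", "4" = "N3", "S3" = "N3", "S4" = "N3", "SWS" = "N3",
    "R" = "R", "REM" = "R", "5" = "R",
    "UNKNOWN" = "unknown", "?" = "unknown", "A" = "unknown", "MT" = "unknown")
}

#' Read a hypnogram from a plain-text file
#'
#' One stage token per line (or per row of a single-column CSV). Tokens are
#' matched case-insensitively against `aliases`; unmatched tokens map to
#' `"unknown"` with a warning.
#'
#' @param path File path.
#' @param epoch_length_s Epoch length in seconds (default 30).
#' @param offset_s Start of the first epoch (seconds, default 0).
#' @param aliases Named token -> stage map; see [default_stage_aliases()].
#' @return A [scoring()].
#' @export
read_scoring <- function(path, epoch_length_s = 30, offset_s = 0,
                         aliases = default_stage_aliases()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tokens <- trimws(readLines(path, warn = FALSE))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) abort(paste0("Empty hypnogram file: ", path))
  mapped <- unname(aliases[toupper(tokens)])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warn(paste0("Unrecognized stage tokens mapped to 'unknown': ",
                paste(unique(tokens[unknown]), collapse = ", ")))
    mapped[unknown] <- "unknown"
  }
  scoring(mapped, epoch_length_s, offset_s)
}

#' Stage at given times
#'
#' @param scoring A [scoring()], or NULL (everything `"unknown"`).
#' @param t_s Numeric vector of times in seconds.
#' @return Character vector of stage labels.
#' @export
stage_at <- function(scoring, t_s) {
  if (is.null(scoring)) return(rep("unknown", length(t_s)))
  e <- floor((t_s - scoring$offset_s) / scoring$epoch_length_s)
  out <- rep("unknown", length(t_s))
  ok <- e >= 0 & e < length(scoring$stages)
  out[ok] <- scoring$stages[e[ok] + 1L]
  out
}

#' Per-sample stage labels for a recording
#' @param scoring A [scoring()] or NULL.
#' @param n_samples Number of samples.
#' @param fs Sample rate in Hz.
#' @return Character vector of length `n_samples`.
#' @export
stage_per_sample <- function(scoring, n_samples, fs) {
  stage_at(scoring, (seq_len(n_samples) - 1L) / fs)
}
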