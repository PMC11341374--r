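#' Channel-resolved artifact event table
#'
#' The tabular currency of the package: one row per detected (or injected, or
#' manually annotated) event, with half-open time intervals `[start_s, end_s)`
#' in seconds from the recording origin. Events not tied to one channel use
#' the [GLOBAL_CHANNEL] sentinel.
#'
#' @param channel,start_s,end_s,event_type,detector Column vectors (recycled
#'   to a common length by [tibble::tibble()]).
#' @return A tibble of class `scrub_events` with those five columns.
#' @export
#' @examples
#' event_table("C3", 10, 12.5, "highamp", "highamp")
event_table <- function(channel = character(), start_s = numeric(),
                        end_s = numeric(), event_type = character(),
                        detector = event_type) {
  tbl <- tibble::tibble(channel = as.character(channel),
                        start_s = as.numeric(start_s),
                        end_s = as.numeric(end_s),
                        event_type = as.character(event_type),
                        detector = as.character(detector))
  validate_events(tbl)
}

validate_events <- function(tbl, channels = NULL) {
  stopifnot(all(c("channel", "start_s", "end_s", "event_type", "detector")
                %in% names(tbl)))
  bad <- which(!(tbl$start_s < tbl$end_s))
  if (length(bad)) {
    abort(paste0("Event rows with start_s >= end_s: ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  if (!is.null(channels)) {
    unk <- setdiff(unique(tbl$channel), c(channels, GLOBAL_CHANNEL))
    if (length(unk)) {
      abort(paste0("Events reference unknown channels: ",
                   paste(unk, collapse = ", ")))
    }
  }
  class(tbl) <- unique(c("scrub_events", class(tbl)))
  tbl
}

#' Write / read an event table as CSV
#'
#' Plain CSV with header `channel,start_s,end_s,event_type,detector`; times
#' are written with 6 decimal places, so a round trip is lossless at that
#' precision.
#'
#' @param events A [event_table()].
#' @param path File path.
#' @return `path` invisibly (write); a `scrub_events` tibble (read).
#' @export
write_event_table <- function(events, path) {
  events <- validate_events(tibble::as_tibble(events))
  out <- data.frame(channel = events$channel,
                    start_s = sprintf("%.6f", events$start_s),
                    end_s = sprintf("%.6f", events$end_s),
                    event_type = events$event_type,
                    detector = events$detector)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read.csv(path, colClasses = c("character", "character", "character",
                                      "character", "character"))
  start_s <- suppressWarnings(as.numeric(df$start_s))
  end_s <- suppressWarnings(as.numeric(df$end_s))
  bad <- which(is.na(start_s) | is.na(end_s))
  if (length(bad)) {
    abort(paste0("Malformed numeric field in event table row ", bad[1L]))
  }
  bad <- which(start_s >= end_s)
  if (length(bad)) {
    abort(paste0("start_s >= end_s in event table row ", bad[1L]))
  }
  event_table(df$channel, start_s, end_s, df$event_type, df$detector)
}

# Row-bind a list of event tables (possibly empty).
bind_events <- function(lst) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0, TRUE)]
  if (!length(lst)) return(event_table())
  validate_events(dplyr::bind_rows(lst))
}
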