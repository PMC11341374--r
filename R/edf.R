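# Minimal EDF (European Data Format) support: fixed-width ASCII header plus
# little-endian int16 data records. Restricted to what polysomnography
# pipelines here need: continuous recordings, identical sample rate across
# signals. Physical calibration uses a symmetric range per channel, so the
# write->read round trip is exact up to 16-bit quantization of that range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1L, width)
  edf_pad(trimws(s), width)
}

#' Write a recording to EDF
#'
#' @param x A [recording()]. The sample rate times `record_duration_s` must be
#'   an integer (samples per data record).
#' @param path Output path.
#' @param record_duration_s Data-record length in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, record_duration_s = 1) {
  fs <- x$sample_rate_hz
  spr <- fs * record_duration_s
  if (abs(spr - round(spr)) > 1e-9) {
    abort("sample_rate_hz * record_duration_s must be an integer for EDF.")
  }
  spr <- as.integer(round(spr))
  n_ch <- nrow(x$data)
  n_rec <- ceiling(ncol(x$data) / spr)
  # pad the tail with zeros to fill the last record
  dat <- cbind(x$data, matrix(0, n_ch, n_rec * spr - ncol(x$data)))
  phys_max <- pmax(apply(abs(dat), 1L, max), 1)  # symmetric range, >= 1 uV
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * n_ch, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(record_duration_s, 8), edf_pad(n_ch, 4),
    paste(vapply(x$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), n_ch), collapse = ""),
    paste(rep(edf_pad("uV", 8), n_ch), collapse = ""),
    paste(vapply(-phys_max, edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(-dig_max, 8), n_ch), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), n_ch), collapse = ""),
    paste(rep(edf_pad("", 80), n_ch), collapse = ""),
    paste(rep(edf_pad(spr, 8), n_ch), collapse = ""),
    paste(rep(edf_pad("", 32), n_ch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the rounded physical range so scaling matches what a reader sees
  phys_max_r <- as.numeric(vapply(phys_max, function(p) trimws(edf_num(p, 8)), ""))
  scale <- dig_max / phys_max_r
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- round(dat[, idx, drop = FALSE] * scale)
    block <- pmin(pmax(block, -dig_max), dig_max)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_s <- function(n) readChar(con, n, useBytes = TRUE)
  rd_n <- function(n, field) {
    s <- trimws(rd_s(n))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) abort(paste0("EDF header field `", field, "` is not numeric: '", s, "'"))
    v
  }
  rd_s(8 + 80 + 80 + 8 + 8)                       # version, ids, date, time
  rd_n(8, "header_bytes")
  rd_s(44)
  n_rec <- rd_n(8, "n_records")
  rec_dur <- rd_n(8, "record_duration")
  n_ch <- as.integer(rd_n(4, "n_signals"))
  if (n_ch < 1L) abort("EDF header field `n_signals` must be >= 1.")
  labels <- trimws(vapply(seq_len(n_ch), function(i) rd_s(16), ""))
  if (anyDuplicated(labels)) {
    abort(paste0("EDF header has duplicate signal labels: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  rd_s(80 * n_ch)                                  # transducer
  rd_s(8 * n_ch)                                   # physical dimension
  phys_min <- vapply(seq_len(n_ch), function(i) rd_n(8, "physical_min"), 0)
  phys_max <- vapply(seq_len(n_ch), function(i) rd_n(8, "physical_max"), 0)
  dig_min <- vapply(seq_len(n_ch), function(i) rd_n(8, "digital_min"), 0)
  dig_max <- vapply(seq_len(n_ch), function(i) rd_n(8, "digital_max"), 0)
  rd_s(80 * n_ch)                                  # prefiltering
  spr <- vapply(seq_len(n_ch), function(i) rd_n(8, "samples_per_record"), 0)
  rd_s(32 * n_ch)
  if (length(unique(spr)) != 1L) {
    abort("EDF with per-signal sample rates is not supported.")
  }
  spr <- as.integer(spr[1L])
  if (rec_dur <= 0) abort("EDF header field `record_duration` must be > 0.")
  fs <- spr / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  dat <- matrix(0, n_ch, n_rec * spr)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr, size = 2L,
                   endian = "little", signed = TRUE)
    if (length(raw) < n_ch * spr) abort("EDF data truncated before final record.")
    dat[, ((r - 1L) * spr + 1L):(r * spr)] <-
      matrix(raw, n_ch, spr, byrow = TRUE) * gain + offset
  }
  recording(dat, fs, labels)
}
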