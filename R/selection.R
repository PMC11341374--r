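#' Select clean data bouts by stage and minimum duration
#'
#' Keeps the time covered by the requested sleep stages and by non-rejected
#' grid segments, forms maximal uninterrupted runs ("bouts"), and drops runs
#' shorter than `min_duration_s`. Typical use: all bouts of at least 60 s of
#' clean N2. By default a transition between two *requested* stages (e.g. N2
#' to N3 with both requested) does not break a bout; set
#' `break_on_stage_change = TRUE` to split there too.
#'
#' @param rec A [recording()].
#' @param rejection Logical per-segment rejection vector (from
#'   [build_grid_set()]), or `NULL` for none.
#' @param segment_length_s Segment length the rejection vector refers to.
#' @param scoring A [scoring()]; may be `NULL` only with `stages = "ALL"`.
#' @param stages Character vector of stages to keep, or `"ALL"`.
#' @param min_duration_s Minimum bout duration in seconds.
#' @param mode `"trials"` (one data block per bout) or `"pseudocontinuous"`
#'   (blocks concatenated; the bout table records the boundaries).
#' @param strict Require duration strictly greater than `min_duration_s`
#'   instead of at least it.
#' @param break_on_stage_change Split bouts at every stage transition.
#' @return A list with `bouts` (tibble: `start_s`, `end_s`, `n_samples`,
#'   `stages`) and `data` (list of `scrub_recording` blocks for `"trials"`;
#'   a single concatenated `scrub_recording` for `"pseudocontinuous"`).
#' @export
select_clean <- function(rec, rejection = NULL, segment_length_s = 5,
                         scoring = NULL, stages = "ALL", min_duration_s = 0,
                         mode = c("trials", "pseudocontinuous"),
                         strict = FALSE, break_on_stage_change = FALSE) {
  mode <- match.arg(mode)
  if (!length(stages)) abort("`stages` must be nonempty (or \"ALL\").")
  fs <- rec$sample_rate_hz
  n <- n_samples(rec)
  t_mid <- (seq_len(n) - 0.5) / fs
  samp_stage <- stage_per_sample(scoring, n, fs)
  keep <- if (identical(stages, "ALL")) rep(TRUE, n) else samp_stage %in% stages
  if (!is.null(rejection) && any(rejection)) {
    seg <- pmin(floor(t_mid / segment_length_s) + 1L, length(rejection))
    keep <- keep & !rejection[seg]
  }
  run_id <- cumsum(c(TRUE, diff(as.integer(keep)) != 0))
  if (break_on_stage_change) {
    run_id <- cumsum(c(TRUE, (diff(as.integer(keep)) != 0) |
                         (samp_stage[-1L] != samp_stage[-n])))
  }
  bouts <- list()
  for (id in unique(run_id[keep])) {
    idx <- which(run_id == id)
    dur <- length(idx) / fs
    ok <- if (strict) dur > min_duration_s else dur >= min_duration_s
    if (!ok) next
    bouts[[length(bouts) + 1L]] <- tibble::tibble(
      start_s = (idx[1L] - 1L) / fs, end_s = idx[length(idx)] / fs,
      n_samples = length(idx),
      stages = paste(unique(samp_stage[idx]), collapse = ","))
  }
  bout_tbl <- if (length(bouts)) dplyr::bind_rows(bouts) else
    tibble::tibble(start_s = numeric(), end_s = numeric(),
                   n_samples = integer(), stages = character())
  blocks <- lapply(seq_len(nrow(bout_tbl)), function(i) {
    idx <- (time_to_sample(bout_tbl$start_s[i], fs) + 1L):
      (time_to_sample(bout_tbl$end_s[i] - 1e-9, fs) + 1L)
    recording(rec$data[, idx, drop = FALSE], fs, rec$channel_labels,
              start_time_s = bout_tbl$start_s[i], allow_na = TRUE)
  })
  if (mode == "trials") {
    return(list(bouts = bout_tbl, data = blocks))
  }
  dat <- if (length(blocks)) do.call(cbind, lapply(blocks, `[[`, "data")) else
    rec$data[, 0, drop = FALSE]
  list(bouts = bout_tbl,
       data = recording(dat, fs, rec$channel_labels, 0, allow_na = TRUE))
}

#' Write a bout table as CSV
#' @param bouts Bout tibble from [select_clean()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bout_table <- function(bouts, path) {
  write.csv(as.data.frame(bouts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
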