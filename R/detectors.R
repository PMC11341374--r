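#' Declarative artifact detector specification
#'
#' A detector is a recipe, not code: which channels and sleep stages to
#' consider, a chain of signal primitives to apply, and a detection
#' criterion. Channel-wise detectors threshold a processed per-sample signal;
#' pairwise detectors compute a pair metric (correlation or maximum absolute
#' difference) between a target channel and designated partners over
#' fixed-length windows.
#'
#' Chain steps are lists `list(op = <name>, ...)` with ops
#' `abs`, `bandpass(low_hz, high_hz)`, `highpass(low_hz)`,
#' `envelope(smooth_s)`, `zscore`, `gradient_abs`, `median_filter(order)`.
#'
#' @param name Unique detector name; also used as the emitted `event_type`.
#' @param scope `"channelwise"`, `"pairwise_local"` (partners from the
#'   layout's neighbor map) or `"pairwise_global"` (all other channels).
#' @param chain List of processing steps (channelwise: full chain;
#'   pairwise: optional preprocessing applied to all channels).
#' @param cmp,threshold,min_duration_s Channel-wise criterion: flag maximal
#'   runs where the processed signal is `gt`/`lt` the threshold, discarding
#'   runs shorter than `min_duration_s`.
#' @param window_s,pair_metric,pair_cmp,pair_threshold,neighbor_fraction
#'   Pairwise criterion: cut the recording into consecutive windows of
#'   `window_s` seconds (anchored at time 0, last partial window dropped);
#'   flag the target for a whole window when the fraction of evaluated
#'   partners whose `pair_metric` (`"pearson_r"` or `"max_abs_difference"`)
#'   satisfies `pair_cmp`/`pair_threshold` strictly exceeds
#'   `neighbor_fraction` (so `0` means "any partner").
#' @param padding_s,merge_gap_s Event padding and merge gap in seconds.
#' @param stages Stage subset to consider, or `"ALL"`.
#' @param channels Channel subset, or `"ALL"`.
#' @param min_channels Minimum channel count required to run (pairwise
#'   detectors are skipped with a warning below this).
#' @return An object of class `scrub_detector`.
#' @export
detector_spec <- function(name, scope = c("channelwise", "pairwise_local",
                                          "pairwise_global"),
                          chain = list(),
                          cmp = NULL, threshold = NULL, min_duration_s = 0,
                          window_s = NULL, pair_metric = NULL,
                          pair_cmp = NULL, pair_threshold = NULL,
                          neighbor_fraction = 0.5,
                          padding_s = 0, merge_gap_s = 0,
                          stages = "ALL", channels = "ALL",
                          min_channels = 1L) {
  scope <- match.arg(scope)
  if (scope == "channelwise") {
    if (is.null(cmp) || is.null(threshold)) {
      abort("Channel-wise detectors need `cmp` and `threshold`.")
    }
    cmp <- match.arg(cmp, c("gt", "lt"))
  } else {
    if (is.null(window_s) || window_s <= 0) {
      abort("Pairwise detectors need `window_s` > 0.")
    }
    pair_metric <- match.arg(pair_metric, c("pearson_r", "max_abs_difference"))
    pair_cmp <- match.arg(pair_cmp, c("gt", "lt"))
    if (is.null(pair_threshold)) abort("Pairwise detectors need `pair_threshold`.")
  }
  structure(list(name = name, scope = scope, chain = chain, cmp = cmp,
                 threshold = threshold, min_duration_s = min_duration_s,
                 window_s = window_s, pair_metric = pair_metric,
                 pair_cmp = pair_cmp, pair_threshold = pair_threshold,
                 neighbor_fraction = neighbor_fraction,
                 padding_s = padding_s, merge_gap_s = merge_gap_s,
                 stages = stages, channels = channels,
                 min_channels = as.integer(min_channels)),
            class = "scrub_detector")
}

#' Bundle detectors into a named set
#' @param ... `scrub_detector` objects.
#' @param name Set name.
#' @return A `scrub_detector_set` (list of detectors, unique names).
#' @export
detector_set <- function(..., name = "custom") {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "scrub_detector")) {
    specs <- specs[[1L]]
  }
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) abort("Detector names must be unique.")
  structure(stats::setNames(specs, nms), class = "scrub_detector_set",
            set_name = name)
}

#' @export
print.scrub_detector_set <- function(x, ...) {
  cat(sprintf("<scrub_detector_set '%s'> %d detectors: %s\n",
              attr(x, "set_name"), length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' The default nine-detector set
#'
#' Channel-wise detectors: `highamp` (|x| > 300 uV), `lowamp` (|x| < 5 uV for
#' at least 30 s), `lowfreq` (0.3-15 Hz envelope z > 8), `highfreq`
#' (60-120 Hz envelope z > 3), `jump` (median filter + absolute gradient
#' z > 25), `flatline` (absolute gradient < 1 uV for at least 1 s at 250 Hz).
#' Pairwise detectors: `deviant` (30 s windows, r < 0.3 for more than half of
#' the local neighbors), `similar` (30 s windows, any local neighbor with
#' max |difference| < 0.5 uV), `similar2` (5 s windows after 2 Hz high-pass,
#' r > 0.9 with more than half of all other channels).
#'
#' Sample-rate adjustments: the jump median-filter order scales as the
#' nearest odd integer to `9 * fs / 250`; the flatline gradient threshold
#' scales as `1 uV * 250 / fs`; the highfreq upper band edge is 120 Hz when
#' the Nyquist frequency exceeds 120 Hz and `0.95 * Nyquist` otherwise, and
#' the detector is omitted (with a warning) when that edge falls to 80 Hz or
#' below, so the returned set can have fewer than nine members at low sample
#' rates.
#'
#' @param sample_rate_hz Recording sample rate in Hz.
#' @return A `scrub_detector_set` (9 detectors at 250 Hz).
#' @export
default_detector_set <- function(sample_rate_hz = 250) {
  if (sample_rate_hz <= 0) abort("`sample_rate_hz` must be positive.")
  fs <- sample_rate_hz
  nyq <- fs / 2
  jump_order <- round((9 * fs / 250 - 1) / 2) * 2 + 1
  specs <- list(
    detector_spec("highamp", "channelwise",
                  chain = list(list(op = "abs")),
                  cmp = "gt", threshold = 300, min_duration_s = 0,
                  padding_s = 0.1, merge_gap_s = 1),
    detector_spec("lowamp", "channelwise",
                  chain = list(list(op = "abs")),
                  cmp = "lt", threshold = 5, min_duration_s = 30,
                  padding_s = 0.1, merge_gap_s = 1),
    detector_spec("lowfreq", "channelwise",
                  chain = list(list(op = "bandpass", low_hz = 0.3, high_hz = 15),
                               list(op = "envelope", smooth_s = 1),
                               list(op = "zscore")),
                  cmp = "gt", threshold = 8, min_duration_s = 0,
                  padding_s = 3, merge_gap_s = 1),
    detector_spec("highfreq", "channelwise",
                  chain = list(list(op = "bandpass", low_hz = 60,
                                    high_hz = if (nyq > 120) 120 else 0.95 * nyq),
                               list(op = "envelope", smooth_s = 1),
                               list(op = "zscore")),
                  cmp = "gt", threshold = 3, min_duration_s = 0,
                  padding_s = 0.1, merge_gap_s = 1),
    detector_spec("jump", "channelwise",
                  chain = list(list(op = "median_filter", order = jump_order),
                               list(op = "gradient_abs"),
                               list(op = "zscore")),
                  cmp = "gt", threshold = 25, min_duration_s = 0,
                  padding_s = 0.1, merge_gap_s = 1),
    detector_spec("flatline", "channelwise",
                  chain = list(list(op = "gradient_abs")),
                  cmp = "lt", threshold = 1 * 250 / fs, min_duration_s = 1,
                  padding_s = 0.1, merge_gap_s = 1),
    detector_spec("deviant", "pairwise_local",
                  window_s = 30, pair_metric = "pearson_r",
                  pair_cmp = "lt", pair_threshold = 0.3,
                  neighbor_fraction = 0.5,
                  padding_s = 0, merge_gap_s = 60, min_channels = 3L),
    detector_spec("similar", "pairwise_local",
                  window_s = 30, pair_metric = "max_abs_difference",
                  pair_cmp = "lt", pair_threshold = 0.5,
                  neighbor_fraction = 0,
                  padding_s = 0, merge_gap_s = 60, min_channels = 3L),
    detector_spec("similar2", "pairwise_global",
                  chain = list(list(op = "highpass", low_hz = 2)),
                  window_s = 5, pair_metric = "pearson_r",
                  pair_cmp = "gt", pair_threshold = 0.9,
                  neighbor_fraction = 0.5,
                  padding_s = 0, merge_gap_s = 5, min_channels = 2L)
  )
  hf_edge <- specs[[4L]]$chain[[1L]]$high_hz
  if (hf_edge <= 80) {
    warn(sprintf(paste0("highfreq detector omitted: achievable upper band ",
                        "edge %.1f Hz <= 80 Hz at fs = %g Hz."), hf_edge, fs))
    specs <- specs[-4L]
  }
  detector_set(specs, name = "default")
}

# Apply a chain step to a recording; `mask` marks stage-included samples and
# feeds the z-score statistics only (filters need signal continuity).
apply_chain <- function(rec, chain, mask = NULL) {
  for (step in chain) {
    rec <- switch(step$op,
      abs = apply_channels(rec, abs),
      bandpass = bandpass(rec, step$low_hz, step$high_hz),
      highpass = highpass(rec, step$low_hz),
      envelope = envelope(rec, step$smooth_s %||% 1),
      gradient_abs = gradient_abs(rec),
      median_filter = median_filter(rec, step$order),
      zscore = {
        if (is.null(mask) || all(mask)) {
          zscore_per_channel(rec)
        } else {
          apply_channels(rec, function(x) {
            ctr <- mean(x[mask])
            sc <- sqrt(mean((x[mask] - ctr)^2))
            if (sc == 0) numeric(length(x)) else (x - ctr) / sc
          })
        }
      },
      abort(paste0("Unknown chain op: ", step$op))
    )
  }
  rec
}

#' Run a single detector
#'
#' @param rec A [recording()].
#' @param spec A [detector_spec()].
#' @param scoring Optional [scoring()]; required when the spec restricts
#'   stages.
#' @param layout Optional [electrode_layout()]; required for
#'   `pairwise_local` scope.
#' @return A [event_table()] with `event_type = detector = spec$name`;
#'   `NULL` when the detector is skipped (too few channels), with a warning.
#' @export
run_detector <- function(rec, spec, scoring = NULL, layout = NULL) {
  chans <- if (identical(spec$channels, "ALL")) rec$channel_labels else
    intersect(spec$channels, rec$channel_labels)
  if (length(chans) < spec$min_channels) {
    warn(sprintf("Detector '%s' skipped: %d channel(s) < min_channels = %d.",
                 spec$name, length(chans), spec$min_channels))
    return(NULL)
  }
  sub <- subset_channels(rec, chans)
  mask <- NULL
  if (!identical(spec$stages, "ALL")) {
    if (is.null(scoring)) {
      abort(sprintf("Detector '%s' restricts stages but no scoring given.",
                    spec$name))
    }
    mask <- stage_per_sample(scoring, n_samples(sub), sub$sample_rate_hz) %in%
      spec$stages
  }
  dur <- duration_s(sub)
  if (spec$scope == "channelwise") {
    proc <- apply_chain(sub, spec$chain, mask)
    rows <- lapply(chans, function(ch) {
      x <- proc$data[ch, ]
      if (!is.null(mask)) {
        x[!mask] <- if (spec$cmp == "gt") -Inf else Inf
      }
      iv <- threshold_intervals(x, sub$sample_rate_hz, spec$cmp,
                                spec$threshold, spec$min_duration_s)
      iv <- pad_and_merge(iv, spec$padding_s, spec$merge_gap_s, dur)
      if (!nrow(iv)) return(NULL)
      event_table(ch, iv$start_s, iv$end_s, spec$name, spec$name)
    })
    return(bind_events(rows))
  }
  # pairwise
  if (spec$scope == "pairwise_local") {
    if (is.null(layout)) {
      abort(sprintf("Detector '%s' needs an electrode layout (local neighbors).",
                    spec$name))
    }
    partners <- lapply(chans, function(ch) intersect(layout$neighbor_map[[ch]], chans))
  } else {
    partners <- lapply(chans, function(ch) setdiff(chans, ch))
  }
  names(partners) <- chans
  proc <- if (length(spec$chain)) apply_chain(sub, spec$chain, mask) else sub
  fs <- sub$sample_rate_hz
  win_n <- as.integer(round(spec$window_s * fs))
  n_win <- n_samples(sub) %/% win_n
  flags <- matrix(FALSE, length(chans), n_win, dimnames = list(chans, NULL))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * win_n + 1L):(w * win_n)
    if (!is.null(mask)) {
      mid_t <- (idx[1L] - 1L + win_n / 2) / fs
      if (!(stage_at(scoring, mid_t) %in% spec$stages)) next
    }
    wdat <- proc$data[, idx, drop = FALSE]
    sds <- apply(wdat, 1L, function(v) sd(v))
    for (ch in chans) {
      prt <- partners[[ch]]
      if (!length(prt)) next
      if (spec$pair_metric == "pearson_r") {
        # zero-variance windows have undefined correlation; drop those partners
        if (sds[ch] == 0) next
        prt <- prt[sds[prt] > 0]
        if (!length(prt)) next
        vals <- as.numeric(cor(wdat[ch, ], t(wdat[prt, , drop = FALSE])))
      } else {
        vals <- apply(abs(wdat[prt, , drop = FALSE] -
                            matrix(wdat[ch, ], length(prt), win_n, byrow = TRUE)),
                      1L, max)
      }
      meets <- if (spec$pair_cmp == "gt") vals > spec$pair_threshold else
        vals < spec$pair_threshold
      if (mean(meets) > spec$neighbor_fraction) flags[ch, w] <- TRUE
    }
  }
  rows <- lapply(chans, function(ch) {
    w <- which(flags[ch, ])
    if (!length(w)) return(NULL)
    iv <- tibble::tibble(start_s = (w - 1L) * spec$window_s,
                         end_s = w * spec$window_s)
    iv <- pad_and_merge(iv, spec$padding_s, spec$merge_gap_s, dur)
    event_table(ch, iv$start_s, iv$end_s, spec$name, spec$name)
  })
  bind_events(rows)
}

#' Run a full detector set
#'
#' Detectors run independently; a failing detector emits a warning and an
#' empty result rather than aborting the others.
#'
#' @inheritParams run_detector
#' @param set A `scrub_detector_set`.
#' @return Named list (detector name -> [event_table()]).
#' @export
run_detector_set <- function(rec, set, scoring = NULL, layout = NULL) {
  out <- lapply(set, function(spec) {
    tryCatch(run_detector(rec, spec, scoring, layout),
             error = function(e) {
               warn(sprintf("Detector '%s' failed: %s", spec$name,
                            conditionMessage(e)))
               event_table()
             })
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Serialize / restore a detector set
#'
#' The YAML form exposes every threshold, duration, padding and merge
#' parameter so detector sets can be edited without code.
#'
#' @param set A `scrub_detector_set`.
#' @return `detector_set_to_yaml`: a YAML string;
#'   `detector_set_from_yaml`: a `scrub_detector_set`.
#' @export
detector_set_to_yaml <- function(set) {
  strip <- function(spec) {
    lst <- unclass(spec)
    lst[!vapply(lst, is.null, TRUE)]
  }
  yaml::as.yaml(list(name = attr(set, "set_name"),
                     detectors = lapply(unname(set), strip)))
}

#' @rdname detector_set_to_yaml
#' @param text YAML string produced by `detector_set_to_yaml` (or hand-written
#'   in the same schema).
#' @export
detector_set_from_yaml <- function(text) {
  lst <- yaml::yaml.load(text)
  specs <- lapply(lst$detectors, function(d) do.call(detector_spec, d))
  detector_set(specs, name = lst$name %||% "custom")
}
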