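#' Boolean channel-by-segment artifact grid
#'
#' Artifact bookkeeping discretizes time into fixed-length segments (default
#' 5 s) and stores per channel whether each segment contains artifact. The
#' final segment may be shorter than `segment_length_s` when the recording
#' duration is not a multiple of it.
#'
#' @param values Logical channels x segments matrix.
#' @param channels Channel labels (rownames).
#' @param segment_length_s Segment length in seconds.
#' @param duration_s Recording duration in seconds; defaults to
#'   `ncol(values) * segment_length_s`.
#' @param origin Free-text tag recording how the grid was produced.
#' @return An object of class `scrub_grid`.
#' @export
artifact_grid <- function(values, channels = rownames(values),
                          segment_length_s = 5,
                          duration_s = ncol(values) * segment_length_s,
                          origin = "manual") {
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(values)))
  if (length(channels) != nrow(values)) {
    abort("`channels` must match the grid's row count.")
  }
  n_seg <- as.integer(ceiling(duration_s / segment_length_s - 1e-9))
  if (ncol(values) != n_seg) {
    abort(sprintf("Grid has %d segments but duration %g s at %g s/segment needs %d.",
                  ncol(values), duration_s, segment_length_s, n_seg))
  }
  rownames(values) <- channels
  structure(list(values = values, channels = as.character(channels),
                 segment_length_s = as.numeric(segment_length_s),
                 n_segments = ncol(values),
                 duration_s = as.numeric(duration_s), origin = origin),
            class = "scrub_grid")
}

#' @export
print.scrub_grid <- function(x, ...) {
  cat(sprintf("<scrub_grid '%s'> %d channels x %d segments (%g s); %.1f%% artifactual\n",
              x$origin, nrow(x$values), x$n_segments, x$segment_length_s,
              100 * mean(x$values)))
  invisible(x)
}

# Start/end times and actual durations of all segments.
segment_bounds <- function(grid) {
  s <- (seq_len(grid$n_segments) - 1L) * grid$segment_length_s
  e <- pmin(s + grid$segment_length_s, grid$duration_s)
  list(start = s, end = e, dur = e - s)
}

#' Grid-processing parameters
#'
#' Thresholds for the five-step grid algebra. A `NULL` threshold disables the
#' corresponding step entirely; this is distinct from a threshold of 1, which
#' still fires on fully artifactual columns/channels.
#'
#' @param segment_length_s Segment length in seconds (default 5).
#' @param element_min_proportion An element is artifactual when the summed
#'   event overlap strictly exceeds this fraction of the segment's actual
#'   duration (default 0: any overlap counts).
#' @param pool_mode Only `"OR"` is implemented.
#' @param pool_subset Detector names to pool, or `NULL` for all.
#' @param spatial_threshold Fraction of artifactual neighbors at/above which a
#'   clean channel is added, or `NULL` (off).
#' @param rejection_threshold Fraction of artifactual channels at/above which
#'   a segment is rejected, or `NULL` (off).
#' @param temporal_threshold Fraction of artifactual non-rejected segments
#'   at/above which a whole channel is marked, or `NULL` (off).
#' @param rejection_input `"combined"` (basic or spatial; default) or
#'   `"basic"`: which grid drives segment rejection.
#' @return A list of class `scrub_grid_params`.
#' @export
grid_params <- function(segment_length_s = 5, element_min_proportion = 0,
                        pool_mode = "OR", pool_subset = NULL,
                        spatial_threshold = NULL, rejection_threshold = NULL,
                        temporal_threshold = NULL,
                        rejection_input = c("combined", "basic")) {
  pool_mode <- match.arg(pool_mode, "OR")
  for (t in list(spatial_threshold, rejection_threshold, temporal_threshold)) {
    if (!is.null(t) && (t < 0 || t > 1)) {
      abort("Grid thresholds must lie in [0, 1] (or NULL to disable).")
    }
  }
  structure(list(segment_length_s = segment_length_s,
                 element_min_proportion = element_min_proportion,
                 pool_mode = pool_mode, pool_subset = pool_subset,
                 spatial_threshold = spatial_threshold,
                 rejection_threshold = rejection_threshold,
                 temporal_threshold = temporal_threshold,
                 rejection_input = match.arg(rejection_input)),
            class = "scrub_grid_params")
}

#' Convert an event table to an artifact grid
#'
#' Element (channel, segment) is artifactual when the summed overlap of that
#' channel's events with the segment strictly exceeds
#' `element_min_proportion` of the segment's actual duration (the final
#' partial segment uses its true, shorter duration). Events on the
#' [GLOBAL_CHANNEL] sentinel mark every channel.
#'
#' @param events A [event_table()].
#' @param channels Channel labels defining the grid rows.
#' @param duration_s Recording duration in seconds.
#' @param segment_length_s Segment length in seconds.
#' @param element_min_proportion See [grid_params()].
#' @param origin Tag for the resulting grid.
#' @return A [artifact_grid()].
#' @export
events_to_grid <- function(events, channels, duration_s, segment_length_s = 5,
                           element_min_proportion = 0, origin = "events") {
  validate_events(events, channels)
  n_seg <- as.integer(ceiling(duration_s / segment_length_s - 1e-9))
  overlap <- matrix(0, length(channels), n_seg,
                    dimnames = list(channels, NULL))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev_s <- max(events$start_s[i], 0)
      ev_e <- min(events$end_s[i], duration_s)
      if (ev_s >= ev_e) next
      s0 <- max(floor(ev_s / segment_length_s), 0)
      s1 <- min(ceiling(ev_e / segment_length_s) - 1, n_seg - 1L)
      chs <- if (events$channel[i] == GLOBAL_CHANNEL) channels else events$channel[i]
      for (s in s0:s1) {
        seg_s <- s * segment_length_s
        seg_e <- min(seg_s + segment_length_s, duration_s)
        ov <- min(ev_e, seg_e) - max(ev_s, seg_s)
        if (ov > 0) overlap[chs, s + 1L] <- overlap[chs, s + 1L] + ov
      }
    }
  }
  bounds_dur <- pmin(seq_len(n_seg) * segment_length_s, duration_s) -
    (seq_len(n_seg) - 1L) * segment_length_s
  vals <- sweep(overlap, 2L, element_min_proportion * bounds_dur, `>`)
  artifact_grid(vals, channels, segment_length_s, duration_s, origin)
}

#' Pool per-detector grids into the basic artifact grid
#'
#' Element-wise logical OR over the selected detector grids.
#'
#' @param grid_map Named list of [artifact_grid()]s with identical shape.
#' @param subset Detector names to pool (default all).
#' @return The pooled `scrub_grid` tagged `"basic"`.
#' @export
pool_grids <- function(grid_map, subset = NULL) {
  if (!is.null(subset)) grid_map <- grid_map[subset]
  if (!length(grid_map)) abort("No grids to pool.")
  g1 <- grid_map[[1L]]
  vals <- Reduce(`|`, lapply(grid_map, function(g) {
    if (!identical(dim(g$values), dim(g1$values))) {
      abort("All grids must share the same shape to pool.")
    }
    g$values
  }))
  artifact_grid(vals, g1$channels, g1$segment_length_s, g1$duration_s, "basic")
}

#' Spatial expansion
#'
#' Per segment, a channel that is clean in `basic` is added when the fraction
#' of its neighbors that are artifactual is at least `threshold`. The result
#' holds only the additions (elements already true in `basic` are false
#' here); the pass is not iterated, so added channels never recruit further
#' channels.
#'
#' @param basic The basic artifact grid.
#' @param neighbor_map Symmetric neighbor map from [build_neighbors()].
#' @param threshold Fraction in [0, 1], or `NULL` (off: all-false grid).
#' @return A `scrub_grid` of additions, tagged `"spatial"`.
#' @export
spatial_expand <- function(basic, neighbor_map, threshold) {
  vals <- matrix(FALSE, nrow(basic$values), ncol(basic$values),
                 dimnames = dimnames(basic$values))
  if (!is.null(threshold)) {
    for (ch in basic$channels) {
      nb <- intersect(neighbor_map[[ch]], basic$channels)
      if (!length(nb)) next
      frac <- colMeans(basic$values[nb, , drop = FALSE])
      vals[ch, ] <- !basic$values[ch, ] & frac >= threshold
    }
  }
  artifact_grid(vals, basic$channels, basic$segment_length_s,
                basic$duration_s, "spatial")
}

#' Segment rejection
#'
#' A segment is marked for rejection when the fraction of artifactual
#' channels (over all channels of the grid) is at least `threshold`.
#'
#' @param combined Grid driving rejection (basic, or basic | spatial).
#' @param threshold Fraction in [0, 1], or `NULL` (off).
#' @return Logical vector, one flag per segment.
#' @export
reject_segments <- function(combined, threshold) {
  if (is.null(threshold)) return(rep(FALSE, combined$n_segments))
  colMeans(combined$values) >= threshold
}

#' Temporal expansion (bad-channel rule)
#'
#' Per channel, the artifactual fraction is computed over non-rejected
#' segments only, so rejection does not drive bad-channel detection. A
#' channel at/above `threshold` is marked at all segments; the result holds
#' only the additions relative to `combined`.
#'
#' @param combined Grid of artifacts so far (basic | spatial).
#' @param rejection Logical per-segment rejection vector.
#' @param threshold Fraction in [0, 1], or `NULL` (off).
#' @return A `scrub_grid` of additions, tagged `"temporal"`.
#' @export
temporal_expand <- function(combined, rejection, threshold) {
  vals <- matrix(FALSE, nrow(combined$values), ncol(combined$values),
                 dimnames = dimnames(combined$values))
  if (!is.null(threshold)) {
    keep <- !rejection
    if (any(keep)) {
      frac <- rowMeans(combined$values[, keep, drop = FALSE])
      bad <- frac >= threshold
      vals[bad, ] <- !combined$values[bad, , drop = FALSE]
    }
  }
  artifact_grid(vals, combined$channels, combined$segment_length_s,
                combined$duration_s, "temporal")
}

#' Compose the repair grid
#'
#' `repair = (basic | spatial | temporal) & !rejection` with the rejection
#' vector broadcast over channels: rejected segments contain too many noisy
#' channels for meaningful interpolation, so nothing in them is repaired.
#'
#' @param basic,spatial,temporal Grids from the preceding steps.
#' @param rejection Logical per-segment vector.
#' @return A `scrub_grid` tagged `"repair"`.
#' @export
compose_repair <- function(basic, spatial, temporal, rejection) {
  vals <- (basic$values | spatial$values | temporal$values) &
    matrix(!rejection, nrow(basic$values), length(rejection), byrow = TRUE)
  artifact_grid(vals, basic$channels, basic$segment_length_s,
                basic$duration_s, "repair")
}

#' Run the full five-step grid algebra
#'
#' Converts per-detector event tables to grids, pools them, and applies
#' spatial expansion, segment rejection, temporal expansion and repair-grid
#' composition in order.
#'
#' @param event_map Named list (detector -> [event_table()]).
#' @param channels Channel labels.
#' @param duration_s Recording duration in seconds.
#' @param params A [grid_params()].
#' @param layout Optional [electrode_layout()] (required when
#'   `spatial_threshold` is enabled).
#' @return A list of class `scrub_grid_set` with elements `detector` (list of
#'   grids), `basic`, `spatial`, `rejection` (logical vector), `temporal`,
#'   `repair`, and `params`.
#' @export
build_grid_set <- function(event_map, channels, duration_s,
                           params = grid_params(), layout = NULL) {
  det_grids <- lapply(names(event_map), function(nm) {
    events_to_grid(event_map[[nm]], channels, duration_s,
                   params$segment_length_s, params$element_min_proportion,
                   origin = nm)
  })
  names(det_grids) <- names(event_map)
  if (length(det_grids)) {
    basic <- pool_grids(det_grids, params$pool_subset)
  } else {
    n_seg <- as.integer(ceiling(duration_s / params$segment_length_s - 1e-9))
    basic <- artifact_grid(matrix(FALSE, length(channels), n_seg), channels,
                           params$segment_length_s, duration_s, "basic")
  }
  if (!is.null(params$spatial_threshold) && is.null(layout)) {
    abort("Spatial expansion is enabled but no layout was given.")
  }
  spatial <- spatial_expand(basic,
                            if (is.null(layout)) NULL else layout$neighbor_map,
                            params$spatial_threshold)
  combined <- artifact_grid(basic$values | spatial$values, basic$channels,
                            basic$segment_length_s, basic$duration_s, "combined")
  rej_input <- if (params$rejection_input == "basic") basic else combined
  rejection <- reject_segments(rej_input, params$rejection_threshold)
  temporal <- temporal_expand(combined, rejection, params$temporal_threshold)
  repair <- compose_repair(basic, spatial, temporal, rejection)
  stopifnot(!any(repair$values[, rejection, drop = FALSE]))
  structure(list(detector = det_grids, basic = basic, spatial = spatial,
                 rejection = rejection, temporal = temporal, repair = repair,
                 params = params),
            class = "scrub_grid_set")
}

#' @export
print.scrub_grid_set <- function(x, ...) {
  cat(sprintf(paste0("<scrub_grid_set> %d detectors; basic %.1f%%, repair ",
                     "%.1f%%, rejected %d/%d segments\n"),
              length(x$detector), 100 * mean(x$basic$values),
              100 * mean(x$repair$values), sum(x$rejection),
              length(x$rejection)))
  invisible(x)
}

#' Grid summary statistics
#'
#' Percentages of channel-segment elements marked artifactual per detector
#' grid, for the basic and repair grids, and the percentage of segments
#' marked for rejection — overall and broken down by sleep stage (a segment's
#' stage is the stage of the epoch containing its midpoint).
#'
#' @param grid_set A `scrub_grid_set`.
#' @param scoring Optional [scoring()]; without it every segment has stage
#'   `"unknown"`.
#' @return A tibble with columns `measure`, `stage` (`"all"` plus observed
#'   stages), `percent`, and `n_segments`.
#' @export
grid_summary <- function(grid_set, scoring = NULL) {
  basic <- grid_set$basic
  b <- segment_bounds(basic)
  seg_stage <- stage_at(scoring, (b$start + b$end) / 2)
  grids <- c(grid_set$detector,
             list(basic = basic, spatial = grid_set$spatial,
                  temporal = grid_set$temporal, repair = grid_set$repair))
  groups <- c(list(all = rep(TRUE, basic$n_segments)),
              lapply(stats::setNames(nm = unique(seg_stage)),
                     function(st) seg_stage == st))
  rows <- purrr::map_dfr(names(grids), function(gn) {
    purrr::map_dfr(names(groups), function(st) {
      sel <- groups[[st]]
      tibble::tibble(measure = gn, stage = st,
                     percent = 100 * mean(grids[[gn]]$values[, sel, drop = FALSE]),
                     n_segments = sum(sel))
    })
  })
  rej <- purrr::map_dfr(names(groups), function(st) {
    sel <- groups[[st]]
    tibble::tibble(measure = "rejection", stage = st,
                   percent = 100 * mean(grid_set$rejection[sel]),
                   n_segments = sum(sel))
  })
  dplyr::bind_rows(rows, rej)
}

#' @export
glance.scrub_grid_set <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$basic$values),
                 n_segments = x$basic$n_segments,
                 segment_length_s = x$basic$segment_length_s,
                 basic_pct = 100 * mean(x$basic$values),
                 repair_pct = 100 * mean(x$repair$values),
                 rejection_pct = 100 * mean(x$rejection))
}

#' @export
tidy.scrub_grid_set <- function(x, scoring = NULL, ...) {
  grid_summary(x, scoring)
}

#' Convert a grid back to an event table
#'
#' Per channel, maximal runs of artifactual segments become one event each;
#' the final event is clipped to the recording duration.
#'
#' @param grid A [artifact_grid()].
#' @return A [event_table()] with `event_type = detector = grid$origin`.
#' @export
grid_to_events <- function(grid) {
  L <- grid$segment_length_s
  rows <- lapply(grid$channels, function(ch) {
    r <- rle(as.logical(grid$values[ch, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    event_table(ch, (starts[keep] - 1L) * L,
                pmin(ends[keep] * L, grid$duration_s),
                grid$origin, grid$origin)
  })
  bind_events(rows)
}
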