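#' Spherical-spline parameters
#'
#' Constants of the weighted spherical-spline interpolator: the spline order
#' `m` (stiffness of the kernel), the truncation point of the Legendre
#' series, and the ridge term added to the knot system to tolerate noisy or
#' nearly coincident electrodes. Defaults follow common EEG practice
#' (m = 4, 20 terms, lambda = 1e-5).
#'
#' @param order_m Spline order (integer >= 2).
#' @param n_legendre_terms Series truncation (>= `order_m`).
#' @param regularization_lambda Nonnegative ridge constant.
#' @return A list of class `scrub_spline_params`.
#' @export
spline_params <- function(order_m = 4, n_legendre_terms = 20,
                          regularization_lambda = 1e-5) {
  if (order_m < 2) abort("`order_m` must be >= 2.")
  if (n_legendre_terms < order_m) abort("`n_legendre_terms` must be >= order_m.")
  if (regularization_lambda < 0) abort("`regularization_lambda` must be >= 0.")
  structure(list(order_m = as.integer(order_m),
                 n_legendre_terms = as.integer(n_legendre_terms),
                 regularization_lambda = regularization_lambda),
            class = "scrub_spline_params")
}

# Center positions on their centroid and project to the unit sphere.
unit_positions <- function(pos) {
  pos <- sweep(pos, 2L, colMeans(pos))
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) abort("Electrode at the centroid: zero-norm position.")
  pos / nrm
}

#' Spherical-spline kernel matrix
#'
#' Evaluates the spline kernel
#' `g(x) = (1 / 4 pi) * sum_{n=1}^{N} (2n + 1) / (n (n + 1))^m * P_n(x)`
#' at the cosines of the angles between two sets of unit-sphere positions,
#' with `P_n` the Legendre polynomials computed by the three-term recursion.
#'
#' @param pos_a,pos_b Matrices of unit-norm 3-D positions (rows).
#' @param params A [spline_params()].
#' @return `nrow(pos_a)` x `nrow(pos_b)` kernel matrix (symmetric when the
#'   two sets coincide).
#' @export
spline_g_matrix <- function(pos_a, pos_b = pos_a, params = spline_params()) {
  if (any(abs(sqrt(rowSums(pos_a^2)) - 1) > 1e-6) ||
      any(abs(sqrt(rowSums(pos_b^2)) - 1) > 1e-6)) {
    abort("Positions must be unit-normalized (see unit_positions).")
  }
  x <- pmin(pmax(pos_a %*% t(pos_b), -1), 1)
  g <- matrix(0, nrow(x), ncol(x))
  p_prev <- matrix(1, nrow(x), ncol(x))  # P_0
  p_cur <- x                             # P_1
  for (n in seq_len(params$n_legendre_terms)) {
    if (n > 1L) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      p_prev <- p_cur
      p_cur <- p_next
    }
    g <- g + (2 * n + 1) / (n * (n + 1))^params$order_m * p_cur
  }
  g / (4 * pi)
}

#' Interpolate bad channels at one segment
#'
#' Solves the regularized spline system on the good channels (kernel matrix
#' plus ridge, augmented with the constant term) and evaluates the resulting
#' surface at the bad channels' positions, independently for every time
#' sample. Uses exclusively information from the good channels; their samples
#' are returned untouched.
#'
#' @param segment_data Channels x samples matrix (all channels).
#' @param good_idx,bad_idx Disjoint row indices of clean and artifactual
#'   channels.
#' @param positions 3-D positions, one row per channel of `segment_data`.
#' @param params A [spline_params()].
#' @return `segment_data` with the bad rows replaced. Fewer than 3 good
#'   channels raises a condition of class `scrub_not_repairable`.
#' @export
interpolate_channels <- function(segment_data, good_idx, bad_idx, positions,
                                 params = spline_params()) {
  if (length(intersect(good_idx, bad_idx))) {
    abort("`good_idx` and `bad_idx` must be disjoint.")
  }
  if (length(good_idx) < 3L) {
    rlang::abort("Fewer than 3 clean channels: segment not repairable.",
                 class = "scrub_not_repairable")
  }
  upos <- unit_positions(positions)
  gg <- spline_g_matrix(upos[good_idx, , drop = FALSE], params = params)
  gb <- spline_g_matrix(upos[bad_idx, , drop = FALSE],
                        upos[good_idx, , drop = FALSE], params)
  ng <- length(good_idx)
  m <- rbind(cbind(gg + diag(params$regularization_lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(segment_data[good_idx, , drop = FALSE],
               rep(0, ncol(segment_data)))
  sol <- solve(m, rhs)
  coef <- sol[seq_len(ng), , drop = FALSE]
  const <- sol[ng + 1L, ]
  out <- segment_data
  out[bad_idx, ] <- gb %*% coef +
    matrix(const, length(bad_idx), ncol(segment_data), byrow = TRUE)
  out
}

#' Repair a recording segment-wise according to a grid
#'
#' At each grid segment, channels flagged in `repair_grid` are replaced:
#' `"spline"` interpolates them from the clean channels,
#' `"nan"`/`"zero"` overwrite the flagged spans with a fixed value. For
#' spline repair, wherever a channel's repaired status changes (segment
#' boundaries between repaired and original signal, or between two repaired
#' segments with different clean sets) the two versions are linearly
#' crossfaded over `crossfade_s` seconds centered on the boundary, which
#' suppresses discontinuities. Segments with fewer than 3 clean channels are
#' left unmodified and reported.
#'
#' @param rec A [recording()].
#' @param repair_grid A [artifact_grid()] matching the recording's channels
#'   and duration.
#' @param layout A [electrode_layout()] (required for spline).
#' @param method `"spline"`, `"nan"` or `"zero"`.
#' @param crossfade_s Crossfade length in seconds (spline only; default 0.1).
#' @param params A [spline_params()].
#' @return A list with `recording` (repaired copy) and `not_repairable`
#'   (tibble of channel/segment elements that could not be interpolated).
#' @export
repair_by_grid <- function(rec, repair_grid, layout = NULL,
                           method = c("spline", "nan", "zero"),
                           crossfade_s = 0.1, params = spline_params()) {
  method <- match.arg(method)
  if (!identical(repair_grid$channels, rec$channel_labels)) {
    abort("Grid channels must match the recording's channels (same order).")
  }
  if (abs(repair_grid$duration_s - duration_s(rec)) > repair_grid$segment_length_s) {
    abort("Grid duration does not match the recording.")
  }
  fs <- rec$sample_rate_hz
  n <- n_samples(rec)
  vals <- repair_grid$values
  out <- rec$data
  not_rep <- tibble::tibble(channel = character(), segment = integer())
  b <- segment_bounds(repair_grid)
  seg_idx <- lapply(seq_len(repair_grid$n_segments), function(s) {
    a <- time_to_sample(b$start[s], fs) + 1L
    z <- min(time_to_sample(b$end[s] - 1e-9, fs) + 1L, n)
    if (a > z) NULL else a:z
  })
  if (method %in% c("nan", "zero")) {
    fill <- if (method == "nan") NA_real_ else 0
    for (s in seq_len(repair_grid$n_segments)) {
      bad <- which(vals[, s])
      if (length(bad) && !is.null(seg_idx[[s]])) out[bad, seg_idx[[s]]] <- fill
    }
    return(list(recording = recording(out, fs, rec$channel_labels,
                                      rec$start_time_s, allow_na = TRUE),
                not_repairable = not_rep))
  }
  if (is.null(layout)) abort("Spline repair requires an electrode layout.")
  missing <- setdiff(rec$channel_labels, layout$labels)
  if (length(missing)) {
    abort(paste0("Layout lacks positions for: ", paste(missing, collapse = ", ")))
  }
  pos <- layout$positions[rec$channel_labels, , drop = FALSE]
  ext <- max(0L, as.integer(round(crossfade_s / 2 * fs)))
  # interpolate each flagged segment once (extended by the crossfade
  # half-width on both sides), keyed by segment
  rep_ext <- vector("list", repair_grid$n_segments)
  ext_rng <- vector("list", repair_grid$n_segments)
  for (s in seq_len(repair_grid$n_segments)) {
    bad <- which(vals[, s])
    if (!length(bad) || is.null(seg_idx[[s]])) next
    good <- setdiff(seq_len(nrow(out)), bad)
    rng <- max(1L, seg_idx[[s]][1L] - ext):min(n, seg_idx[[s]][length(seg_idx[[s]])] + ext)
    res <- tryCatch(
      interpolate_channels(rec$data[, rng, drop = FALSE], good, bad, pos, params),
      scrub_not_repairable = function(e) NULL)
    if (is.null(res)) {
      not_rep <- dplyr::bind_rows(not_rep,
        tibble::tibble(channel = rec$channel_labels[bad], segment = s))
      vals[, s] <- FALSE  # leave data untouched
      next
    }
    rep_ext[[s]] <- res[vals[, s], , drop = FALSE]
    rownames(rep_ext[[s]]) <- rec$channel_labels[vals[, s]]
    ext_rng[[s]] <- rng
  }
  ramp_up <- if (ext > 0) (seq_len(2L * ext) - 0.5) / (2L * ext) else numeric()
  for (ci in seq_len(nrow(out))) {
    ch <- rec$channel_labels[ci]
    fl <- vals[ci, ]
    if (!any(fl)) next
    r <- rle(fl)
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1L
    for (k in which(r$values)) {
      s0 <- seg_start[k]; s1 <- seg_end[k]
      a <- seg_idx[[s0]][1L]
      z <- seg_idx[[s1]][length(seg_idx[[s1]])]
      # core replacement, segment by segment
      for (s in s0:s1) {
        idx <- seg_idx[[s]]
        out[ci, idx] <- rep_ext[[s]][ch, match(idx, ext_rng[[s]])]
      }
      if (ext == 0L) next
      # internal boundaries: crossfade between the two segment solutions
      if (s1 > s0) for (s in s0:(s1 - 1L)) {
        bnd <- seg_idx[[s + 1L]][1L]
        zone <- (bnd - ext):(bnd + ext - 1L)
        keep <- zone >= 1L & zone <= n
        zone <- zone[keep]; w <- ramp_up[keep]
        left <- rep_ext[[s]][ch, match(zone, ext_rng[[s]])]
        right <- rep_ext[[s + 1L]][ch, match(zone, ext_rng[[s + 1L]])]
        ok <- !is.na(left) & !is.na(right)
        out[ci, zone[ok]] <- (1 - w[ok]) * left[ok] + w[ok] * right[ok]
      }
      # run edges: crossfade original <-> repaired, centered on the boundary
      zone <- (a - ext):(a + ext - 1L)
      keep <- zone >= 1L & zone <= n
      zs <- zone[keep]; w <- ramp_up[keep]
      repv <- rep_ext[[s0]][ch, match(zs, ext_rng[[s0]])]
      ok <- !is.na(repv)
      out[ci, zs[ok]] <- (1 - w[ok]) * rec$data[ci, zs[ok]] + w[ok] * repv[ok]
      zone <- (z + 1L - ext):(z + ext)
      keep <- zone >= 1L & zone <= n
      zs <- zone[keep]; w <- ramp_up[keep]
      repv <- rep_ext[[s1]][ch, match(zs, ext_rng[[s1]])]
      ok <- !is.na(repv)
      out[ci, zs[ok]] <- w[ok] * rec$data[ci, zs[ok]] + (1 - w[ok]) * repv[ok]
    }
  }
  list(recording = recording(out, fs, rec$channel_labels, rec$start_time_s,
                             allow_na = TRUE),
       not_repairable = not_rep)
}
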