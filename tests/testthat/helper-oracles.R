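# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's vectorized implementations: they
# loop over samples/elements and state the definitions directly.

# per-sample run-length oracle for threshold_intervals
oracle_threshold_intervals <- function(x, fs, cmp, threshold, min_duration_s) {
  hit <- if (cmp == "gt") x > threshold else x < threshold
  out <- NULL
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (hit[i]) {
      j <- i
      while (j < n && hit[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / fs >= min_duration_s) {
        out <- rbind(out, c((i - 1L) / fs, j / fs))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    tibble::tibble(start_s = numeric(), end_s = numeric())
  } else {
    tibble::tibble(start_s = out[, 1L], end_s = out[, 2L])
  }
}

# pad/clip/merge oracle working on explicit interval pairs
oracle_pad_and_merge <- function(iv, pad, gap, dur) {
  if (!nrow(iv)) return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  s <- pmax(iv$start_s - pad, 0)
  e <- pmin(iv$end_s + pad, dur)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  o <- order(s, e); s <- s[o]; e <- e[o]
  res <- NULL
  for (k in seq_along(s)) {
    if (!is.null(res) && s[k] - res[nrow(res), 2L] < gap) {
      res[nrow(res), 2L] <- max(res[nrow(res), 2L], e[k])
    } else {
      res <- rbind(res, c(s[k], e[k]))
    }
  }
  if (is.null(res)) return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  tibble::tibble(start_s = res[, 1L], end_s = res[, 2L])
}

# element-by-element re-statement of the five grid steps
oracle_grid_steps <- function(basic_vals, neighbor_map, channels,
                              thr_spatial, thr_reject, thr_temporal) {
  nch <- nrow(basic_vals); nseg <- ncol(basic_vals)
  spatial <- matrix(FALSE, nch, nseg)
  if (!is.null(thr_spatial)) {
    for (ci in seq_len(nch)) {
      nb <- match(neighbor_map[[channels[ci]]], channels)
      nb <- nb[!is.na(nb)]
      if (!length(nb)) next
      for (s in seq_len(nseg)) {
        if (!basic_vals[ci, s]) {
          frac <- sum(basic_vals[nb, s]) / length(nb)
          if (frac >= thr_spatial) spatial[ci, s] <- TRUE
        }
      }
    }
  }
  combined <- basic_vals | spatial
  reject <- rep(FALSE, nseg)
  if (!is.null(thr_reject)) {
    for (s in seq_len(nseg)) {
      if (sum(combined[, s]) / nch >= thr_reject) reject[s] <- TRUE
    }
  }
  temporal <- matrix(FALSE, nch, nseg)
  if (!is.null(thr_temporal) && any(!reject)) {
    for (ci in seq_len(nch)) {
      frac <- sum(combined[ci, !reject]) / sum(!reject)
      if (frac >= thr_temporal) {
        for (s in seq_len(nseg)) {
          if (!combined[ci, s]) temporal[ci, s] <- TRUE
        }
      }
    }
  }
  rep_grid <- matrix(FALSE, nch, nseg)
  for (ci in seq_len(nch)) {
    for (s in seq_len(nseg)) {
      rep_grid[ci, s] <- (basic_vals[ci, s] || spatial[ci, s] ||
                            temporal[ci, s]) && !reject[s]
    }
  }
  list(spatial = spatial, reject = reject, temporal = temporal,
       repair = rep_grid)
}

# spherical-spline kernel via pracma's Legendre functions (independent of
# the package's recursion)
oracle_g_matrix <- function(pos_a, pos_b, m, n_terms) {
  x <- pmin(pmax(pos_a %*% t(pos_b), -1), 1)
  g <- matrix(0, nrow(x), ncol(x))
  for (n in seq_len(n_terms)) {
    pn <- matrix(pracma::legendre(n, as.vector(x))[1L, ],
                 nrow(x), ncol(x))
    g <- g + (2 * n + 1) / (n * (n + 1))^m * pn
  }
  g / (4 * pi)
}

# small random event table on given channels
random_events <- function(channels, duration_s, n_events) {
  s <- runif(n_events, 0, duration_s - 0.5)
  e <- pmin(s + runif(n_events, 0.1, duration_s / 3), duration_s)
  event_table(sample(channels, n_events, replace = TRUE), s, e, "x", "x")
}

# default layout + neighbors used by pairwise detector tests
test_layout_all_to_all <- function(n) {
  lay <- gen_layout(n)
  build_neighbors(lay, threshold = Inf)
}

match_class_map <- c(highamp = "highamp", lowamp = "lowamp",
                     lowfreq = "lowfreq", highfreq = "highfreq",
                     jump = "jump", flatline = "flatline",
                     deviant = "deviant", similar = "bridged",
                     similar2 = "reference")
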