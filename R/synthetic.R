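#' Quasi-uniform synthetic electrode layout
#'
#' Deterministic Fibonacci lattice on the upper unit hemisphere: a plausible
#' whole-head montage for any channel count, used by the synthetic recording
#' generator and by interpolation tests.
#'
#' @param n_channels Number of electrodes.
#' @return A [electrode_layout()] with unit-norm positions and an empty
#'   neighbor map (call [build_neighbors()]).
#' @export
gen_layout <- function(n_channels) {
  i <- seq_len(n_channels) - 1L
  z <- (i + 0.5) / n_channels          # height above the equatorial plane
  phi <- i * pi * (3 - sqrt(5))        # golden angle
  r <- sqrt(1 - z^2)
  electrode_layout(paste0("E", seq_len(n_channels)),
                   cbind(x = r * cos(phi), y = r * sin(phi), z = z))
}

#' Synthetic-recording configuration
#'
#' Defines the study conditions emulated by [gen_recording()]: a
#' stage-structured night in miniature (10 minutes by default) with pink-noise
#' background, stage-specific oscillations, and a plan of injected artifacts
#' with ground truth. See [default_artifact_plan()] for the default plan.
#'
#' @param n_channels Channel count (default 16).
#' @param sample_rate_hz Sample rate (default 250).
#' @param duration_s Total duration in seconds (default 600).
#' @param hypnogram Character vector of stage labels, one per 30 s epoch;
#'   default covers W, N1, N2, N3 and R.
#' @param background_rms_uv Per-channel background RMS in microvolts
#'   (default 15, typical of scalp sleep EEG).
#' @param background_alpha Spectral exponent of the 1/f^alpha background
#'   (default 1).
#' @param mixing_scale Spatial decay constant of the channel-mixing kernel
#'   `exp(-d / (mixing_scale * radius))` (default 0.5).
#' @param osc_amp_uv Named amplitudes (microvolts) for stage oscillations:
#'   `alpha` (10 Hz, W), `spindle` (13 Hz bursts, N2), `slow` (0.75 Hz, N3).
#' @param emg_rms_uv Baseline RMS (microvolts) of the broadband (40 Hz and
#'   up) muscle-tone component, independent per channel, whose level cycles
#'   slowly and boundedly as `1 + emg_mod_depth * sin(2 pi t / emg_mod_period_s)`
#'   with a channel-specific phase. Real overnight EEG has slowly varying
#'   muscle tone; it is this variation that dominates the standard deviation
#'   of z-scored high-frequency envelopes and makes the z > 3 criterion
#'   specific to genuine muscle bursts. A bounded (sinusoidal) modulator
#'   keeps the tone itself from ever crossing the threshold.
#' @param emg_mod_depth,emg_mod_period_s Depth (0-1) and period of the tone
#'   modulation.
#' @param artifacts Artifact plan tibble (`type`, `channel`, `start_s`,
#'   `duration_s`, `severity`, `channel2`), or `NULL` for none.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `scrub_synth_config`.
#' @export
synth_config <- function(n_channels = 16, sample_rate_hz = 250,
                         duration_s = 600,
                         hypnogram = default_hypnogram(duration_s),
                         background_rms_uv = 15, background_alpha = 1,
                         mixing_scale = 0.5,
                         osc_amp_uv = c(alpha = 20, spindle = 25, slow = 40),
                         emg_rms_uv = 6, emg_mod_depth = 0.6,
                         emg_mod_period_s = 97,
                         artifacts = default_artifact_plan(),
                         seed = 1L) {
  if (!is.null(artifacts) && nrow(artifacts)) {
    if (any(artifacts$start_s + artifacts$duration_s > duration_s + 1e-9)) {
      abort("Artifact plan extends beyond the recording duration.")
    }
  }
  structure(list(n_channels = n_channels, sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s, hypnogram = hypnogram,
                 background_rms_uv = background_rms_uv,
                 background_alpha = background_alpha,
                 mixing_scale = mixing_scale, osc_amp_uv = osc_amp_uv,
                 emg_rms_uv = emg_rms_uv, emg_mod_depth = emg_mod_depth,
                 emg_mod_period_s = emg_mod_period_s,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "scrub_synth_config")
}

#' @rdname synth_config
#' @param duration_s Recording duration in seconds.
#' @export
default_hypnogram <- function(duration_s = 600) {
  base <- c("W", "W", "N1", "N2", "N2", "N2", "N3", "N3", "N3", "N2",
            "N2", "R", "R", "N2", "N2", "N3", "N3", "N2", "R", "W")
  n <- ceiling(duration_s / 30)
  rep_len(base, n)
}

#' Default artifact plan
#'
#' Forty injections spanning all nine target classes of the default
#' detectors, scheduled so channel-wise artifacts (channels E1-E12, first
#' six minutes) and the long pairwise artifacts (deviant/bridged, channels
#' E9-E16, last four minutes, aligned to 30 s windows) do not collide on a
#' channel. Severities follow the class definitions: high-amplitude bursts
#' peak at 700 uV, low-amplitude spans are attenuated to a sub-microvolt
#' peak (a
#' dried or disconnected electrode) for 40 s, drifts are 0.5 Hz at 240 uV for 6 s,
#' muscle-band bursts 30 uV RMS, steps 220 uV with exponential recovery,
#' flatlines hold the signal for 2.5-3 s, deviant spans replace the channel
#' with independent noise for 60 s, bridged spans copy a neighboring channel
#' for 60 s, and reference failures mix a common 4-12 Hz source at 40 uV RMS
#' into every channel for 20 s (pairwise correlations ~0.95; a failing
#' reference electrode injects the reference site's own EEG, which is
#' low/mid-frequency).
#'
#' @return Tibble with columns `type`, `channel`, `start_s`, `duration_s`,
#'   `severity`, `channel2`.
#' @export
default_artifact_plan <- function() {
  tibble::tribble(
    ~type,       ~channel, ~start_s, ~duration_s, ~severity,
    "highamp",   "E1",        20,       2.5,        700,
    "highamp",   "E2",        50,       2.0,        700,
    "highamp",   "E3",        80,       3.0,        700,
    "highamp",   "E4",       110,       2.0,        700,
    "highamp",   "E5",       140,       2.5,        700,
    "jump",      "E6",        30,       0.2,        220,
    "jump",      "E7",        60,       0.2,       -220,
    "jump",      "E8",        90,       0.2,        220,
    "jump",      "E9",       120,       0.2,       -220,
    "jump",      "E10",      158,       0.2,        220,
    "lowfreq",   "E11",       20,       6,          240,
    "lowfreq",   "E12",       45,       6,          240,
    "lowfreq",   "E8",       170,       6,          240,
    "lowfreq",   "E9",       200,       6,          240,
    "lowfreq",   "E10",      230,       6,          240,
    "highfreq",  "E4",       170,       5,           30,
    "highfreq",  "E5",       195,       5,           30,
    "highfreq",  "E6",       220,       5,           30,
    "highfreq",  "E7",       245,       5,           30,
    "highfreq",  "E8",       270,       5,           30,
    "flatline",  "E6",       170,       3,            0,
    "flatline",  "E7",       200,       3,            0,
    "flatline",  "E8",       230,       2.5,          0,
    "flatline",  "E9",       170,       3,            0,
    "flatline",  "E10",      200,       2.5,          0,
    "lowamp",    "E2",       250,      40,          0.6,
    "lowamp",    "E3",       295,      40,          0.6,
    "lowamp",    "E4",       250,      40,          0.6,
    "lowamp",    "E5",       295,      40,          0.6,
    "deviant",   "E13",      360,      60,            0,
    "deviant",   "E14",      420,      60,            0,
    "deviant",   "E15",      480,      60,            0,
    "deviant",   "E16",      540,      60,            0,
    "bridged",   "E9",       360,      60,            0,
    "bridged",   "E10",      420,      60,            0,
    "bridged",   "E11",      480,      60,            0,
    "bridged",   "E12",      540,      60,            0,
    "reference", GLOBAL_CHANNEL, 95,   20,           40,
    "reference", GLOBAL_CHANNEL, 135,  20,           55,
    "reference", GLOBAL_CHANNEL, 340,  20,           55
  ) |> dplyr::mutate(channel2 = NA_character_)
}

# 1/f^alpha noise of length n via frequency-domain shaping; unit variance.
pink_noise <- function(n, fs, alpha) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  re <- rnorm(nf); im <- rnorm(nf)
  spec <- complex(real = re, imaginary = im) * amp
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = re[nf] * amp[nf], imaginary = 0)
    if (nf > 1L) full[n:(nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  } else {
    full[n:(nf + 2L)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

# linear edge ramp of `m` samples at both ends of a length-n envelope
edge_ramp <- function(n, m) {
  env <- rep(1, n)
  m <- min(m, floor(n / 2))
  if (m > 0) {
    env[seq_len(m)] <- seq_len(m) / m
    env[n + 1L - seq_len(m)] <- seq_len(m) / m
  }
  env
}

#' Generate a synthetic sleep EEG recording with ground truth
#'
#' Background is spatially mixed 1/f^alpha noise (mixing kernel
#' `exp(-d / (mixing_scale * radius))` over electrode distances), rescaled to
#' the target per-channel RMS. Stage oscillations (alpha in W, spindle bursts
#' in N2, slow waves in N3) are added with a smooth channel-specific
#' topographic gain. Each planned artifact is injected and recorded in the
#' ground-truth event table; bridged injections yield truth rows on both
#' channels of the pair, reference failures on every channel.
#'
#' @param config A [synth_config()].
#' @return List with elements `recording`, `scoring`, `truth`
#'   (ground-truth [event_table()]), and `layout` (neighbors built with the
#'   default distance threshold).
#' @export
gen_recording <- function(config = synth_config()) {
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  nch <- config$n_channels
  layout <- gen_layout(nch)
  # neighbor cutoff adapted to montage density: the immediate ring of the
  # lattice (1.3 x the median nearest-neighbor spacing)
  d_all <- as.matrix(stats::dist(layout$positions))
  nn <- apply(d_all + diag(Inf, nch), 1L, min)
  layout <- build_neighbors(layout, threshold = 1.3 * median(nn))
  # spatially mixed pink-noise background
  src <- t(vapply(seq_len(nch), function(i) pink_noise(n, fs, config$background_alpha),
                  numeric(n)))
  d <- as.matrix(stats::dist(layout$positions))
  w <- exp(-d / (config$mixing_scale * 1))   # unit-sphere radius = 1
  dat <- w %*% src
  dat <- dat / sqrt(rowMeans(dat^2)) * config$background_rms_uv
  # stage oscillations with a smooth topographic gain
  scor <- scoring(config$hypnogram, 30)
  samp_stage <- stage_per_sample(scor, n, fs)
  t_s <- (seq_len(n) - 1L) / fs
  gain <- 0.4 + 0.6 * layout$positions[, "z"]
  osc <- numeric(n)
  w_idx <- samp_stage == "W"
  osc[w_idx] <- config$osc_amp_uv[["alpha"]] * sin(2 * pi * 10 * t_s[w_idx])
  n3_idx <- samp_stage == "N3"
  osc[n3_idx] <- config$osc_amp_uv[["slow"]] * sin(2 * pi * 0.75 * t_s[n3_idx])
  n2_idx <- samp_stage == "N2"
  if (any(n2_idx)) {
    burst <- (t_s %% 6) < 1                       # 1 s spindle burst every 6 s
    env <- 0.5 - 0.5 * cos(2 * pi * (t_s %% 6))   # smooth within the burst
    sp <- config$osc_amp_uv[["spindle"]] * env * sin(2 * pi * 13 * t_s)
    osc[n2_idx] <- sp[n2_idx] * burst[n2_idx]
  }
  dat <- dat + outer(gain, osc)
  # slowly cycling muscle tone: broadband >= 40 Hz, independent per channel
  # (uniform topography; per-channel z-scoring absorbs any common gain)
  if (config$emg_rms_uv > 0) {
    emg_hi <- min(120, 0.95 * fs / 2)
    for (i in seq_len(nch)) {
      e <- pink_noise(n, fs, 0)
      e <- bandpass(recording(matrix(e, 1L), fs, "tmp"), 40, emg_hi)$data[1L, ]
      e <- e / sqrt(mean(e^2))
      mod <- 1 + config$emg_mod_depth *
        sin(2 * pi * t_s / config$emg_mod_period_s + 2 * pi * i / nch)
      dat[i, ] <- dat[i, ] + config$emg_rms_uv * mod * e
    }
  }
  rownames(dat) <- layout$labels
  # artifact injection
  truth <- list()
  plan <- config$artifacts
  clean <- dat  # pre-injection copy, used as bridging source material
  if (!is.null(plan) && nrow(plan)) {
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      a <- time_to_sample(p$start_s, fs) + 1L
      b <- min(time_to_sample(p$start_s + p$duration_s - 1e-9, fs) + 1L, n)
      idx <- a:b
      len <- length(idx)
      tt <- t_s[idx] - p$start_s
      end_s <- p$start_s + p$duration_s
      add_truth <- function(ch, type = p$type, s = p$start_s, e = end_s) {
        truth[[length(truth) + 1L]] <<-
          event_table(ch, s, e, type, "injected")
      }
      switch(p$type,
        highamp = {
          dat[p$channel, idx] <- dat[p$channel, idx] +
            p$severity * hann(len) * sin(2 * pi * 1.5 * tt)
          add_truth(p$channel)
        },
        lowamp = {
          # attenuate so the peak stays below the severity (microvolts),
          # with 0.5 s ramps to avoid injecting discontinuities
          sc <- p$severity / max(abs(dat[p$channel, idx]))
          ramp <- edge_ramp(len, round(0.5 * fs))
          fac <- 1 - (1 - sc) * ramp
          dat[p$channel, idx] <- dat[p$channel, idx] * fac
          add_truth(p$channel)
        },
        lowfreq = {
          dat[p$channel, idx] <- dat[p$channel, idx] +
            p$severity * hann(len) * sin(2 * pi * 0.5 * tt)
          add_truth(p$channel)
        },
        highfreq = {
          burst <- pink_noise(len, fs, 0)
          rec_tmp <- recording(matrix(burst, 1L), fs, "tmp")
          burst <- bandpass(rec_tmp, 60, min(120, 0.95 * fs / 2))$data[1L, ]
          burst <- burst / sqrt(mean(burst^2)) * p$severity *
            edge_ramp(len, round(0.25 * fs))
          dat[p$channel, idx] <- dat[p$channel, idx] + burst
          add_truth(p$channel)
        },
        jump = {
          tail_idx <- idx[1L]:n
          dat[p$channel, tail_idx] <- dat[p$channel, tail_idx] +
            p$severity * exp(-(t_s[tail_idx] - t_s[idx[1L]]) / 0.5)
          add_truth(p$channel, s = p$start_s - 0.1, e = p$start_s + 0.1)
        },
        flatline = {
          held <- dat[p$channel, idx[1L]]
          dat[p$channel, idx] <- held
          # amplifier saturates and recovers continuously: short linear
          # blends into and out of the hold (outside the truth span)
          m <- round(0.2 * fs)
          if (idx[1L] > 1L) {
            pre <- max(1L, idx[1L] - m):(idx[1L] - 1L)
            wpre <- seq_along(pre) / (length(pre) + 1L)
            dat[p$channel, pre] <- (1 - wpre) * dat[p$channel, pre] +
              wpre * held
          }
          if (idx[len] < n) {
            post <- (idx[len] + 1L):min(idx[len] + m, n)
            wpost <- seq_along(post) / (length(post) + 1L)
            dat[p$channel, post] <- (1 - wpost) * held +
              wpost * dat[p$channel, post]
          }
          add_truth(p$channel)
        },
        deviant = {
          # replace with independent noise; blend in/out just outside the
          # span so the transition is neither a jump nor inside the span
          m <- round(0.2 * fs)
          a2 <- max(1L, idx[1L] - m)
          b2 <- min(n, idx[len] + m)
          len2 <- b2 - a2 + 1L
          repl <- pink_noise(len2, fs, config$background_alpha) *
            config$background_rms_uv
          cf <- edge_ramp(len2, m)
          dat[p$channel, a2:b2] <- (1 - cf) * dat[p$channel, a2:b2] + cf * repl
          add_truth(p$channel)
        },
        bridged = {
          src_ch <- p$channel2
          if (is.na(src_ch)) {
            # nearest layout neighbor not itself targeted by a long artifact
            cand <- setdiff(layout$labels,
                            c(p$channel,
                              plan$channel[plan$type %in% c("deviant", "bridged")]))
            if (!length(cand)) cand <- setdiff(layout$labels, p$channel)
            src_ch <- cand[which.min(d[p$channel, cand])]
          }
          # exact copy inside the span (a gel bridge short-circuits the
          # electrodes); blend in/out just outside the span to avoid steps
          dat[p$channel, idx] <- clean[src_ch, idx]
          m <- round(0.2 * fs)
          pre <- max(1L, idx[1L] - m):(idx[1L] - 1L)
          if (length(pre) && idx[1L] > 1L) {
            wpre <- seq_along(pre) / (length(pre) + 1L)
            dat[p$channel, pre] <- (1 - wpre) * dat[p$channel, pre] +
              wpre * clean[src_ch, pre]
          }
          post <- (idx[len] + 1L):min(idx[len] + m, n)
          if (length(post) && idx[len] < n) {
            wpost <- seq_along(post) / (length(post) + 1L)
            dat[p$channel, post] <- (1 - wpost) * clean[src_ch, post] +
              wpost * dat[p$channel, post]
          }
          add_truth(p$channel)
          add_truth(src_ch)
        },
        reference = {
          common <- pink_noise(len, fs, 0)
          rec_tmp <- recording(matrix(common, 1L), fs, "tmp")
          common <- bandpass(rec_tmp, 4, 12)$data[1L, ]
          common <- common / sqrt(mean(common^2)) * p$severity *
            edge_ramp(len, round(0.25 * fs))
          dat[, idx] <- dat[, idx] +
            matrix(common, nch, len, byrow = TRUE)
          for (ch in layout$labels) add_truth(ch)
        },
        abort(paste0("Unknown artifact type in plan: ", p$type))
      )
    }
  }
  list(recording = recording(dat, fs, layout$labels),
       scoring = scor,
       truth = bind_events(truth),
       layout = layout)
}
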