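#' Data-quality figure
#'
#' The at-a-glance quality plot: a hypnogram strip on top; a central
#' channel-by-segment raster with basic artifact in gray, spatial-expansion
#' additions in magenta, temporal-expansion additions in gold and rejected
#' segments as red columns; and marginal summaries (per-segment artifactual
#' channel fraction below, per-channel artifactual segment fraction to the
#' right).
#'
#' @param grid_set A `scrub_grid_set` from [build_grid_set()].
#' @param scoring Optional [scoring()] for the hypnogram strip.
#' @param colors Named colors for `basic`, `spatial`, `temporal`, `rejected`.
#' @return A patchwork/ggplot object (print or [ggplot2::ggsave()] it).
#' @export
plot_quality <- function(grid_set, scoring = NULL,
                         colors = c(basic = "gray40", spatial = "magenta",
                                    temporal = "gold", rejected = "red")) {
  basic <- grid_set$basic
  nseg <- basic$n_segments
  L <- basic$segment_length_s
  chans <- basic$channels
  state <- matrix(NA_character_, length(chans), nseg)
  state[grid_set$temporal$values] <- "temporal"
  state[grid_set$spatial$values] <- "spatial"
  state[basic$values] <- "basic"
  state[, grid_set$rejection] <- "rejected"
  cells <- tidyr::expand_grid(channel = chans, segment = seq_len(nseg))
  cells$state <- state[cbind(match(cells$channel, chans), cells$segment)]
  cells <- dplyr::filter(cells, !is.na(.data$state))
  cells$state <- factor(cells$state, levels = names(colors))
  combined <- basic$values | grid_set$spatial$values | grid_set$temporal$values
  p_raster <- ggplot2::ggplot(cells,
      ggplot2::aes(x = (.data$segment - 0.5) * L,
                   y = factor(.data$channel, rev(chans)),
                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = colors, limits = names(colors),
                               drop = FALSE, name = NULL) +
    ggplot2::scale_x_continuous(limits = c(0, nseg * L), expand = c(0, 0)) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  marg_seg <- tibble::tibble(t = (seq_len(nseg) - 0.5) * L,
                             frac = colMeans(combined))
  p_bottom <- ggplot2::ggplot(marg_seg, ggplot2::aes(.data$t, .data$frac)) +
    ggplot2::geom_col(width = L, fill = "gray40") +
    ggplot2::scale_x_continuous(limits = c(0, nseg * L), expand = c(0, 0)) +
    ggplot2::labs(x = "time (s)", y = "channel\nfraction") +
    ggplot2::theme_minimal(base_size = 9)
  marg_ch <- tibble::tibble(channel = factor(chans, rev(chans)),
                            frac = rowMeans(combined))
  p_right <- ggplot2::ggplot(marg_ch, ggplot2::aes(.data$frac, .data$channel)) +
    ggplot2::geom_col(fill = "gray40") +
    ggplot2::labs(x = "segment fraction", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  hyp <- tibble::tibble(t = (seq_len(nseg) - 0.5) * L,
                        stage = factor(stage_at(scoring, (seq_len(nseg) - 0.5) * L),
                                       rev(STAGE_LEVELS)))
  p_hyp <- ggplot2::ggplot(hyp, ggplot2::aes(.data$t, .data$stage, group = 1)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::scale_x_continuous(limits = c(0, nseg * L), expand = c(0, 0)) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (p_hyp + patchwork::plot_spacer() +
       p_raster + p_right +
       p_bottom + patchwork::plot_spacer()) +
      patchwork::plot_layout(ncol = 2, widths = c(4, 1),
                             heights = c(1, 4, 1))
  } else {
    p_raster
  }
}

#' @export
autoplot.scrub_grid_set <- function(object, scoring = NULL, ...) {
  plot_quality(object, scoring, ...)
}

write_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid$values * 1L)
  names(df) <- paste0("seg", seq_len(ncol(df)))
  write.csv(cbind(channel = grid$channels, df), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Run the full cleaning pipeline from a config
#'
#' detect -> grids -> repair -> select -> summarize, driven by a YAML file or
#' an equivalent nested list. The config names its inputs (`recording`,
#' `scoring`, `layout` — or a `synthetic` block to generate them), the
#' detector set (`"default"` or an inline serialized set), grid parameters,
#' repair method and selection spec. Outputs written to `output_dir`:
#' per-detector event CSVs, grid CSVs with a JSON parameter sidecar,
#' `summary.json`, a bout table, optionally a repaired EDF, and a
#' `quality.png` figure (skipped with a warning when no graphics device is
#' available). All defaulted decisions are appended to `pipeline.log`.
#'
#' @param config Path to a YAML config, or a nested list with the same
#'   structure.
#' @param output_dir Overrides the config's `output_dir`.
#' @return Invisibly, a list with `grid_set`, `summary` (tibble),
#'   `selection`, `repaired`, and `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) abort("Config must name an `output_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(config$synthetic)) {
    sc_args <- config$synthetic
    sc <- do.call(synth_config, sc_args)
    gen <- gen_recording(sc)
    rec <- gen$recording; scor <- gen$scoring; layout <- gen$layout
    note("inputs: synthetic recording (seed %d, %d channels, %g s)",
         sc$seed, sc$n_channels, sc$duration_s)
  } else {
    rec <- read_recording(config$recording$path,
                          config$recording$format %||% "edf")
    scor <- if (!is.null(config$scoring)) {
      read_scoring(config$scoring$path,
                   config$scoring$epoch_length_s %||% 30)
    } else NULL
    layout <- if (!is.null(config$layout)) {
      build_neighbors(read_layout(config$layout$path),
                      threshold = config$layout$neighbor_threshold)
    } else NULL
  }

  det_cfg <- config$detectors %||% "default"
  set <- if (identical(det_cfg, "default")) {
    note("detectors: default set at fs = %g Hz", rec$sample_rate_hz)
    default_detector_set(rec$sample_rate_hz)
  } else if (is.character(det_cfg)) {
    detector_set_from_yaml(paste(readLines(det_cfg), collapse = "\n"))
  } else {
    detector_set_from_yaml(yaml::as.yaml(det_cfg))
  }

  event_map <- run_detector_set(rec, set, scor, layout)
  files <- character()
  for (nm in names(event_map)) {
    f <- file.path(out_dir, paste0("events_", nm, ".csv"))
    write_event_table(event_map[[nm]], f)
    files <- c(files, f)
  }

  g <- config$grid %||% list()
  params <- grid_params(
    segment_length_s = g$segment_length_s %||% 5,
    element_min_proportion = g$element_min_proportion %||% 0,
    spatial_threshold = g$spatial_threshold,
    rejection_threshold = g$rejection_threshold,
    temporal_threshold = g$temporal_threshold,
    rejection_input = g$rejection_input %||% "combined")
  note("grid: segment %g s, spatial %s, rejection %s, temporal %s",
       params$segment_length_s,
       params$spatial_threshold %||% "off",
       params$rejection_threshold %||% "off",
       params$temporal_threshold %||% "off")
  grid_set <- build_grid_set(event_map, rec$channel_labels, duration_s(rec),
                             params, layout)
  for (nm in c("basic", "spatial", "temporal", "repair")) {
    f <- file.path(out_dir, paste0("grid_", nm, ".csv"))
    write_grid_csv(grid_set[[nm]], f)
    files <- c(files, f)
  }
  jsonlite::write_json(
    list(segment_length_s = params$segment_length_s,
         n_segments = grid_set$basic$n_segments,
         channels = grid_set$basic$channels,
         rejection = grid_set$rejection,
         params = params[!vapply(params, is.null, TRUE)]),
    file.path(out_dir, "grids.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  summary_tbl <- grid_summary(grid_set, scor)
  jsonlite::write_json(summary_tbl, file.path(out_dir, "summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, c("grids.json", "summary.json")))

  rep_cfg <- config$repair %||% list(method = "none")
  repaired <- NULL
  if (!identical(rep_cfg$method %||% "none", "none")) {
    res <- repair_by_grid(rec, grid_set$repair, layout,
                          method = rep_cfg$method,
                          crossfade_s = rep_cfg$crossfade_s %||% 0.1)
    repaired <- res$recording
    if (nrow(res$not_repairable)) {
      write.csv(as.data.frame(res$not_repairable),
                file.path(out_dir, "not_repairable.csv"), row.names = FALSE)
      note("repair: %d channel-segment element(s) not repairable",
           nrow(res$not_repairable))
    }
    if (isTRUE(rep_cfg$write_edf) && !anyNA(repaired$data)) {
      f <- file.path(out_dir, "repaired.edf")
      write_edf(repaired, f)
      files <- c(files, f)
    }
  }

  sel_cfg <- config$selection
  sel <- NULL
  if (!is.null(sel_cfg)) {
    sel <- select_clean(repaired %||% rec, grid_set$rejection,
                        params$segment_length_s, scor,
                        stages = sel_cfg$stages %||% "ALL",
                        min_duration_s = sel_cfg$min_duration_s %||% 0,
                        mode = sel_cfg$mode %||% "trials")
    f <- file.path(out_dir, "bouts.csv")
    write_bout_table(sel$bouts, f)
    files <- c(files, f)
  }

  fig <- tryCatch({
    p <- plot_quality(grid_set, scor)
    f <- file.path(out_dir, "quality.png")
    suppressMessages(ggplot2::ggsave(f, p, width = 9, height = 6, dpi = 120))
    f
  }, error = function(e) {
    warn(paste0("Quality figure could not be written: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(fig)) files <- c(files, fig)

  writeLines(log_lines, log_path)
  invisible(list(grid_set = grid_set, summary = summary_tbl, selection = sel,
                 repaired = repaired, files = files))
}
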