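#' Electrode layout
#'
#' Per-channel 3-D scalp coordinates plus a (possibly empty) symmetric
#' neighborhood map. Units are arbitrary; the head is assumed approximately
#' spherical. Positions are centered and projected to the unit sphere only
#' inside the spherical-spline routines, not here.
#'
#' @param labels Character vector of unique channel labels.
#' @param positions Numeric matrix, one row per label, columns x/y/z.
#' @param neighbor_map Named list (label -> character vector of neighbor
#'   labels); must be symmetric and free of self-neighbors.
#' @return An object of class `scrub_layout`.
#' @export
electrode_layout <- function(labels, positions, neighbor_map = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("Electrode labels must be unique.")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 3L) {
    abort("`positions` must be an n x 3 matrix matching `labels`.")
  }
  if (!all(is.finite(positions))) abort("Electrode coordinates must be finite.")
  rownames(positions) <- labels
  if (is.null(neighbor_map)) {
    neighbor_map <- stats::setNames(rep(list(character()), length(labels)), labels)
  }
  for (lab in names(neighbor_map)) {
    nb <- neighbor_map[[lab]]
    if (lab %in% nb) abort(paste0("Channel ", lab, " listed as its own neighbor."))
    for (b in nb) {
      if (!lab %in% neighbor_map[[b]]) {
        abort(paste0("Neighbor map is not symmetric: ", lab, " -> ", b))
      }
    }
  }
  structure(list(labels = labels, positions = positions,
                 neighbor_map = neighbor_map),
            class = "scrub_layout")
}

#' @export
print.scrub_layout <- function(x, ...) {
  deg <- lengths(x$neighbor_map)
  cat(sprintf("<scrub_layout> %d electrodes; neighbor degree %s\n",
              length(x$labels),
              if (all(deg == 0)) "unset" else
                sprintf("median %g (range %g-%g)", median(deg), min(deg), max(deg))))
  invisible(x)
}

#' Read electrode coordinates from a delimited text file
#'
#' Expects rows of `label, x, y, z` (comma, tab or whitespace separated). A
#' single leading header line is skipped automatically when its coordinate
#' fields are non-numeric. The returned layout has an empty neighbor map; call
#' [build_neighbors()] next.
#'
#' @param path File path.
#' @return A [electrode_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("Empty layout file: ", path))
  parse_row <- function(line) strsplit(trimws(line), "[,\t ]+")[[1]]
  first <- parse_row(lines[1L])
  start <- 1L
  # a header line ("label,x,y,z") has no numeric coordinate at all; a data
  # row with one bad coordinate is an error, not a header
  if (length(first) >= 4L && all(is.na(suppressWarnings(as.numeric(first[2:4]))))) {
    start <- 2L
  }
  if (start > length(lines)) abort(paste0("No data rows in layout file: ", path))
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- parse_row(lines[i])
    if (length(f) < 4L) abort(paste0("Layout row ", i, " has fewer than 4 fields."))
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz))) {
      abort(paste0("Non-numeric coordinate in layout row ", i, ": ", lines[i]))
    }
    list(label = f[1L], xyz = xyz)
  })
  labels <- vapply(rows, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    abort(paste0("Duplicate electrode label in layout: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  electrode_layout(labels, do.call(rbind, lapply(rows, `[[`, "xyz")))
}

#' Build a neighborhood map from electrode distances
#'
#' Channels a, b are neighbors iff their Euclidean distance is at most
#' `threshold`. `threshold = Inf` yields the all-to-all map. The default
#' threshold is 0.35 times the median distance of electrodes from their
#' centroid (median head radius), a degree of locality that on a regular
#' whole-head montage yields a ring of immediate neighbors.
#'
#' @param layout A [electrode_layout()].
#' @param method Only `"distance"` is implemented.
#' @param threshold Distance cutoff (same units as the coordinates).
#' @return The layout with `neighbor_map` filled in.
#' @export
build_neighbors <- function(layout, method = "distance",
                            threshold = NULL) {
  method <- match.arg(method, "distance")
  pos <- layout$positions
  if (is.null(threshold)) {
    ctr <- colMeans(pos)
    radii <- sqrt(rowSums(sweep(pos, 2L, ctr)^2))
    threshold <- 0.35 * median(radii)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number (possibly Inf).")
  }
  d <- as.matrix(stats::dist(pos))
  nb <- lapply(seq_along(layout$labels), function(i) {
    layout$labels[d[i, ] <= threshold & seq_along(layout$labels) != i]
  })
  electrode_layout(layout$labels, pos, stats::setNames(nb, layout$labels))
}
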