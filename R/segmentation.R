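#' Detect mother-machine trenches in a frame
#'
#' Locates the periodic column structure of the trench array from a single
#' fluorescence frame: the medium-filled trenches carry a higher background
#' than the PDMS bulk, so the per-column median profile is bimodal and
#' thresholding it at the midpoint of its range yields one contiguous run of
#' columns per trench.  Row extent is recovered the same way from the
#' per-row profile restricted to trench columns.  Both orientations are
#' tried; the one yielding more periodic runs wins, so a transposed frame
#' returns the same trenches under the transposed convention.
#'
#' @param frame numeric matrix (one channel, counts).
#' @param min_contrast minimum profile range (counts) below which the frame
#'   is considered structureless.
#' @return a data.frame of class `trench_map` with columns `trench_id`,
#'   `row0`, `row1`, `col0`, `col1` (0-based, half-open pixel rectangles,
#'   sorted by position) and attribute `orientation` (`"columns"` or
#'   `"rows"`).  Empty (with a warning) when no periodic structure is found.
#' @export
detect_trenches <- function(frame, min_contrast = 10) {
  runs_of <- function(profile, thr = mean(range(profile))) {
    if (diff(range(profile)) < min_contrast) return(NULL)
    above <- profile > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(start = starts[r$values], end = ends[r$values])
  }
  ## threshold for the along-trench extent: bright cells inflate the profile
  ## maximum, so separate the outside level from the (cell-robust) upper
  ## quartile instead of the range midpoint
  extent_thr <- function(profile)
    min(profile) + 0.5 * (stats::quantile(profile, 0.75, names = FALSE) -
                            min(profile))
  empty_map <- function() {
    warning("no periodic trench structure found; returning empty trench map")
    structure(data.frame(trench_id = integer(), row0 = integer(),
                         row1 = integer(), col0 = integer(),
                         col1 = integer()),
              class = c("trench_map", "data.frame"), orientation = "columns")
  }

  col_runs <- runs_of(apply(frame, 2, stats::median))
  row_runs <- runs_of(apply(frame, 1, stats::median))
  n_col <- if (is.null(col_runs)) 0 else nrow(col_runs)
  n_row <- if (is.null(row_runs)) 0 else nrow(row_runs)
  if (n_col == 0 && n_row == 0) return(empty_map())
  orientation <- if (n_col >= n_row) "columns" else "rows"

  if (orientation == "columns") {
    runs <- col_runs
    cols <- unlist(lapply(seq_len(nrow(runs)),
                          function(i) runs[i, 1]:runs[i, 2]))
    prof <- apply(frame[, cols, drop = FALSE], 1, stats::median)
    extent <- runs_of(prof, extent_thr(prof))
    if (is.null(extent)) return(empty_map())
    r0 <- unname(extent[1, 1]) - 1L
    r1 <- unname(extent[nrow(extent), 2])
    map <- data.frame(trench_id = seq_len(nrow(runs)),
                      row0 = r0, row1 = r1,
                      col0 = unname(runs[, 1] - 1L), col1 = unname(runs[, 2]))
  } else {
    runs <- row_runs
    rows <- unlist(lapply(seq_len(nrow(runs)),
                          function(i) runs[i, 1]:runs[i, 2]))
    prof <- apply(frame[rows, , drop = FALSE], 2, stats::median)
    extent <- runs_of(prof, extent_thr(prof))
    if (is.null(extent)) return(empty_map())
    c0 <- unname(extent[1, 1]) - 1L
    c1 <- unname(extent[nrow(extent), 2])
    map <- data.frame(trench_id = seq_len(nrow(runs)),
                      row0 = unname(runs[, 1] - 1L), row1 = unname(runs[, 2]),
                      col0 = c0, col1 = c1)
  }
  structure(map, class = c("trench_map", "data.frame"),
            orientation = orientation)
}

#' Crop one trench out of a frame
#'
#' @param frame numeric matrix.
#' @param trench_map a [detect_trenches()] map.
#' @param trench_id trench to crop.
#' @return numeric matrix; for `"rows"` orientation the crop is transposed so
#'   the closed end is always at the top.
#' @export
crop_trench <- function(frame, trench_map, trench_id) {
  t <- trench_map[trench_map$trench_id == trench_id, ]
  if (!nrow(t)) stop(sprintf("trench %d not in map", trench_id))
  m <- frame[(t$row0 + 1):t$row1, (t$col0 + 1):t$col1, drop = FALSE]
  if (identical(attr(trench_map, "orientation"), "rows")) m <- t(m)
  m
}

#' Segment bacteria inside one trench
#'
#' Per-trench automatic (Otsu) thresholding on the detection channel,
#' connected-component labelling, removal of components below the
#' minimum-size filter, and a distance-transform watershed split of
#' components longer than twice the median cell length (division doublets).
#' Labels are assigned from the closed end (top) toward the open end.
#'
#' The constitutively bright, pH-independent TRITC (mCherry) channel is the
#' intended detection channel.
#'
#' @param trench_raster numeric matrix, one trench crop of the detection
#'   channel (closed end at the top).
#' @param pixels_per_micron raster scale, used to convert the size filter and
#'   geometry to physical units.
#' @param min_area_um2 minimum cell area (um^2); smaller components are
#'   discarded.
#' @param min_contrast minimum foreground-background separation (counts) for
#'   the threshold to be considered evidence of cells.
#' @param bit_depth camera bit depth, for the saturation guard.
#' @param split_doublets watershed-split over-long components.
#' @return list of cell masks, each a list with `label`, `pixels` (linear
#'   indices into the trench raster), `centroid_px` (row, col), `top_px`,
#'   `length_um`, `width_um`, `area_um2`.
#' @export
segment_cells <- function(trench_raster, pixels_per_micron,
                          min_area_um2 = 0.5, min_contrast = 50,
                          bit_depth = 16, split_doublets = TRUE) {
  if (mean(trench_raster >= 2^bit_depth - 1) > 0.2)
    stop("trench raster is saturated; check the camera bit depth / exposure")
  rng <- range(trench_raster)
  if (diff(rng) == 0) return(list())

  norm <- (trench_raster - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg) || all(fg)) return(list())
  if (mean(trench_raster[fg]) - mean(trench_raster[!fg]) < min_contrast)
    return(list())

  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- as.matrix(EBImage::imageData(lab))
  min_px <- max(1, round(min_area_um2 * pixels_per_micron^2))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  if (!length(keep)) return(list())
  lab[!(lab %in% keep)] <- 0

  ## split long components (likely touching cells) on the distance transform
  if (split_doublets && length(keep) >= 1) {
    lens <- vapply(keep, function(l) {
      rows <- which(lab == l, arr.ind = TRUE)[, 1]
      diff(range(rows)) + 1
    }, numeric(1))
    med_len <- stats::median(lens)
    long <- keep[lens > 2 * med_len]
    for (l in long) {
      comp <- lab == l
      dm <- EBImage::distmap(EBImage::Image(comp))
      ws <- as.matrix(EBImage::imageData(EBImage::watershed(dm)))
      if (max(ws) > 1) {
        lab[comp] <- 0
        base <- max(lab)
        lab[ws > 0 & comp] <- base + ws[ws > 0 & comp]
      }
    }
  }

  labels <- sort(unique(lab[lab > 0]))
  masks <- lapply(labels, function(l) {
    idx <- which(lab == l)
    rc <- arrayInd(idx, dim(lab))
    list(pixels = idx,
         centroid_px = c(mean(rc[, 1]), mean(rc[, 2])),
         top_px = min(rc[, 1]),
         length_um = (diff(range(rc[, 1])) + 1) / pixels_per_micron,
         width_um = (diff(range(rc[, 2])) + 1) / pixels_per_micron,
         area_um2 = length(idx) / pixels_per_micron^2)
  })
  ## labels from the closed end (top) toward the open end
  ord <- order(vapply(masks, function(m) m$centroid_px[1], numeric(1)))
  masks <- masks[ord]
  for (i in seq_along(masks)) masks[[i]]$label <- i
  masks
}

#' @export
print.trench_map <- function(x, ...) {
  cat(sprintf("<trench_map> %d trench(es), orientation %s\n",
              nrow(x), attr(x, "orientation")))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}
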