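#' Write an image stack as multi-page TIFF files
#'
#' One file per field and channel, page order following the imaging
#' schedule; the post-PI TRITC frame, when present, is appended as the last
#' page of the TRITC file.  Counts are stored as 16-bit-normalized
#' grayscale.
#'
#' @param stack an `mm_stack`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_stack_tiff <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxc <- 2^stack$optics$bit_depth - 1
  paths <- character(0)
  for (f in seq_along(stack$fields)) {
    field <- stack$fields[[f]]
    for (ch in c("fitc", "tritc")) {
      pages <- lapply(field$frames, function(fr) fr[[ch]] / maxc)
      if (ch == "tritc" && !is.null(field$post_pi))
        pages <- c(pages, list(field$post_pi / maxc))
      path <- file.path(dir, sprintf("field%02d_%s.tif", f, toupper(ch)))
      tiff::writeTIFF(pages, path, bits.per.sample = 16)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Write segmentation masks as a label image TIFF and geometry CSV
#'
#' @param masks mask list from [segment_cells()].
#' @param dim dimensions of the trench raster the masks index into.
#' @param tiff_path,csv_path output paths (either may be `NULL` to skip).
#' @param pixels_per_micron raster scale for the geometry table.
#' @return invisibly, the label matrix.
#' @export
write_masks <- function(masks, dim, tiff_path = NULL, csv_path = NULL,
                        pixels_per_micron = 1) {
  lab <- matrix(0L, dim[1], dim[2])
  for (m in masks) lab[m$pixels] <- m$label
  if (!is.null(tiff_path))
    tiff::writeTIFF(lab / max(1L, max(lab)), tiff_path, bits.per.sample = 16)
  if (!is.null(csv_path)) {
    geo <- do.call(rbind, lapply(masks, function(m)
      data.frame(label = m$label,
                 centroid_row_px = m$centroid_px[1],
                 centroid_col_px = m$centroid_px[2],
                 length_um = m$length_um, width_um = m$width_um,
                 area_um2 = m$area_um2)))
    utils::write.csv(geo, csv_path, row.names = FALSE)
  }
  invisible(lab)
}
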