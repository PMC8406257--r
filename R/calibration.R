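#' Fit the linear ratio-to-pH calibration
#'
#' Ordinary least squares of pH on the mean measured ratio per standard
#' (each buffer standard gets equal weight regardless of how many cells it
#' contributed).  The regression direction is the inverse map the pipeline
#' applies, so no per-call inversion is needed.  The model's validity range
#' is fixed to the pHluorin linear regime, pH 6.5 to 8.0.
#'
#' @param points data.frame with columns `ph` (the known standard) and
#'   `ratio` (one row per measured cell).
#' @return object of class `calibration_model`: slope `a` (pH per ratio
#'   unit), intercept `b` (pH), `valid_range`, and fit diagnostics
#'   (`n_standards`, `residual_sd`, `r_squared`, the per-standard means).
#' @export
fit_calibration <- function(points) {
  points <- points[!is.na(points$ratio), , drop = FALSE]
  agg <- stats::aggregate(ratio ~ ph, data = points, FUN = mean)
  if (nrow(agg) < 2)
    stop("need at least 2 distinct pH standards to fit a calibration")
  if (stats::sd(agg$ratio) == 0)
    stop("degenerate calibration: identical ratios across standards")
  fit <- stats::lm(ph ~ ratio, data = agg)
  s <- suppressWarnings(summary(fit)) # "essentially perfect fit" is expected
                                      # for noiseless standards
  structure(
    list(a = unname(stats::coef(fit)[2]),
         b = unname(stats::coef(fit)[1]),
         valid_range = c(6.5, 8.0),
         n_standards = nrow(agg),
         residual_sd = if (nrow(agg) > 2) s$sigma else 0,
         r_squared = if (nrow(agg) > 2) s$r.squared else 1,
         standards = agg),
    class = "calibration_model")
}

#' Convert measured ratios to pH estimates
#'
#' Applies `pH = a R + b` and flags estimates outside the pHluorin linear
#' validity range [6.5, 8.0] as invalid.  Invalid values are retained in the
#' returned table (so nothing silently vanishes) but must be excluded from
#' downstream means and histograms; [ph_distribution()] does so.
#'
#' @param model a [fit_calibration()] model.
#' @param ratio numeric vector (NA propagates to NA pH with `valid = FALSE`).
#' @return data.frame with columns `ph` and `valid`.
#' @export
ratio_to_ph <- function(model, ratio) {
  ph <- model$a * ratio + model$b
  valid <- !is.na(ph) & ph >= model$valid_range[1] & ph <= model$valid_range[2]
  data.frame(ph = ph, valid = valid)
}

#' Extract per-cell calibration points from a rendered standard set
#'
#' Image-mode sets go through the same trench detection, segmentation and
#' background-subtracted photometry as experimental frames; trace-mode sets
#' use the emitted intensities directly.
#'
#' @param calset a [render_calibration_set()] result.
#' @param min_area_um2,low_floor segmentation/photometry settings (image
#'   mode).
#' @return data.frame with columns `ph` and `ratio`, ready for
#'   [fit_calibration()].
#' @export
calibration_points <- function(calset, min_area_um2 = 0.5, low_floor = 10) {
  if (calset$mode == "trace") {
    rows <- do.call(rbind, calset$sets)
    return(data.frame(ph = rows$standard_ph,
                      ratio = rows$fitc / rows$tritc))
  }
  optics <- calset$optics
  out <- lapply(calset$sets, function(stack) {
    ratios <- unlist(lapply(stack$fields, function(field) {
      fr <- field$frames[[1]]
      tm <- detect_trenches(fr$tritc)
      unlist(lapply(tm$trench_id, function(k) {
        tritc <- crop_trench(fr$tritc, tm, k)
        fitc <- crop_trench(fr$fitc, tm, k)
        masks <- segment_cells(tritc, optics$pixels_per_micron,
                               min_area_um2 = min_area_um2,
                               bit_depth = optics$bit_depth)
        if (!length(masks)) return(numeric(0))
        bg <- estimate_background(fitc, tritc, masks)
        vapply(masks, function(m)
          measure_cell(m, fitc, tritc, bg, low_floor)$ratio, numeric(1))
      }))
    }))
    data.frame(ph = stack$standard_ph, ratio = ratios)
  })
  do.call(rbind, out)
}

#' Read / write a calibration model as a key-value file
#'
#' @param model a `calibration_model`.
#' @param path file path (YAML).
#' @return `read_calibration` returns a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  out <- unclass(model)
  out$standards <- as.list(out$standards)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$standards <- as.data.frame(raw$standards)
  raw$valid_range <- as.numeric(raw$valid_range)
  structure(raw, class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> pH = %.4g R + %.4g\n", x$a, x$b))
  cat(sprintf("  %d standards, residual SD %.3g pH, R^2 %.5g, valid pH [%.1f, %.1f]\n",
              x$n_standards, x$residual_sd, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
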