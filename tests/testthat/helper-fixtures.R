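# Shared fixtures: everything is generated in code at test time.

# A rectangular mask in a raster of dimensions `dm`, in segment_cells layout.
rect_mask <- function(dm, r0, r1, c0, c1, label = 1) {
  idx <- as.vector(outer(r0:r1, (c0:c1 - 1) * dm[1], `+`))
  rc <- arrayInd(idx, dm)
  list(pixels = idx,
       centroid_px = c(mean(rc[, 1]), mean(rc[, 2])),
       top_px = min(rc[, 1]),
       length_um = (r1 - r0 + 1),
       width_um = (c1 - c0 + 1),
       area_um2 = length(idx),
       label = label)
}

# Trench raster with uniform background plus rectangular cells.
trench_raster <- function(dm = c(120, 10), bg = 100, cells = list()) {
  m <- matrix(bg, dm[1], dm[2])
  for (cl in cells) m[cl$r0:cl$r1, cl$c0:cl$c1] <- cl$value
  m
}

# End-to-end trace run on a given preset without file output.
trace_run <- function(preset, n, seed, ...) {
  run_experiment(run_config(preset = preset, n_lineages = n, mode = "trace",
                            seed = seed, ...), quiet = TRUE)
}

# Fitted calibration from rendered standards for a given optics/mode.
fit_from_standards <- function(optics, mode = "image", seed = 7,
                               standards = c(6.5, 7.0, 7.5, 8.0)) {
  fit_calibration(calibration_points(
    render_calibration_set(standards, optics, seed = seed, mode = mode)))
}
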