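#' Optics and rendering configuration for the synthetic microscope
#'
#' Describes the raster geometry (trench layout, pixel scale), the sCMOS
#' noise model (Poisson shot noise on expected counts plus additive Gaussian
#' read noise), per-channel backgrounds, and the ground-truth map linking
#' intracellular pH to the expected FITC/TRITC intensity ratio.
#'
#' The ground-truth map is the line `pH = ph_slope * R + ph_intercept`
#' (defaults 5 and 4, so pH 7.5 corresponds to R = 0.7); the renderer emits
#' `FITC = R(pH) * TRITC`, with both channels scaled by the cell's expression
#' level so that the ratio cancels expression and copy-number variation.
#'
#' @param pixels_per_micron raster scale (px/um).
#' @param trench_length_um,trench_width_um,trench_pitch_um trench geometry
#'   (um); the closed end is at the top of the raster.
#' @param n_trenches trenches per rendered field of view.
#' @param margin_um blank margin above/below the trench row (um).
#' @param psf_sigma_um Gaussian PSF sigma (um); 0 disables blurring.
#' @param bg_fitc,bg_tritc expected in-trench background level per channel
#'   (counts); outside-trench background is `bg_outside_frac` of it.
#' @param bg_outside_frac fraction of the in-trench background seen in the
#'   PDMS bulk between trenches.
#' @param shot_noise logical; Poisson noise on expected counts.
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param bit_depth camera bit depth; counts are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param tritc_scale expected per-pixel TRITC signal (counts above
#'   background) for a cell of expression level 1.
#' @param ph_slope,ph_intercept ground-truth calibration line
#'   (pH units per ratio unit; pH units).  `ph_slope` must be positive so the
#'   map is strictly increasing over pH [6.0, 8.5].
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(pixels_per_micron = 6,
                          trench_length_um = 20,
                          trench_width_um = 1.6,
                          trench_pitch_um = 5,
                          n_trenches = 12,
                          margin_um = 2,
                          psf_sigma_um = 0,
                          bg_fitc = 100,
                          bg_tritc = 100,
                          bg_outside_frac = 0.5,
                          shot_noise = TRUE,
                          read_noise_sd = 2,
                          bit_depth = 16,
                          tritc_scale = 1000,
                          ph_slope = 5,
                          ph_intercept = 4) {
  optics <- structure(
    list(pixels_per_micron = pixels_per_micron,
         trench_length_um = trench_length_um,
         trench_width_um = trench_width_um,
         trench_pitch_um = trench_pitch_um,
         n_trenches = n_trenches,
         margin_um = margin_um,
         psf_sigma_um = psf_sigma_um,
         bg_fitc = bg_fitc,
         bg_tritc = bg_tritc,
         bg_outside_frac = bg_outside_frac,
         shot_noise = shot_noise,
         read_noise_sd = read_noise_sd,
         bit_depth = bit_depth,
         tritc_scale = tritc_scale,
         ph_slope = ph_slope,
         ph_intercept = ph_intercept),
    class = "optics_config")
  validate_optics(optics)
}

#' @rdname optics_config
#' @param optics an `optics_config`.
#' @export
validate_optics <- function(optics) {
  lens <- c("pixels_per_micron", "trench_length_um", "trench_width_um",
            "trench_pitch_um", "margin_um", "tritc_scale")
  for (f in lens)
    if (optics[[f]] <= 0) stop(sprintf("%s: must be positive", f))
  if (optics$n_trenches < 1) stop("n_trenches: must be at least 1")
  if (optics$trench_width_um >= optics$trench_pitch_um)
    stop("trench_width_um: must be smaller than trench_pitch_um")
  if (optics$bg_fitc < 0 || optics$bg_tritc < 0)
    stop("bg_fitc/bg_tritc: background must be non-negative")
  if (optics$read_noise_sd < 0) stop("read_noise_sd: must be non-negative")
  if (optics$psf_sigma_um < 0) stop("psf_sigma_um: must be non-negative")
  if (optics$ph_slope <= 0)
    stop("ph_slope: ground-truth map must be strictly increasing in R")
  if (!optics$bit_depth %in% c(8, 12, 16)) stop("bit_depth: use 8, 12 or 16")
  optics
}

#' Turn off all rendering noise
#'
#' @param optics an `optics_config`.
#' @return the config with shot noise disabled and read noise zero.
#' @export
optics_noiseless <- function(optics) {
  optics$shot_noise <- FALSE
  optics$read_noise_sd <- 0
  optics
}

#' Ground-truth pH/ratio map
#'
#' Forward and inverse evaluation of the generator's calibration line.  The
#' analysis pipeline never uses these; they exist so tests can compare fitted
#' calibrations and measured ratios against planted truth.
#'
#' @param optics an `optics_config`.
#' @param ph,ratio numeric vectors.
#' @return numeric vector.
#' @export
true_ratio_of_ph <- function(optics, ph) {
  (ph - optics$ph_intercept) / optics$ph_slope
}

#' @rdname true_ratio_of_ph
#' @export
true_ph_of_ratio <- function(optics, ratio) {
  optics$ph_slope * ratio + optics$ph_intercept
}

## raster geometry helpers (package-internal); all pixel rectangles are
## 0-based, row-major, half-open, rows increasing away from the closed end
frame_dim_px <- function(optics) {
  ppm <- optics$pixels_per_micron
  c(rows = round((optics$trench_length_um + 2 * optics$margin_um) * ppm),
    cols = round(optics$n_trenches * optics$trench_pitch_um * ppm))
}

trench_rects <- function(optics) {
  ppm <- optics$pixels_per_micron
  gap <- (optics$trench_pitch_um - optics$trench_width_um) / 2
  r0 <- round(optics$margin_um * ppm)
  r1 <- round((optics$margin_um + optics$trench_length_um) * ppm)
  k <- seq_len(optics$n_trenches)
  c0 <- round(((k - 1) * optics$trench_pitch_um + gap) * ppm)
  c1 <- round(((k - 1) * optics$trench_pitch_um + gap +
                 optics$trench_width_um) * ppm)
  data.frame(trench_id = k, row0 = r0, row1 = r1, col0 = c0, col1 = c1)
}

#' @export
print.optics_config <- function(x, ...) {
  d <- frame_dim_px(x)
  cat(sprintf("<optics_config> %d trenches, %.3g px/um, field %d x %d px\n",
              x$n_trenches, x$pixels_per_micron, d["rows"], d["cols"]))
  cat(sprintf("  noise: shot %s, read SD %.3g counts, bit depth %d\n",
              if (x$shot_noise) "on" else "off", x$read_noise_sd, x$bit_depth))
  cat(sprintf("  ground-truth map: pH = %.3g R + %.3g\n",
              x$ph_slope, x$ph_intercept))
  invisible(x)
}
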