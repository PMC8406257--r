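## Shared frame rasteriser.  `cells` carries one row per cell with local
## trench index, axial placement (um from the closed end) and the expected
## per-pixel TRITC signal and FITC/TRITC ratio.  Expected images are built
## first; Poisson shot noise and Gaussian read noise are applied afterwards
## (sCMOS model), then counts are clipped to the camera bit depth.
.render_frame <- function(cells, optics, noisy = TRUE) {
  d <- frame_dim_px(optics)
  rects <- trench_rects(optics)
  ppm <- optics$pixels_per_micron

  out_f <- optics$bg_fitc * optics$bg_outside_frac
  out_t <- optics$bg_tritc * optics$bg_outside_frac
  e_fitc <- matrix(out_f, d["rows"], d["cols"])
  e_tritc <- matrix(out_t, d["rows"], d["cols"])
  for (k in seq_len(nrow(rects))) {
    rr <- (rects$row0[k] + 1):rects$row1[k]
    cc <- (rects$col0[k] + 1):rects$col1[k]
    e_fitc[rr, cc] <- optics$bg_fitc
    e_tritc[rr, cc] <- optics$bg_tritc
  }

  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      k <- cells$trench[i]
      if (cells$top_um[i] + cells$length_um[i] > optics$trench_length_um)
        stop(sprintf(
          "trench %d: cells exceed trench capacity (%.1f um needed, %.1f um available)",
          k, cells$top_um[i] + cells$length_um[i], optics$trench_length_um))
      r0 <- rects$row0[k] + round(cells$top_um[i] * ppm) + 1
      r1 <- rects$row0[k] + round((cells$top_um[i] + cells$length_um[i]) * ppm)
      inset <- round((optics$trench_width_um - cells$width_um[i]) / 2 * ppm)
      c0 <- rects$col0[k] + inset + 1
      c1 <- rects$col1[k] - inset
      tr <- cells$tritc_px[i]
      e_fitc[r0:r1, c0:c1] <- e_fitc[r0:r1, c0:c1] + cells$ratio[i] * tr
      e_tritc[r0:r1, c0:c1] <- e_tritc[r0:r1, c0:c1] + tr
    }
  }

  if (optics$psf_sigma_um > 0) {
    sig <- optics$psf_sigma_um * ppm
    e_fitc <- as.matrix(EBImage::gblur(EBImage::Image(e_fitc), sigma = sig))
    e_tritc <- as.matrix(EBImage::gblur(EBImage::Image(e_tritc), sigma = sig))
  }

  maxc <- 2^optics$bit_depth - 1
  emit <- function(e) {
    x <- e
    if (noisy && optics$shot_noise)
      x <- matrix(stats::rpois(length(e), e), nrow(e), ncol(e))
    if (noisy && optics$read_noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, optics$read_noise_sd)
    pmin(pmax(x, 0), maxc)
  }
  list(fitc = emit(e_fitc), tritc = emit(e_tritc))
}

## cells of one cohort frame restricted to one field, in render_frame layout
.field_cells <- function(cohort, optics, frame_h, offset) {
  cells <- cohort_cells(cohort, frame_h)
  cells <- cells[cells$trench_id > offset &
                   cells$trench_id <= offset + optics$n_trenches, ,
                 drop = FALSE]
  data.frame(trench = cells$trench_id - offset,
             top_um = cells$top_um,
             length_um = cells$length_um,
             width_um = cells$width_um,
             tritc_px = cells$expression * cells$tritc_factor *
               optics$tritc_scale,
             ratio = true_ratio_of_ph(optics, cells$true_ph))
}

#' Render a cohort as image stacks or intensity traces
#'
#' In `image` mode the cohort is laid out in fields of view of
#' `optics$n_trenches` trenches and rendered frame by frame into two-channel
#' rasters (FITC carries the pH-dependent pHluorin signal, TRITC the
#' pH-independent mCherry signal; both scale with the cell's expression level
#' so their ratio cancels it).  In `trace` mode the per-lineage
#' noiseless-equivalent intensities are emitted directly, skipping the
#' raster.
#'
#' Lysed lineages emit nothing from their lysis time onward; divided
#' lineages contribute the mother and an abutting daughter.
#'
#' @param cohort an [make_cohort()] cohort.
#' @param optics an [optics_config()].
#' @param mode `"image"` or `"trace"`.
#' @param seed integer seed for the rendering noise (unused in trace mode).
#' @return `image` mode: an object of class `mm_stack` (list of fields, each
#'   holding per-frame `fitc`/`tritc` matrices).  `trace` mode: a data.frame
#'   of class `mm_traces` with columns `lineage_id`, `trench_id`, `frame_h`,
#'   `n_cells`, `fitc`, `tritc` (NA when the lineage is absent).
#' @export
render_stack <- function(cohort, optics = optics_config(),
                         mode = c("image", "trace"), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "trace") {
    li <- cohort$lineages
    rows <- lapply(cohort$schedule, function(t) {
      cells <- cohort_cells(cohort, t)
      mother <- cells[cells$cell_index == 1, , drop = FALSE]
      n_cells <- tabulate(cells$lineage_id, nbins = nrow(li))
      tritc <- rep(NA_real_, nrow(li))
      fitc <- rep(NA_real_, nrow(li))
      tritc[mother$lineage_id] <- mother$expression * mother$tritc_factor *
        optics$tritc_scale
      fitc[mother$lineage_id] <- true_ratio_of_ph(optics, mother$true_ph) *
        tritc[mother$lineage_id]
      data.frame(lineage_id = li$lineage_id, trench_id = li$trench_id,
                 frame_h = t, n_cells = n_cells, fitc = fitc, tritc = tritc)
    })
    traces <- do.call(rbind, rows)
    traces <- traces[order(traces$lineage_id, traces$frame_h), ]
    rownames(traces) <- NULL
    class(traces) <- c("mm_traces", "data.frame")
    return(traces)
  }

  withr::local_seed(as.integer(seed))
  n <- nrow(cohort$lineages)
  offsets <- seq(0, n - 1, by = optics$n_trenches)
  fields <- lapply(offsets, function(off) {
    frames <- lapply(cohort$schedule, function(t)
      .render_frame(.field_cells(cohort, optics, t, off), optics))
    names(frames) <- paste0("t", cohort$schedule)
    list(trench_offset = off, frames = frames, post_pi = NULL)
  })
  structure(list(optics = optics, schedule = cohort$schedule,
                 n_lineages = n, fields = fields),
            class = "mm_stack")
}

#' Append the end-point propidium iodide frame
#'
#' Emulates flowing propidium iodide through the device after the 24 h frame:
#' each surviving cell's TRITC signal is multiplied by its fate's PI fold
#' change (about 1 for persister and VBNC cells, >1 for membrane-compromised
#' susceptible-non-lysed cells); lysed cells are absent.
#'
#' @param stack an `mm_stack` or `mm_traces` object containing the 24 h frame.
#' @param cohort the cohort the stack was rendered from.
#' @param seed seed for the rendering noise of the post-PI frame.
#' @return the input object with a post-PI TRITC frame appended (`post_pi`
#'   matrix per field for stacks; `tritc_post_pi` column for traces).
#' @export
apply_pi_event <- function(stack, cohort, seed = 1) {
  UseMethod("apply_pi_event")
}

#' @export
apply_pi_event.mm_stack <- function(stack, cohort, seed = 1) {
  if (!"t24" %in% names(stack$fields[[1]]$frames))
    stop("stack has no 24 h frame; cannot apply the PI event")
  withr::local_seed(as.integer(seed))
  li <- cohort$lineages
  for (f in seq_along(stack$fields)) {
    off <- stack$fields[[f]]$trench_offset
    cells <- cohort_cells(cohort, 24)
    cells <- cells[cells$trench_id > off &
                     cells$trench_id <= off + stack$optics$n_trenches, ,
                   drop = FALSE]
    fold <- li$pi_fold[match(cells$lineage_id, li$lineage_id)]
    fold[is.na(fold)] <- 1
    layout <- data.frame(trench = cells$trench_id - off,
                         top_um = cells$top_um,
                         length_um = cells$length_um,
                         width_um = cells$width_um,
                         tritc_px = cells$expression * cells$tritc_factor *
                           stack$optics$tritc_scale * fold,
                         ratio = true_ratio_of_ph(stack$optics,
                                                  cells$true_ph))
    stack$fields[[f]]$post_pi <-
      .render_frame(layout, stack$optics, noisy = TRUE)$tritc
  }
  stack
}

#' @export
apply_pi_event.mm_traces <- function(stack, cohort, seed = 1) {
  if (!24 %in% stack$frame_h)
    stop("traces have no 24 h frame; cannot apply the PI event")
  li <- cohort$lineages
  fold <- li$pi_fold[match(stack$lineage_id, li$lineage_id)]
  stack$tritc_post_pi <- NA_real_
  at24 <- stack$frame_h == 24 & !is.na(stack$tritc)
  f <- ifelse(is.na(fold), 1, fold)
  stack$tritc_post_pi[at24] <- stack$tritc[at24] * f[at24]
  stack
}

#' Render a calibration standard set
#'
#' Emulates the CCCP-equilibrated calibration acquisition: for each external
#' pH standard, every cell's intracellular pH equals the standard, and a
#' single two-channel frame is rendered with the same optics as the
#' experiment.  Expression levels still vary cell to cell, which is exactly
#' what the ratio is meant to cancel.
#'
#' @param standards pH values of the buffer standards (default the four
#'   points 6.5, 7.0, 7.5, 8.0).
#' @param optics an [optics_config()].
#' @param seed integer seed.
#' @param mode `"image"` or `"trace"`.
#' @param n_cells cells rendered per standard.
#' @return object of class `mm_calibration_set`: list with `standards` and,
#'   per standard, either an `mm_stack` (image mode) or a data.frame of
#'   per-cell intensities (trace mode).
#' @export
render_calibration_set <- function(standards = c(6.5, 7.0, 7.5, 8.0),
                                   optics = optics_config(), seed = 1,
                                   mode = c("image", "trace"),
                                   n_cells = 36) {
  mode <- match.arg(mode)
  if (!length(standards)) stop("standards list is empty")
  lo <- true_ratio_of_ph(optics, min(standards))
  if (lo <= 0)
    stop("standards outside the ground-truth map domain (ratio must stay positive)")
  withr::local_seed(as.integer(seed))
  sdlog <- sqrt(log(1 + 0.25^2))

  per_standard <- lapply(standards, function(ph) {
    expr <- stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)
    if (mode == "trace") {
      tritc <- expr * optics$tritc_scale
      return(data.frame(standard_ph = ph, cell = seq_len(n_cells),
                        fitc = true_ratio_of_ph(optics, ph) * tritc,
                        tritc = tritc))
    }
    offsets <- seq(0, n_cells - 1, by = optics$n_trenches)
    fields <- lapply(offsets, function(off) {
      k <- min(optics$n_trenches, n_cells - off)
      layout <- data.frame(trench = seq_len(k), top_um = 1,
                           length_um = 3, width_um = 1,
                           tritc_px = expr[off + seq_len(k)] *
                             optics$tritc_scale,
                           ratio = true_ratio_of_ph(optics, ph))
      frames <- list(t0 = .render_frame(layout, optics))
      list(trench_offset = off, frames = frames, post_pi = NULL)
    })
    structure(list(optics = optics, schedule = 0, n_lineages = n_cells,
                   fields = fields, standard_ph = ph),
              class = "mm_stack")
  })
  structure(list(mode = mode, optics = optics, standards = standards,
                 sets = per_standard),
            class = "mm_calibration_set")
}

#' @export
print.mm_stack <- function(x, ...) {
  d <- frame_dim_px(x$optics)
  cat(sprintf("<mm_stack> %d field(s) of %d trenches, %d frame(s), %dx%d px\n",
              length(x$fields), x$optics$n_trenches,
              length(x$fields[[1]]$frames), d["rows"], d["cols"]))
  if (!is.null(x$fields[[1]]$post_pi)) cat("  post-PI TRITC frame present\n")
  invisible(x)
}
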