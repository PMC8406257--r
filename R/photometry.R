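#' Estimate per-channel background in a trench
#'
#' The background is the average fluorescence of the in-trench pixels not
#' covered by any cell mask, computed per channel.  If the trench is full
#' (no free pixels), the caller-supplied frame-level fallback is used.
#'
#' @param trench_fitc,trench_tritc numeric matrices, the two channel crops of
#'   one trench.
#' @param masks mask list from [segment_cells()] for the same crop.
#' @param stat `"mean"` (the default, matching the assay's averaging) or
#'   `"median"` for robustness.
#' @param fallback optional numeric length-2 frame-level background
#'   (FITC, TRITC) used when the trench has no free pixels.
#' @return named numeric `c(B_fitc, B_tritc)`.
#' @export
estimate_background <- function(trench_fitc, trench_tritc, masks = list(),
                                stat = c("mean", "median"),
                                fallback = NULL) {
  stat <- match.arg(stat)
  covered <- unique(unlist(lapply(masks, `[[`, "pixels")))
  free <- setdiff(seq_along(trench_fitc), covered)
  if (!length(free)) {
    if (is.null(fallback))
      stop("no background pixels available in the trench and no fallback given")
    return(c(B_fitc = fallback[1], B_tritc = fallback[2]))
  }
  f <- if (stat == "mean") mean else stats::median
  c(B_fitc = f(trench_fitc[free]), B_tritc = f(trench_tritc[free]))
}

#' Measure one cell: background-subtracted intensities and ratio
#'
#' Computes the mean FITC and TRITC intensity over the mask pixels, subtracts
#' the channel backgrounds, and forms the pHluorin/mCherry ratio
#' `R = I_FITC / I_TRITC`.  Because both channels scale identically with
#' expression level and plasmid copy number, R cancels that common-mode
#' variation.  A non-positive TRITC signal yields an undefined ratio with a
#' QC flag rather than an error; a TRITC signal below `low_floor` flags the
#' record `low_signal`.
#'
#' @param mask one mask from [segment_cells()].
#' @param trench_fitc,trench_tritc channel crops the mask indexes into.
#' @param backgrounds numeric `c(B_fitc, B_tritc)` from
#'   [estimate_background()].
#' @param low_floor minimum trusted TRITC signal (counts); default 10,
#'   i.e. 5x the default read-noise SD.
#' @return one-row data.frame: `label`, `I_fitc`, `I_tritc`, `B_fitc`,
#'   `B_tritc`, `ratio`, `qc` (`"ok"`, `"low_signal"` or `"no_tritc"`).
#' @export
measure_cell <- function(mask, trench_fitc, trench_tritc, backgrounds,
                         low_floor = 10) {
  if (!length(mask$pixels)) stop("empty mask")
  i_f <- mean(trench_fitc[mask$pixels]) - backgrounds[[1]]
  i_t <- mean(trench_tritc[mask$pixels]) - backgrounds[[2]]
  qc <- "ok"
  ratio <- NA_real_
  if (i_t <= 0) {
    qc <- "no_tritc"
  } else {
    ratio <- i_f / i_t
    if (i_t < low_floor) qc <- "low_signal"
  }
  data.frame(label = mask$label, I_fitc = i_f, I_tritc = i_t,
             B_fitc = unname(backgrounds[[1]]),
             B_tritc = unname(backgrounds[[2]]),
             ratio = ratio, qc = qc)
}
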