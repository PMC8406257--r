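#' Imaging schedule of the assay
#'
#' Frames are taken hourly through the ampicillin window (0-3 h) and the
#' first hours of regrowth, then once at the 24 h end point.
#'
#' @return numeric vector of frame times in hours.
#' @export
imaging_schedule <- function() c(0, 1, 2, 3, 4, 5, 6, 24)

#' Generate a ground-truthed synthetic cohort
#'
#' Draws `n_lineages` mother-machine lineages from a strain preset.  Each
#' lineage occupies its own trench, carries a fate drawn i.i.d. from the
#' preset's fate probabilities, a time-zero intracellular pH drawn from the
#' fate's mixture distribution, a mean-anchored pH trajectory with per-frame
#' Gaussian noise, a log-normal fluorophore expression level, and the fate's
#' end-point behaviour: persisters divide once in the division window (after
#' drug removal), susceptible-lysed lineages disappear at a lysis time inside
#' the lysis window, susceptible-non-lysed lineages stain with propidium
#' iodide and lose reporter signal, VBNC lineages neither divide nor stain.
#'
#' Everything downstream (rendering, analysis, evaluation) treats this object
#' as the ground truth.
#'
#' @param preset a [strain_preset()].
#' @param n_lineages number of lineages (= trenches) to draw.
#' @param seed integer seed; the draw is fully reproducible given
#'   (preset, n_lineages, seed).
#' @return an object of class `mm_cohort`: a list with elements `preset`,
#'   `schedule`, `lineages` (one row per lineage: ids, fate, expression,
#'   division/lysis times, PI response, cell geometry) and `ph` (matrix of
#'   true pH, lineages x frames).
#' @export
make_cohort <- function(preset, n_lineages, seed = 1) {
  preset <- validate_preset(preset)
  if (n_lineages < 1) stop("n_lineages must be at least 1")
  withr::local_seed(as.integer(seed))

  schedule <- imaging_schedule()
  fates3 <- sample(c("persister", "vbnc", "susceptible"), n_lineages,
                   replace = TRUE, prob = preset$fate_probs)
  lysed <- fates3 == "susceptible" &
    stats::runif(n_lineages) < preset$susceptible_lysed_frac
  fate <- ifelse(fates3 == "susceptible",
                 ifelse(lysed, "susceptible_lysed", "susceptible_not_lysed"),
                 fates3)

  ## log-normal expression with given mean and CV
  sdlog <- sqrt(log(1 + preset$expression_cv^2))
  meanlog <- log(preset$expression_mean) - sdlog^2 / 2
  expression <- stats::rlnorm(n_lineages, meanlog, sdlog)

  div_frames <- schedule[schedule > preset$division_window[1] &
                           schedule <= preset$division_window[2]]
  lys_frames <- schedule[schedule >= preset$lysis_window[1] &
                           schedule <= preset$lysis_window[2]]
  division_time <- rep(NA_real_, n_lineages)
  is_pers <- fate == "persister"
  division_time[is_pers] <- sample(div_frames, sum(is_pers), replace = TRUE)
  lysis_time <- rep(NA_real_, n_lineages)
  is_lys <- fate == "susceptible_lysed"
  lysis_time[is_lys] <- sample(lys_frames, sum(is_lys), replace = TRUE)

  pi_fold <- unname(preset$pi_fold[ifelse(fates3 == "susceptible",
                                          "susceptible_not_lysed", fates3)])
  pi_fold[is_lys] <- NA_real_
  expr24 <- unname(preset$expression_24h_factor[
    ifelse(fates3 == "susceptible", "susceptible_not_lysed", fates3)])
  expr24[is_lys] <- NA_real_

  ## true pH: t=0 from the fate's mixture, later frames anchored + noise
  ph <- matrix(NA_real_, n_lineages, length(schedule),
               dimnames = list(NULL, paste0("t", schedule)))
  for (f3 in c("persister", "vbnc", "susceptible")) {
    idx <- which(fates3 == f3)
    if (!length(idx)) next
    mix <- preset$t0_ph[[f3]]
    comp <- sample.int(length(mix$weights), length(idx), replace = TRUE,
                       prob = mix$weights)
    ph[idx, 1] <- stats::rnorm(length(idx), mix$means[comp], mix$sds[comp])
    mean_traj <- stats::approx(preset$anchors[[f3]]$time_h,
                               preset$anchors[[f3]]$ph,
                               xout = schedule[-1], rule = 2)$y
    later <- matrix(rep(mean_traj, each = length(idx)), nrow = length(idx))
    ph[idx, -1] <- later + stats::rnorm(length(later), 0, preset$traj_sd)
  }
  ## pH undefined after lysis
  for (i in which(is_lys)) ph[i, schedule >= lysis_time[i]] <- NA_real_

  lineages <- data.frame(
    lineage_id = seq_len(n_lineages),
    trench_id = seq_len(n_lineages),
    fate = fate,
    expression = expression,
    division_time = division_time,
    lysis_time = lysis_time,
    pi_fold = pi_fold,
    expression_24h_factor = expr24,
    pi_positive = fate == "susceptible_not_lysed",
    cell_length_um = pmin(pmax(stats::rnorm(n_lineages, 3, 0.3), 2), 4),
    cell_width_um = 1)

  structure(list(preset = preset, schedule = schedule,
                 lineages = lineages, ph = ph),
            class = "mm_cohort")
}

#' True cell layout of a cohort at one frame
#'
#' Expands lineage records into the individual cells present in each trench
#' at a given frame: the mother sits at the closed end and, after a division,
#' the daughter abuts below it (separated by a thin septum gap), pushed
#' toward the open end.
#'
#' @param cohort an `mm_cohort`.
#' @param frame_h frame time (h), one of the cohort schedule.
#' @param offset_um distance of the mother's closed-end pole from the trench
#'   top (um).
#' @param septum_um gap between stacked cells (um).
#' @return data.frame with one row per cell: `lineage_id`, `trench_id`,
#'   `cell_index`, `top_um`, `length_um`, `width_um`, `true_ph`,
#'   `tritc_factor` (expression modifier at this frame).
#' @export
cohort_cells <- function(cohort, frame_h, offset_um = 1, septum_um = 0.2) {
  stopifnot(frame_h %in% cohort$schedule)
  li <- cohort$lineages
  col <- match(frame_h, cohort$schedule)
  present <- is.na(li$lysis_time) | frame_h < li$lysis_time
  divided <- !is.na(li$division_time) & frame_h >= li$division_time
  n_cells <- ifelse(present, 1L + divided, 0L)

  idx <- rep(which(present), times = n_cells[present])
  cell_index <- sequence(n_cells[present])
  top <- offset_um + (cell_index - 1) * (li$cell_length_um[idx] + septum_um)
  tritc_factor <- rep(1, length(idx))
  if (frame_h == 24) {
    f <- li$expression_24h_factor[idx]
    tritc_factor <- ifelse(is.na(f), 1, f)
  }
  data.frame(lineage_id = li$lineage_id[idx],
             trench_id = li$trench_id[idx],
             cell_index = cell_index,
             top_um = top,
             length_um = li$cell_length_um[idx],
             width_um = li$cell_width_um[idx],
             true_ph = cohort$ph[idx, col],
             expression = li$expression[idx],
             tritc_factor = tritc_factor)
}

#' Long-format ground truth table
#'
#' @param cohort an `mm_cohort`.
#' @return data.frame with columns `lineage_id`, `trench_id`, `frame_h`,
#'   `fate`, `true_ph` (NA after lysis).
#' @export
cohort_truth <- function(cohort) {
  li <- cohort$lineages
  n <- nrow(li)
  k <- length(cohort$schedule)
  data.frame(lineage_id = rep(li$lineage_id, each = k),
             trench_id = rep(li$trench_id, each = k),
             frame_h = rep(cohort$schedule, n),
             fate = rep(li$fate, each = k),
             true_ph = as.vector(t(cohort$ph)))
}

#' @export
print.mm_cohort <- function(x, ...) {
  tab <- table(factor(x$lineages$fate,
                      levels = c("persister", "vbnc", "susceptible_lysed",
                                 "susceptible_not_lysed")))
  cat(sprintf("<mm_cohort> %d lineages from preset '%s'\n",
              nrow(x$lineages), x$preset$name))
  cat(sprintf("  fates: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  schedule (h): %s\n", paste(x$schedule, collapse = ", ")))
  invisible(x)
}
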