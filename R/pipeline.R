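#' Analyze an image-mode stack end to end
#'
#' Runs the full measurement chain on rendered frames: trench detection (on
#' the time-zero TRITC frame; trenches are static), per-trench Otsu
#' segmentation on TRITC, background-subtracted two-channel photometry,
#' overlap-based lineage tracking, PI-response measurement on the post-PI
#' frame, ratio-to-pH conversion through the supplied calibration, and
#' end-point phenotype classification of every time-zero lineage.  Ground
#' truth is never consulted.
#'
#' @param stack an [render_stack()] image stack (with the PI frame appended
#'   via [apply_pi_event()] if phenotyping is to use PI evidence).
#' @param calibration a [fit_calibration()] model.
#' @param pi_threshold,low_expr_percentile,min_area_um2,low_floor,min_contrast
#'   analysis thresholds (see the respective module functions).
#' @return list of class `mm_analysis`: `photometry` (per lineage and frame:
#'   intensities, backgrounds, ratio, pH, validity, QC, mask geometry) and
#'   `calls` (a [classify_cohort()] table; `lineage_id` is the global trench
#'   id).
#' @export
analyze_stack <- function(stack, calibration, pi_threshold = 2,
                          low_expr_percentile = 0.10, min_area_um2 = 0.5,
                          low_floor = 10, min_contrast = 50) {
  optics <- stack$optics
  ppm <- optics$pixels_per_micron
  sched <- stack$schedule
  phot_rows <- list()
  feat_rows <- list()
  have_pi <- !is.null(stack$fields[[1]]$post_pi)

  for (field in stack$fields) {
    tm <- detect_trenches(field$frames[[1]]$tritc)
    for (k in tm$trench_id) {
      gid <- field$trench_offset + k
      crops <- lapply(field$frames, function(fr)
        list(fitc = crop_trench(fr$fitc, tm, k),
             tritc = crop_trench(fr$tritc, tm, k)))
      masks_by_frame <- lapply(crops, function(cr)
        segment_cells(cr$tritc, ppm, min_area_um2 = min_area_um2,
                      min_contrast = min_contrast,
                      bit_depth = optics$bit_depth))
      lin <- build_lineages(masks_by_frame, sched, ppm)
      if (!nrow(lin$tracks)) next

      ## photometry for every tracked mask
      meas <- list() # "<frame>:<label>" -> measurement row
      for (i in seq_along(sched)) {
        masks <- masks_by_frame[[i]]
        if (!length(masks)) next
        bg <- estimate_background(crops[[i]]$fitc, crops[[i]]$tritc, masks)
        for (m in masks)
          meas[[paste(sched[i], m$label, sep = ":")]] <-
            cbind(measure_cell(m, crops[[i]]$fitc, crops[[i]]$tritc, bg,
                               low_floor),
                  length_um = m$length_um, width_um = m$width_um,
                  area_um2 = m$area_um2)
      }
      post_meas <- list()
      if (have_pi) {
        post <- crop_trench(field$post_pi, tm, k)
        masks24 <- masks_by_frame[[length(sched)]]
        if (length(masks24)) {
          bgp <- estimate_background(post, post, masks24)
          for (m in masks24)
            post_meas[[as.character(m$label)]] <-
              mean(post[m$pixels]) - bgp[[2]]
        }
      }

      founders <- lin$tracks$track_id[lin$tracks$founder]
      for (tr in founders) {
        sub <- lineage_subtree(lin, tr)
        fr_sub <- lin$frames[lin$frames$track_id %in% sub &
                               lin$frames$present, , drop = FALSE]
        ## per-frame photometry follows the founder's own track
        fr_own <- lin$frames[lin$frames$track_id == tr &
                               lin$frames$present, , drop = FALSE]
        for (r in seq_len(nrow(fr_own))) {
          key <- paste(fr_own$frame_h[r], fr_own$label[r], sep = ":")
          mrow <- meas[[key]]
          if (is.null(mrow)) next
          phot_rows[[length(phot_rows) + 1]] <-
            cbind(data.frame(lineage_id = gid, trench_id = gid,
                             frame_h = fr_own$frame_h[r]), mrow)
        }
        at24 <- fr_sub[fr_sub$frame_h == sched[length(sched)], , drop = FALSE]
        own24 <- fr_own[fr_own$frame_h == sched[length(sched)], , drop = FALSE]
        lab24 <- if (nrow(own24)) own24$label[1] else
          if (nrow(at24)) at24$label[1] else NA
        t24 <- if (!is.na(lab24))
          meas[[paste(sched[length(sched)], lab24, sep = ":")]]$I_tritc else
            NA_real_
        p24 <- if (!is.na(lab24) && have_pi)
          post_meas[[as.character(lab24)]] else NA_real_
        n3 <- sum(fr_sub$frame_h == 3)
        divided <- any(lin$events$kind == "division" &
                         lin$events$track_id %in% sub &
                         lin$events$time_h > 3) ||
          (nrow(at24) > max(n3, 1))
        feat_rows[[length(feat_rows) + 1]] <- data.frame(
          lineage_id = gid,
          present_at_24h = nrow(at24) > 0,
          divided_after_3h = divided,
          tritc_24h = if (is.null(t24)) NA_real_ else t24,
          tritc_post_pi = if (is.null(p24)) NA_real_ else p24)
      }
    }
  }

  photometry <- do.call(rbind, phot_rows)
  features <- do.call(rbind, feat_rows)
  est <- ratio_to_ph(calibration, photometry$ratio)
  photometry$ph <- est$ph
  photometry$valid <- est$valid
  t0_pop <- photometry$I_tritc[photometry$frame_h == 0]
  calls <- classify_cohort(features, t0_pop, pi_threshold = pi_threshold,
                           low_expr_percentile = low_expr_percentile,
                           low_floor = low_floor, have_pi = have_pi)
  structure(list(photometry = photometry, calls = calls, mode = "image"),
            class = "mm_analysis")
}

#' Analyze trace-mode output end to end
#'
#' The trace table already carries per-lineage background-free intensities,
#' so photometry reduces to forming the FITC/TRITC ratio; tracking reduces to
#' reading presence and cell counts per frame.  Classification and pH
#' estimation are identical to image mode.
#'
#' @param traces an `mm_traces` table (with `tritc_post_pi` from
#'   [apply_pi_event()] if PI evidence is available).
#' @param calibration a [fit_calibration()] model.
#' @param pi_threshold,low_expr_percentile,low_floor analysis thresholds.
#' @return an `mm_analysis` list, as [analyze_stack()].
#' @export
analyze_traces <- function(traces, calibration, pi_threshold = 2,
                           low_expr_percentile = 0.10, low_floor = 10) {
  have_pi <- "tritc_post_pi" %in% names(traces)
  ratio <- ifelse(!is.na(traces$tritc) & traces$tritc > 0,
                  traces$fitc / traces$tritc, NA_real_)
  est <- ratio_to_ph(calibration, ratio)
  photometry <- data.frame(
    lineage_id = traces$lineage_id, trench_id = traces$trench_id,
    frame_h = traces$frame_h, I_fitc = traces$fitc, I_tritc = traces$tritc,
    ratio = ratio, ph = est$ph, valid = est$valid,
    qc = ifelse(is.na(traces$tritc), "absent",
                ifelse(traces$tritc <= 0, "no_tritc",
                       ifelse(traces$tritc < low_floor, "low_signal", "ok"))))

  ## per-lineage evidence, vectorized over the complete lineage x frame grid
  ord <- order(traces$lineage_id, traces$frame_h)
  tr <- traces[ord, , drop = FALSE]
  ids <- unique(tr$lineage_id)
  times <- unique(tr$frame_h)
  stopifnot(nrow(tr) == length(ids) * length(times))
  ncell <- matrix(tr$n_cells, length(times), length(ids))
  tritc24 <- tr$tritc[tr$frame_h == 24]
  post24 <- if (have_pi) tr$tritc_post_pi[tr$frame_h == 24] else
    rep(NA_real_, length(ids))
  n3 <- pmax(ncell[times == 3, ], 1)
  grew <- apply(ncell[times > 3, , drop = FALSE], 2, max) > n3
  features <- data.frame(
    lineage_id = ids,
    present_at_24h = !is.na(tritc24),
    divided_after_3h = grew,
    tritc_24h = tritc24,
    tritc_post_pi = post24)
  t0_pop <- traces$tritc[traces$frame_h == 0]
  calls <- classify_cohort(features, t0_pop, pi_threshold = pi_threshold,
                           low_expr_percentile = low_expr_percentile,
                           low_floor = low_floor, have_pi = have_pi)
  structure(list(photometry = photometry, calls = calls, mode = "trace"),
            class = "mm_analysis")
}

#' Resolve a run configuration
#'
#' Fills defaults, validates thresholds and the preset, and derives the
#' per-stage seeds (cohort, render, calibration) from the single `seed` when
#' they are not given explicitly.  The resolved configuration is echoed into
#' the run log so every stochastic stage is reproducible.
#'
#' @param preset preset name (see [strain_preset_default()]), a YAML preset
#'   file path, or a `strain_preset`.
#' @param n_lineages cohort size.
#' @param mode `"trace"` or `"image"`.
#' @param seed master seed; stage seeds default to `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param seeds optional named list/vector (`cohort`, `render`,
#'   `calibration`) overriding the derived stage seeds.
#' @param optics an [optics_config()] or a list of overrides to the default.
#' @param standards calibration standards (pH).
#' @param calibration_n_cells cells per rendered standard.
#' @param pi_threshold,low_expr_percentile,min_area_um2,low_floor analysis
#'   thresholds.
#' @param outdir output directory (created); `NULL` writes nothing.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "parental", n_lineages = 500,
                       mode = c("trace", "image"), seed = 1, seeds = NULL,
                       optics = list(), standards = c(6.5, 7.0, 7.5, 8.0),
                       calibration_n_cells = 36, pi_threshold = 2,
                       low_expr_percentile = 0.10, min_area_um2 = 0.5,
                       low_floor = 10, outdir = NULL) {
  mode <- match.arg(mode)
  if (is.character(preset)) {
    preset <- if (file.exists(preset)) read_preset(preset) else
      strain_preset_default(preset)
  }
  preset <- validate_preset(preset)
  if (!inherits(optics, "optics_config"))
    optics <- do.call(optics_config, optics)
  if (n_lineages < 1) stop("n_lineages: must be at least 1")
  if (pi_threshold < 1) stop("pi_threshold: must be at least 1")
  if (low_expr_percentile <= 0 || low_expr_percentile > 0.5)
    stop("low_expr_percentile: must be in (0, 0.5]")
  if (min_area_um2 <= 0) stop("min_area_um2: must be positive")
  if (low_floor < 0) stop("low_floor: must be non-negative")
  s <- list(cohort = seed, render = seed + 1, calibration = seed + 2)
  for (nm in names(seeds)) s[[nm]] <- seeds[[nm]]
  structure(list(preset = preset, n_lineages = as.integer(n_lineages),
                 mode = mode, seeds = s, optics = optics,
                 standards = standards,
                 calibration_n_cells = calibration_n_cells,
                 pi_threshold = pi_threshold,
                 low_expr_percentile = low_expr_percentile,
                 min_area_um2 = min_area_um2, low_floor = low_floor,
                 outdir = outdir),
            class = "run_config")
}

.config_lines <- function(cfg) {
  c(sprintf("preset: %s", cfg$preset$name),
    sprintf("n_lineages: %d", cfg$n_lineages),
    sprintf("mode: %s", cfg$mode),
    sprintf("seeds: cohort %d, render %d, calibration %d",
            cfg$seeds$cohort, cfg$seeds$render, cfg$seeds$calibration),
    sprintf("standards: %s", paste(cfg$standards, collapse = ", ")),
    sprintf("thresholds: pi_fold %.3g, low_expr_percentile %.3g, min_area_um2 %.3g, low_floor %.3g",
            cfg$pi_threshold, cfg$low_expr_percentile, cfg$min_area_um2,
            cfg$low_floor),
    sprintf("optics: %s", paste(sprintf("%s=%s", names(unclass(cfg$optics)),
                                        vapply(unclass(cfg$optics), format,
                                               character(1))),
                                collapse = " ")))
}

#' Run a full synthetic experiment
#'
#' Orchestrates generate, render, calibrate, analyze and summarize for one
#' configuration: draws the cohort, renders it (image or trace mode) plus the
#' end-point PI event, fits a calibration from standards rendered with the
#' same optics and mode, runs the measurement chain, classifies every
#' time-zero lineage, and aggregates phenotype fractions and per-time pH
#' summaries.  With `outdir` set, writes `ground_truth.csv`,
#' `photometry.csv`, `calls.csv`, `summary.csv`, `calibration.yaml` and
#' `run_log.txt`.
#'
#' @param config a [run_config()] (or a list of arguments for it, or a YAML
#'   file path).
#' @param quiet suppress progress messages.
#' @return list of class `mm_run`: `config`, `cohort`, `calibration`,
#'   `analysis`, `fractions`, `summaries`.
#' @export
run_experiment <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  log_lines <- c("mmpH run", .config_lines(config))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage generate: %d lineages from preset '%s'", config$n_lineages,
      config$preset$name)
  cohort <- stage("generate",
                  make_cohort(config$preset, config$n_lineages,
                              seed = config$seeds$cohort))
  say("stage render: %s mode", config$mode)
  rendered <- stage("render", {
    r <- render_stack(cohort, config$optics, mode = config$mode,
                      seed = config$seeds$render)
    apply_pi_event(r, cohort, seed = config$seeds$render + 1)
  })
  say("stage calibrate: %d standards", length(config$standards))
  calibration <- stage("calibrate", {
    calset <- render_calibration_set(config$standards, config$optics,
                                     seed = config$seeds$calibration,
                                     mode = config$mode,
                                     n_cells = config$calibration_n_cells)
    fit_calibration(calibration_points(
      calset, min_area_um2 = config$min_area_um2,
      low_floor = config$low_floor))
  })
  say("stage analyze")
  analysis <- stage("analyze", {
    if (config$mode == "image")
      analyze_stack(rendered, calibration,
                    pi_threshold = config$pi_threshold,
                    low_expr_percentile = config$low_expr_percentile,
                    min_area_um2 = config$min_area_um2,
                    low_floor = config$low_floor)
    else
      analyze_traces(rendered, calibration,
                     pi_threshold = config$pi_threshold,
                     low_expr_percentile = config$low_expr_percentile,
                     low_floor = config$low_floor)
  })
  say("stage summarize")
  bundle <- stage("summarize", {
    fractions <- phenotype_fractions(analysis$calls)
    summaries <- do.call(rbind, lapply(c(0, 3, 24), function(t)
      ph_distribution(analysis$photometry, analysis$calls, t)))
    list(fractions = fractions, summaries = summaries)
  })

  run <- structure(list(config = config, cohort = cohort,
                        calibration = calibration, analysis = analysis,
                        fractions = bundle$fractions,
                        summaries = bundle$summaries),
                   class = "mm_run")
  if (!is.null(config$outdir)) {
    stage("write", {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      truth <- cohort_truth(cohort)
      if (config$mode == "trace") {
        tr <- rendered
        i <- match(paste(truth$lineage_id, truth$frame_h),
                   paste(tr$lineage_id, tr$frame_h))
        truth$fitc <- tr$fitc[i]
        truth$tritc <- tr$tritc[i]
      }
      wr <- function(x, f) utils::write.csv(
        x, file.path(config$outdir, f), row.names = FALSE)
      wr(truth, "ground_truth.csv")
      wr(analysis$photometry, "photometry.csv")
      wr(as.data.frame(analysis$calls), "calls.csv")
      wr(as.data.frame(run$summaries), "summary.csv")
      write_calibration(calibration, file.path(config$outdir,
                                               "calibration.yaml"))
      writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
    })
    say("outputs written to %s", config$outdir)
  }
  run
}

#' Fit and persist a calibration model for a configuration
#'
#' Renders the configured standards with the configured optics and mode,
#' fits the linear calibration, logs diagnostics, and (with `outdir` set)
#' serializes the model to `calibration.yaml`.
#'
#' @param config a [run_config()] (or arguments for one, or a YAML path).
#' @param quiet suppress diagnostics.
#' @return a `calibration_model`.
#' @export
run_calibration <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  calset <- render_calibration_set(config$standards, config$optics,
                                   seed = config$seeds$calibration,
                                   mode = config$mode,
                                   n_cells = config$calibration_n_cells)
  model <- fit_calibration(calibration_points(
    calset, min_area_um2 = config$min_area_um2,
    low_floor = config$low_floor))
  if (!quiet) print(model)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_calibration(model, file.path(config$outdir, "calibration.yaml"))
  }
  model
}

#' @export
print.mm_run <- function(x, ...) {
  cat(sprintf("<mm_run> preset '%s', %d lineages, %s mode\n",
              x$config$preset$name, x$config$n_lineages, x$config$mode))
  print(x$fractions)
  invisible(x)
}
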