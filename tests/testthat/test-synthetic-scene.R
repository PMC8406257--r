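test_that("cohort generation is deterministic and honours degenerate fate probabilities", {
  p <- strain_preset_default("parental")
  a <- make_cohort(p, 10, seed = 7)
  b <- make_cohort(p, 10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_cohort(p, 10, seed = 8)))

  pp <- preset_single_fate(p, "persister")
  co <- make_cohort(pp, 50, seed = 1)
  expect_true(all(co$lineages$fate == "persister"))
  expect_true(all(co$lineages$division_time > 3 &
                    co$lineages$division_time <= 24))
})

test_that("cohort ground truth satisfies the phenotype-definition invariants", {
  co <- make_cohort(strain_preset_default("parental"), 3000, seed = 11)
  li <- co$lineages
  vb <- li[li$fate == "vbnc", ]
  expect_true(all(is.na(vb$division_time)))
  expect_false(any(vb$pi_positive))
  lys <- li[li$fate == "susceptible_lysed", ]
  expect_true(all(!is.na(lys$lysis_time)))
  # pH defined at every scheduled frame before lysis, undefined after
  for (i in sample(which(li$fate == "susceptible_lysed"), 10)) {
    before <- co$schedule < li$lysis_time[i]
    expect_true(all(!is.na(co$ph[i, before])))
    expect_true(all(is.na(co$ph[i, !before])))
  }
  expect_true(all(!is.na(co$ph[li$fate != "susceptible_lysed", ])))
})

test_that("fate frequencies converge to the preset probabilities", {
  p <- strain_preset_default("parental")
  co <- make_cohort(p, 1e5, seed = 3)
  f3 <- sub("susceptible_.*", "susceptible", co$lineages$fate)
  counts <- table(factor(f3, levels = names(p$fate_probs)))
  gof <- stats::chisq.test(counts, p = p$fate_probs)
  expect_gt(gof$p.value, 0.01)
  # persister frequency within 3 binomial SDs of 0.01
  se <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(mean(f3 == "persister") - 0.01), 3 * se)
})

test_that("invalid presets fail validation naming the offending field", {
  p <- strain_preset_default("parental")
  bad <- p; bad$fate_probs <- c(persister = 0.01, vbnc = 0.04,
                                susceptible = 0.85)
  expect_error(validate_preset(bad), "fate_probs")
  bad <- p; bad$t0_ph$vbnc$weights <- c(0.5, 0.4)
  expect_error(validate_preset(bad), "weights")
  bad <- p; bad$anchors$persister$ph[1] <- 5.5
  expect_error(validate_preset(bad), "anchors\\[persister\\]")
})

test_that("noiseless rendering reproduces the ground-truth ratio to sub-percent accuracy", {
  co <- make_cohort(strain_preset_default("parental"), 12, seed = 2)
  opt <- optics_noiseless(optics_config())
  st <- render_stack(co, opt, "image", seed = 1)
  fr <- st$fields[[1]]$frames[["t0"]]
  tm <- detect_trenches(fr$tritc)
  expect_equal(nrow(tm), 12)
  for (k in tm$trench_id) {
    tritc <- crop_trench(fr$tritc, tm, k)
    fitc <- crop_trench(fr$fitc, tm, k)
    masks <- segment_cells(tritc, opt$pixels_per_micron)
    expect_length(masks, 1)
    bg <- estimate_background(fitc, tritc, masks)
    r <- measure_cell(masks[[1]], fitc, tritc, bg)$ratio
    r_true <- true_ratio_of_ph(opt, co$ph[k, 1])
    expect_lt(abs(r / r_true - 1), 0.005)
  }
})

test_that("doubling expression doubles both channels and leaves the ratio unchanged", {
  p <- preset_single_fate(strain_preset_default("parental"), "vbnc")
  co <- make_cohort(p, 2, seed = 5)
  co$ph[2, ] <- co$ph[1, ]             # same true pH
  co$lineages$expression <- c(1, 2)    # planted common-mode factor
  co$lineages$cell_length_um <- 3
  opt <- optics_noiseless(optics_config(n_trenches = 2))
  fr <- render_stack(co, opt, "image", seed = 1)$fields[[1]]$frames[["t0"]]
  tm <- detect_trenches(fr$tritc)
  meas <- lapply(1:2, function(k) {
    tritc <- crop_trench(fr$tritc, tm, k)
    fitc <- crop_trench(fr$fitc, tm, k)
    masks <- segment_cells(tritc, opt$pixels_per_micron)
    measure_cell(masks[[1]], fitc, tritc,
                 estimate_background(fitc, tritc, masks))
  })
  expect_equal(meas[[2]]$I_tritc, 2 * meas[[1]]$I_tritc, tolerance = 1e-10)
  expect_equal(meas[[2]]$I_fitc, 2 * meas[[1]]$I_fitc, tolerance = 1e-10)
  expect_equal(meas[[2]]$ratio, meas[[1]]$ratio, tolerance = 1e-12)
})

test_that("trace-mode and image-mode photometry of the same cohort agree within propagated noise", {
  co <- make_cohort(strain_preset_default("parental"), 24, seed = 9)
  opt <- optics_config()
  st <- render_stack(co, opt, "image", seed = 4)
  tr <- render_stack(co, opt, "trace")
  cal <- fit_from_standards(optics_noiseless(opt), seed = 8)
  an <- suppressWarnings(analyze_stack(st, cal)) # no PI frame: ratios only
  ph0 <- an$photometry[an$photometry$frame_h == 0, ]
  r_img <- ph0$ratio[order(ph0$lineage_id)]
  tr0 <- tr[tr$frame_h == 0, ]
  r_trc <- (tr0$fitc / tr0$tritc)[order(tr0$lineage_id)]
  # propagated SD of the measured ratio: shot + read noise on the mean over
  # the mask pixels, both channels, plus the background estimate
  n_px <- 18 * 6 # nominal 3 x 1 um cell at 6 px/um
  tritc <- tr0$tritc[order(tr0$lineage_id)]
  sd_ch <- function(sig) sqrt((sig + opt$bg_tritc + opt$read_noise_sd^2) / n_px)
  sd_r <- sqrt((sd_ch(r_trc * tritc) / tritc)^2 +
                 (r_trc * sd_ch(tritc) / tritc)^2)
  expect_true(all(abs(r_img - r_trc) < 5 * sd_r))
  expect_gte(mean(abs(r_img - r_trc) < 3 * sd_r), 0.9)
})

test_that("calibration stacks have increasing ratios and hit the line exactly without noise", {
  opt <- optics_config()
  cs <- render_calibration_set(c(6.5, 7.0, 7.5, 8.0), opt, seed = 3)
  expect_length(cs$sets, 4)
  pts <- calibration_points(cs)
  means <- tapply(pts$ratio, pts$ph, mean)
  expect_true(all(diff(means) > 0))

  cs0 <- render_calibration_set(c(6.5, 7.0, 7.5, 8.0),
                                optics_noiseless(opt), seed = 3)
  pts0 <- calibration_points(cs0)
  expect_equal(unname(pts0$ratio),
               true_ratio_of_ph(opt, pts0$ph), tolerance = 1e-9)

  # single standard: one stack whose within-stack ratio spread matches the
  # noise model prediction (shot + read over the mask pixels)
  cs1 <- render_calibration_set(7.0, opt, seed = 3, n_cells = 60)
  expect_length(cs1$sets, 1)
  pts1 <- calibration_points(cs1)
  tritc <- opt$tritc_scale # expression averages out at 1
  n_px <- 18 * 6
  sd_ch <- function(sig) sqrt((sig + opt$bg_tritc + opt$read_noise_sd^2) / n_px)
  r <- true_ratio_of_ph(opt, 7.0)
  pred <- sqrt((sd_ch(r * tritc) / tritc)^2 + (r * sd_ch(tritc) / tritc)^2)
  expect_lt(sd(pts1$ratio - mean(pts1$ratio)), 3 * pred)
  expect_error(render_calibration_set(numeric(0), opt), "empty")
})

test_that("the PI event boosts only membrane-compromised survivors", {
  p <- strain_preset_default("parental")
  co <- make_cohort(p, 400, seed = 13)
  tr <- apply_pi_event(render_stack(co, optics_config(), "trace"), co)
  at24 <- tr[tr$frame_h == 24, ]
  fate <- co$lineages$fate[match(at24$lineage_id, co$lineages$lineage_id)]
  fold <- at24$tritc_post_pi / at24$tritc
  expect_equal(unname(fold[fate == "vbnc"]),
               rep(1, sum(fate == "vbnc", na.rm = TRUE)))
  expect_equal(mean(fold[fate == "susceptible_not_lysed"], na.rm = TRUE), 3,
               tolerance = 1e-9)
  expect_true(all(is.na(at24$tritc_post_pi[fate == "susceptible_lysed"])))

  # image mode: lysed cells are absent from the post-PI frame
  co2 <- make_cohort(preset_single_fate(p, "susceptible"), 6, seed = 3)
  co2$lineages$lysis_time[] <- 2
  co2$lineages$fate[] <- "susceptible_lysed"
  opt <- optics_noiseless(optics_config(n_trenches = 6))
  st <- apply_pi_event(render_stack(co2, opt, "image", seed = 1), co2)
  tm <- detect_trenches(st$fields[[1]]$frames[["t0"]]$tritc)
  post <- crop_trench(st$fields[[1]]$post_pi, tm, 1)
  expect_length(segment_cells(post, opt$pixels_per_micron), 0)
  # and a stack without the 24 h frame refuses the event
  st2 <- render_stack(co2, opt, "image", seed = 1)
  st2$fields <- lapply(st2$fields, function(f) {
    f$frames <- f$frames[names(f$frames) != "t24"]; f })
  expect_error(apply_pi_event(st2, co2), "24 h")
})
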