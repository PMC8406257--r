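test_that("frame linking classifies continuation, division and disappearance", {
  dm <- c(120, 10)
  # same cell, slightly grown -> 1:1 continuation
  a <- rect_mask(dm, 10, 27, 3, 8)
  b <- rect_mask(dm, 10, 30, 3, 8)
  lf <- link_frames(list(a), list(b), 6)
  expect_equal(lf$assign$relation, "continuation")
  expect_equal(lf$events$event, "continuation")

  # parent tiled by two daughters -> division with two successors
  d1 <- rect_mask(dm, 10, 18, 3, 8, label = 1)
  d2 <- rect_mask(dm, 20, 28, 3, 8, label = 2)
  lf <- link_frames(list(a), list(d1, d2), 6)
  expect_setequal(lf$assign$relation, c("continuation", "daughter"))
  expect_equal(lf$events$event, "division")
  expect_equal(lf$events$n_children, 2)

  # no successor -> disappearance
  lf <- link_frames(list(a), list(), 6)
  expect_equal(lf$events$event, "disappearance")
  expect_silent(link_frames(list(), list(), 6))

  # an abutting non-overlapping daughter is matched through proximity,
  # a distant new mask near the open end is washed-in
  far <- rect_mask(dm, 100, 117, 3, 8, label = 3)
  near <- rect_mask(dm, 29, 46, 3, 8, label = 2)
  lf <- link_frames(list(a), list(b, near, far), 6)
  expect_equal(lf$assign$relation[lf$assign$label == 2], "daughter")
  expect_equal(lf$assign$relation[lf$assign$label == 3], "washed_in")
})

test_that("a constant single-cell movie yields one lineage ending with the movie", {
  dm <- c(120, 10)
  m <- rect_mask(dm, 10, 27, 3, 8)
  lin <- build_lineages(rep(list(list(m)), 25), 0:24, 6)
  expect_equal(nrow(lin$tracks), 1)
  expect_true(lin$tracks$founder)
  expect_equal(lin$events$kind, "end_of_movie")
  expect_equal(sum(lin$frames$present), 25)
})

test_that("division and lysis times are recovered exactly from rendered ground truth", {
  p <- strain_preset_default("parental")
  co <- make_cohort(preset_single_fate(p, "persister"), 2, seed = 3)
  co$lineages$division_time <- c(5, 24)
  opt <- optics_noiseless(optics_config(n_trenches = 2))
  st <- render_stack(co, opt, "image", seed = 1)
  tm <- detect_trenches(st$fields[[1]]$frames[["t0"]]$tritc)
  for (k in 1:2) {
    mbf <- lapply(st$fields[[1]]$frames, function(fr)
      segment_cells(crop_trench(fr$tritc, tm, k), opt$pixels_per_micron))
    lin <- build_lineages(mbf, st$schedule, opt$pixels_per_micron)
    div <- lin$events[lin$events$kind == "division", ]
    expect_equal(div$time_h, co$lineages$division_time[k])
    expect_equal(sum(lin$tracks$founder), 1)
    expect_equal(nrow(lin$tracks), 2) # mother + one daughter
  }

  co2 <- make_cohort(preset_single_fate(p, "susceptible"), 1, seed = 4)
  co2$lineages$fate <- "susceptible_lysed"
  co2$lineages$lysis_time <- 2
  st2 <- render_stack(co2, optics_noiseless(optics_config(n_trenches = 1)),
                      "image", seed = 1)
  tm2 <- detect_trenches(st2$fields[[1]]$frames[["t0"]]$tritc)
  mbf2 <- lapply(st2$fields[[1]]$frames, function(fr)
    segment_cells(crop_trench(fr$tritc, tm2, 1), 6))
  lin2 <- build_lineages(mbf2, st2$schedule, 6)
  expect_equal(lin2$events$kind[lin2$events$track_id == 1], "disappearance")
  expect_equal(lin2$events$time_h[lin2$events$track_id == 1], 2)
})

test_that("tracking bridges a single missing frame but confirms two-frame absences", {
  dm <- c(120, 10)
  m <- rect_mask(dm, 10, 27, 3, 8)
  sched <- 0:5
  frames <- rep(list(list(m)), 6)
  frames[[3]] <- list() # one missed detection
  lin <- build_lineages(frames, sched, 6)
  expect_equal(nrow(lin$tracks), 1)
  expect_equal(lin$events$kind, "end_of_movie")
  expect_true(any(lin$frames$bridged))

  frames[[4]] <- list() # two consecutive misses: a real disappearance
  lin2 <- build_lineages(frames, sched, 6)
  expect_true("disappearance" %in% lin2$events$kind)
  expect_equal(lin2$events$time_h[lin2$events$kind == "disappearance"], 2)
})

test_that("tracking is invariant to input label permutation and conserves masks", {
  dm <- c(120, 10)
  set.seed(42)
  mk <- function(top, lab) rect_mask(dm, top, top + 17, 3, 8, label = lab)
  frames_a <- list(list(mk(10, 1), mk(40, 2)),
                   list(mk(10, 1), mk(40, 2), mk(62, 3)),
                   list(mk(10, 1), mk(40, 2), mk(62, 3)))
  frames_b <- lapply(frames_a, function(ms) {
    perm <- sample(seq_along(ms))
    ms <- ms[perm]
    for (i in seq_along(ms)) ms[[i]]$label <- i
    ms
  })
  la <- build_lineages(frames_a, 0:2, 6)
  lb <- build_lineages(frames_b, 0:2, 6)
  expect_equal(la$tracks$founder, lb$tracks$founder)
  expect_equal(table(la$events$kind), table(lb$events$kind))
  expect_equal(nrow(la$tracks), nrow(lb$tracks))

  # conservation: masks in frame = living tracked masks + washed-in
  for (i in 1:3) {
    tracked <- sum(la$frames$frame_h == i - 1 & la$frames$present)
    expect_equal(length(frames_a[[i]]),
                 tracked + la$washed_in$n[la$washed_in$frame_h == i - 1])
  }
})
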