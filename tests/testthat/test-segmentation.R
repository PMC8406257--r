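test_that("trench detection recovers the rendered trench grid", {
  opt <- optics_config()
  co <- make_cohort(strain_preset_default("parental"), 12, seed = 6)
  fr <- render_stack(co, opt, "image", seed = 2)$fields[[1]]$frames[["t0"]]
  tm <- detect_trenches(fr$tritc)
  truth <- mmpH:::trench_rects(opt)
  expect_equal(nrow(tm), 12)
  expect_identical(attr(tm, "orientation"), "columns")
  expect_true(all(abs(tm$col0 - truth$col0) <= 1))
  expect_true(all(abs(tm$col1 - truth$col1) <= 1))
  expect_true(all(abs(tm$row0 - truth$row0) <= 1))
  expect_true(all(abs(tm$row1 - truth$row1) <= 1))
  # pitch between consecutive trenches
  pitch_px <- opt$trench_pitch_um * opt$pixels_per_micron
  expect_true(all(abs(diff(tm$col0) - pitch_px) <= 1))

  # transposed frame: same trenches under the transposed convention
  tmt <- detect_trenches(t(fr$tritc))
  expect_identical(attr(tmt, "orientation"), "rows")
  expect_equal(nrow(tmt), 12)
  expect_equal(tmt$row0, tm$col0)
  expect_equal(tmt$col0, tm$row0)
})

test_that("a structureless frame yields an empty trench map with a warning", {
  blank <- matrix(100, 80, 120)
  expect_warning(tm <- detect_trenches(blank), "no periodic")
  expect_equal(nrow(tm), 0)
})

test_that("cell segmentation recovers separated cells and rejects specks and empty trenches", {
  dm <- c(120, 10)
  cells <- list(list(r0 = 10, r1 = 27, c0 = 3, c1 = 8, value = 700),
                list(r0 = 40, r1 = 57, c0 = 3, c1 = 8, value = 900),
                list(r0 = 70, r1 = 87, c0 = 3, c1 = 8, value = 800))
  m <- trench_raster(dm, 100, cells)
  masks <- segment_cells(m, pixels_per_micron = 6)
  expect_length(masks, 3)
  # labels run from the closed end; centroids within 1 px of truth
  for (i in 1:3) {
    expect_equal(masks[[i]]$label, i)
    truth_row <- (cells[[i]]$r0 + cells[[i]]$r1) / 2
    expect_lt(abs(masks[[i]]$centroid_px[1] - truth_row), 1)
    expect_lt(abs(masks[[i]]$centroid_px[2] - 5.5), 1)
  }
  # empty trench (uniform or noisy) -> no masks
  expect_length(segment_cells(trench_raster(dm, 100), 6), 0)
  noisy <- matrix(rpois(prod(dm), 100), dm[1], dm[2])
  expect_length(segment_cells(noisy, 6), 0)
  # one real cell plus a single-pixel speck -> speck removed by size filter
  speck <- trench_raster(dm, 100, cells[1])
  speck[100, 5] <- 5000
  expect_length(segment_cells(speck, 6), 1)
  # saturated raster -> explicit error
  expect_error(segment_cells(matrix(65535, 40, 10), 6), "bit depth")
})

test_that("segmentation count is monotone non-increasing in the minimum-size filter", {
  dm <- c(120, 10)
  m <- trench_raster(dm, 100, list(
    list(r0 = 10, r1 = 27, c0 = 3, c1 = 8, value = 700),
    list(r0 = 40, r1 = 45, c0 = 4, c1 = 6, value = 700),
    list(r0 = 60, r1 = 62, c0 = 5, c1 = 6, value = 700)))
  sizes <- c(0.1, 0.3, 0.5, 1.0, 2.0, 4.0)
  counts <- vapply(sizes, function(s)
    length(segment_cells(m, 6, min_area_um2 = s)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 3)
})

test_that("detection is perfect on noiseless synthetic stacks and masks are disjoint", {
  co <- make_cohort(strain_preset_default("parental"), 24, seed = 21)
  opt <- optics_noiseless(optics_config())
  st <- render_stack(co, opt, "image", seed = 1)
  n_found <- 0
  for (field in st$fields) {
    fr <- field$frames[["t0"]]
    tm <- detect_trenches(fr$tritc)
    for (k in tm$trench_id) {
      masks <- segment_cells(crop_trench(fr$tritc, tm, k),
                             opt$pixels_per_micron)
      n_found <- n_found + length(masks)
      if (length(masks) > 1) {
        pix <- unlist(lapply(masks, `[[`, "pixels"))
        expect_equal(anyDuplicated(pix), 0)
      }
    }
  }
  # recall and precision both 1: every rendered cell found, nothing else
  expect_equal(n_found, nrow(cohort_cells(co, 0)))
})
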