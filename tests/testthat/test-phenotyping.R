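test_that("PI response folds and calls follow the threshold rule", {
  out <- pi_response(c(400, 400, 5), c(1200, 400, 50))
  expect_equal(out$fold, c(3, 1, NA_real_))
  expect_equal(out$pi_positive, c(TRUE, FALSE, NA))

  # VBNC false-positive rate at the measured noise scale stays below 5%:
  # simulate pre/post mean intensities of a fold-1 cell under the shot+read
  # model (signal 1000 counts over ~100 mask pixels)
  set.seed(99)
  n <- 5000
  se <- sqrt((1000 + 100 + 4) / 100)
  pre <- rnorm(n, 1000, se)
  post <- rnorm(n, 1000, se)
  fp <- mean(pi_response(pre, post)$pi_positive, na.rm = TRUE)
  expect_lt(fp, 0.05)
})

test_that("lineage classification follows the decision order", {
  expect_equal(classify_lineage(FALSE, FALSE, NA, NA), "susceptible_lysed")
  expect_equal(classify_lineage(TRUE, TRUE, FALSE, FALSE), "persister")
  # division trumps a PI-positive reading
  expect_equal(classify_lineage(TRUE, TRUE, TRUE, TRUE), "persister")
  expect_equal(classify_lineage(TRUE, FALSE, TRUE, FALSE),
               "susceptible_not_lysed")
  expect_equal(classify_lineage(TRUE, FALSE, FALSE, TRUE),
               "susceptible_not_lysed")
  # undefined PI fold counts as dead-low-signal evidence
  expect_equal(classify_lineage(TRUE, FALSE, NA, FALSE),
               "susceptible_not_lysed")
  expect_equal(classify_lineage(TRUE, FALSE, FALSE, FALSE), "vbnc")
  expect_equal(classify_lineage(TRUE, FALSE, NA, NA, have_pi = FALSE),
               "indeterminate")
})

test_that("without a PI frame surviving non-dividers are indeterminate, with a warning", {
  co <- make_cohort(strain_preset_default("parental"), 300, seed = 31)
  tr <- render_stack(co, optics_config(), "trace") # PI event NOT applied
  cal <- fit_from_standards(optics_config(), mode = "trace")
  expect_warning(an <- analyze_traces(tr, cal), "indeterminate")
  lab <- an$calls$label
  truth <- co$lineages$fate
  expect_true(all(lab[truth %in% c("vbnc", "susceptible_not_lysed")] ==
                    "indeterminate"))
  expect_true(all(lab[truth == "susceptible_lysed"] == "susceptible_lysed"))
})

test_that("calls partition all time-zero lineages and are order-invariant", {
  run <- trace_run("parental", 400, seed = 12)
  calls <- run$analysis$calls
  expect_setequal(calls$lineage_id, run$cohort$lineages$lineage_id)
  expect_equal(anyDuplicated(calls$lineage_id), 0)
  expect_true(all(calls$label %in% c("persister", "vbnc", "susceptible_lysed",
                                     "susceptible_not_lysed")))
  # confusion matrix against truth is the identity in trace mode
  cm <- evaluate_calls(calls, run$cohort)
  expect_equal(sum(diag(cm[, 1:4])), nrow(calls))
})

test_that("the noiseless image-mode confusion matrix is the identity", {
  p <- strain_preset_default("parental")
  p$fate_probs <- c(persister = 0.2, vbnc = 0.3, susceptible = 0.5)
  co <- make_cohort(p, 36, seed = 14)
  opt <- optics_noiseless(optics_config())
  st <- apply_pi_event(render_stack(co, opt, "image", seed = 1), co, seed = 2)
  cal <- fit_from_standards(opt, seed = 3)
  an <- analyze_stack(st, cal)
  cm <- evaluate_calls(an$calls, co)
  expect_equal(sum(diag(cm[, 1:4])), 36)
  expect_equal(sum(cm) - sum(diag(cm[, 1:4])), 0)
})
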