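test_that("phenotype fractions and binomial errors match hand arithmetic", {
  calls <- c(rep("persister", 1), rep("vbnc", 4),
             rep("susceptible_lysed", 50), rep("susceptible_not_lysed", 45))
  f <- phenotype_fractions(calls)
  expect_equal(f$fraction, c(0.01, 0.04, 0.95))
  expect_equal(f$se, sqrt(f$fraction * (1 - f$fraction) / 100))
  expect_equal(sum(f$fraction), 1)

  f2 <- phenotype_fractions(rep("persister", 7))
  expect_equal(f2$fraction, c(1, 0, 0))

  f3 <- phenotype_fractions(c(rep("persister", 3), rep("vbnc", 9),
                              rep("susceptible_lysed", 288)))
  expect_equal(f3$fraction, c(0.01, 0.03, 0.96))
  expect_error(phenotype_fractions(character(0)), "no determinate")
})

test_that("pH distribution summaries match hand arithmetic and flag edge cases", {
  ph_table <- data.frame(lineage_id = 1:4, frame_h = 0,
                         ph = c(7.0, 7.0, 7.2, 9.0),
                         valid = c(TRUE, TRUE, TRUE, FALSE))
  calls <- data.frame(lineage_id = 1:4, label = "vbnc")
  s <- ph_distribution(ph_table, calls, 0)
  expect_equal(s$n, 3)
  expect_equal(s$mean_ph, 7.0667, tolerance = 1e-4)
  expect_equal(s$sem, 0.0667, tolerance = 1e-3)
  expect_equal(s$n_invalid, 1)

  s1 <- ph_distribution(ph_table[1, ], calls, 0)
  expect_equal(s1$sem, 0)
  expect_true(s1$single_cell)

  expect_warning(
    ph_distribution(data.frame(lineage_id = 1, frame_h = 0, ph = 9,
                               valid = FALSE), calls, 0),
    "no valid")
})

test_that("mode detection recovers planted modes and respects the prominence floor", {
  set.seed(5)
  x <- c(rnorm(1000, 7.0, 0.1), rnorm(1000, 7.6, 0.1))
  m <- detect_modes(x)
  expect_length(m, 2)
  expect_lt(abs(m[1] - 7.0), 0.05)
  expect_lt(abs(m[2] - 7.6), 0.05)

  expect_length(detect_modes(rnorm(500, 7.0, 0.1)), 1)
  # a 95:5 mixture: the minor component falls below the prominence floor
  y <- c(rnorm(1900, 7.0, 0.1), rnorm(100, 7.6, 0.1))
  expect_length(detect_modes(y), 1)
  expect_error(detect_modes(rnorm(10)), "at least 20")
})

test_that("bimodality is recovered in at least 95% of seeded replicates", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(1000, 7.0, 0.1), rnorm(1000, 7.6, 0.1))
    m <- detect_modes(x)
    length(m) == 2 && all(abs(m - c(7.0, 7.6)) < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the Welch test matches the closed form and an independent oracle", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, -sqrt(3 / 2), tolerance = 1e-10) # -1.2247
  expect_equal(w$df, 4, tolerance = 1e-10)

  same <- c(1.2, 3.4, 2.2, 5.0)
  w0 <- welch_test(same, same)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  set.seed(77)
  for (i in 1:30) {
    a <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, .1, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, .1, 3))
    o <- stats::t.test(a, b) # oracle: Welch is R's default
    w <- welch_test(a, b)
    expect_equal(w$statistic, unname(o$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(o$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, o$p.value, tolerance = 1e-10)
  }
  expect_error(welch_test(c(1, 1, 1), c(2, 2)), "degenerate")
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})
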