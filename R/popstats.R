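#' Phenotype fractions with binomial standard errors
#'
#' Aggregates end-point calls into the population fractions of persister,
#' VBNC and susceptible cells (susceptible = lysed + non-lysed).
#' Indeterminate calls are excluded from the denominator.
#'
#' @param calls a [classify_cohort()] table or a character vector of labels.
#' @return object of class `phenotype_fractions`: data.frame with one row per
#'   phenotype (`fraction`, `se`, `n`) plus attribute `n_total`.
#' @export
phenotype_fractions <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else calls
  labels <- labels[labels != "indeterminate"]
  if (!length(labels)) stop("no determinate phenotype calls to aggregate")
  labels <- sub("susceptible_.*", "susceptible", labels)
  n <- length(labels)
  lv <- c("persister", "vbnc", "susceptible")
  counts <- table(factor(labels, levels = lv))
  p <- as.numeric(counts) / n
  out <- data.frame(phenotype = lv, fraction = p,
                    se = sqrt(p * (1 - p) / n),
                    n = as.integer(counts))
  attr(out, "n_total") <- n
  class(out) <- c("phenotype_fractions", "data.frame")
  out
}

#' Summarize the pH distribution per phenotype at one time point
#'
#' Restricts the pH table to one frame, keeps only calibration-valid values,
#' and reports per phenotype the mean, standard error of the mean, a fixed-
#' bin histogram (0.1 pH bins over [6.4, 8.1] by default), and KDE-detected
#' mode locations (when at least 20 cells are available).
#'
#' @param ph_table data.frame with columns `lineage_id`, `frame_h`, `ph`,
#'   `valid` (as produced by the analysis functions).
#' @param calls a [classify_cohort()] table (susceptible sub-fates are
#'   pooled).
#' @param time_h frame to summarize.
#' @param breaks histogram bin edges (pH units).
#' @return data.frame of class `ph_distribution_summary` with one row per
#'   phenotype (`phenotype`, `time_h`, `n`, `mean_ph`, `sem`, `n_invalid`,
#'   `single_cell` flag) and attributes `histograms` and `modes` (named
#'   lists).
#' @export
ph_distribution <- function(ph_table, calls, time_h,
                            breaks = seq(6.4, 8.1, by = 0.1)) {
  at <- ph_table[ph_table$frame_h == time_h & !is.na(ph_table$ph), ,
                 drop = FALSE]
  lab <- sub("susceptible_.*", "susceptible",
             calls$label[match(at$lineage_id, calls$lineage_id)])
  keep <- !is.na(lab) & lab != "indeterminate"
  at <- at[keep, , drop = FALSE]
  lab <- lab[keep]
  if (!any(at$valid)) {
    warning(sprintf("no valid pH values at t = %s h", time_h))
    return(structure(data.frame(phenotype = character(), time_h = numeric(),
                                n = integer(), mean_ph = numeric(),
                                sem = numeric(), n_invalid = integer(),
                                single_cell = logical()),
                     class = c("ph_distribution_summary", "data.frame"),
                     histograms = list(), modes = list()))
  }
  phenos <- intersect(c("persister", "vbnc", "susceptible"), unique(lab))
  hists <- list()
  modes <- list()
  rows <- lapply(phenos, function(p) {
    vals_all <- at$ph[lab == p]
    vals <- at$ph[lab == p & at$valid]
    n <- length(vals)
    hb <- range(breaks)
    hists[[p]] <<- graphics::hist(pmin(pmax(vals, hb[1]), hb[2]),
                                  breaks = breaks, plot = FALSE)
    modes[[p]] <<- if (n >= 20) detect_modes(vals) else NA_real_
    data.frame(phenotype = p, time_h = time_h, n = n,
               mean_ph = if (n) mean(vals) else NA_real_,
               sem = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
               n_invalid = length(vals_all) - n,
               single_cell = n == 1)
  })
  structure(do.call(rbind, rows),
            class = c("ph_distribution_summary", "data.frame"),
            histograms = hists, modes = modes)
}

#' Detect modes of a pH sample by kernel density estimation
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth; local maxima whose
#' density reaches at least `prominence` of the global maximum are reported
#' in ascending pH order.  Minor mixture components below the prominence
#' floor are not reported.
#'
#' @param x numeric sample (pH values), at least `n_min` observations.
#' @param prominence density floor as a fraction of the KDE maximum.
#' @param n_min minimum sample size.
#' @param bw bandwidth selector passed to [stats::density()].
#' @return numeric vector of mode locations (pH units), ascending.
#' @export
detect_modes <- function(x, prominence = 0.10, n_min = 20, bw = "nrd0") {
  if (length(x) < n_min)
    stop(sprintf("need at least %d values for mode detection (got %d)",
                 n_min, length(x)))
  d <- stats::density(x, bw = bw)
  y <- d$y
  cand <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) &
                  y >= prominence * max(y))
  if (!length(cand)) return(numeric(0))
  ## keep a candidate only if a real valley (drop below 80% of its height)
  ## separates it from every taller accepted peak; this rejects finite-sample
  ## KDE ripples riding on a single mode
  cand <- cand[order(-y[cand])]
  keep <- cand[1]
  for (i in cand[-1]) {
    valleys <- vapply(keep, function(k)
      min(y[seq(min(i, k), max(i, k))]), numeric(1))
    if (all(valleys < 0.8 * y[i])) keep <- c(keep, i)
  }
  sort(d$x[keep])
}

#' Welch's unpaired two-sample t test
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value from the t distribution:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param a,b numeric samples, each with at least 2 values and nonzero
#'   variance.
#' @return list of class `welch_test`: `statistic`, `df`, `p_value`,
#'   `means`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("degenerate variance: both samples are constant")
  ra <- va / length(a)
  rb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(ra + rb)
  df <- (ra + rb)^2 / (ra^2 / (length(a) - 1) + rb^2 / (length(b) - 1))
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 means = c(mean(a), mean(b))),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t = %.4g, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.phenotype_fractions <- function(x, ...) {
  cat(sprintf("<phenotype_fractions> n = %d\n", attr(x, "n_total")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-11s %.4f +/- %.4f (n = %d)\n", x$phenotype[i],
                x$fraction[i], x$se[i], x$n[i]))
  invisible(x)
}
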