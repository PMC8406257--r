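#' Propidium iodide response of a surviving cell
#'
#' Fold change of the background-subtracted TRITC signal across the PI
#' staining event at 24 h.  PI enters membrane-compromised cells and boosts
#' the red channel, so a fold change at or above `threshold` calls the cell
#' PI-positive.  A pre-PI signal below the low-signal floor leaves the fold
#' undefined (`NA`), which downstream classification treats as
#' low-expression evidence.
#'
#' @param pre_tritc,post_tritc background-subtracted TRITC intensities before
#'   and after PI staining (vectors of equal length).
#' @param threshold PI-positive fold-change cutoff (default 2).
#' @param low_floor minimum trusted pre-PI signal (counts).
#' @return data.frame with columns `fold` and `pi_positive` (logical, `NA`
#'   when the fold is undefined).
#' @export
pi_response <- function(pre_tritc, post_tritc, threshold = 2,
                        low_floor = 10) {
  ok <- !is.na(pre_tritc) & pre_tritc >= low_floor & !is.na(post_tritc)
  fold <- ifelse(ok, post_tritc / pre_tritc, NA_real_)
  data.frame(fold = fold,
             pi_positive = ifelse(ok, fold >= threshold, NA))
}

#' Classify one lineage at the 24 h end point
#'
#' Decision order: (1) a lineage no longer present at 24 h lysed during or
#' after treatment (`susceptible_lysed`); (2) a lineage that divided after
#' drug removal (t > 3 h) resumed growth (`persister`); (3) a surviving
#' non-divider that is PI-positive or has lost reporter expression is dead
#' but intact (`susceptible_not_lysed`); (4) what remains - intact,
#' PI-negative, actively expressing, non-dividing - is `vbnc`.  When the PI
#' frame is missing, surviving non-dividers cannot be separated and are
#' labelled `indeterminate`.
#'
#' @param present_at_24h logical.
#' @param divided_after_3h logical.
#' @param pi_positive logical or NA (NA = undefined fold, low-expression
#'   evidence).
#' @param low_expression logical: 24 h TRITC below the low-expression cutoff.
#' @param have_pi logical: was a PI frame available at all?
#' @return character label.
#' @export
classify_lineage <- function(present_at_24h, divided_after_3h,
                             pi_positive, low_expression,
                             have_pi = TRUE) {
  if (!present_at_24h) return("susceptible_lysed")
  if (isTRUE(divided_after_3h)) return("persister")
  if (!have_pi) return("indeterminate")
  if (is.na(pi_positive)) pi_positive <- TRUE # dead-low signal
  if (pi_positive || isTRUE(low_expression)) return("susceptible_not_lysed")
  "vbnc"
}

#' Classify all time-zero lineages of a run
#'
#' Applies [classify_lineage()] to a per-lineage evidence table and
#' operationalizes "significantly lower expression" as a 24 h TRITC below
#' the `low_expr_percentile` quantile of the time-zero population TRITC.
#'
#' @param features data.frame with one row per time-zero lineage and columns
#'   `lineage_id`, `present_at_24h`, `divided_after_3h`, `tritc_24h`
#'   (pre-PI, NA if absent), `tritc_post_pi` (NA if absent or no PI frame).
#' @param tritc_t0_population numeric vector of time-zero TRITC intensities
#'   defining the expression reference distribution.
#' @param pi_threshold PI fold-change cutoff.
#' @param low_expr_percentile quantile of the time-zero population below
#'   which 24 h expression counts as lost (default 0.10).
#' @param low_floor minimum trusted TRITC signal (counts).
#' @param have_pi was a post-PI frame acquired?  If `FALSE`, surviving
#'   non-dividers are labelled indeterminate, with a warning.
#' @return data.frame of class `phenotype_calls`: `lineage_id`, `label`, and
#'   evidence columns (`divided_after_3h`, `present_at_24h`,
#'   `pi_fold_change`, `expression_percentile`).
#' @export
classify_cohort <- function(features, tritc_t0_population,
                            pi_threshold = 2, low_expr_percentile = 0.10,
                            low_floor = 10, have_pi = TRUE) {
  cutoff <- stats::quantile(tritc_t0_population, low_expr_percentile,
                            na.rm = TRUE, names = FALSE)
  pop_ecdf <- stats::ecdf(tritc_t0_population)
  pi <- pi_response(features$tritc_24h, features$tritc_post_pi,
                    threshold = pi_threshold, low_floor = low_floor)
  low_expr <- !is.na(features$tritc_24h) & features$tritc_24h < cutoff
  labels <- vapply(seq_len(nrow(features)), function(i)
    classify_lineage(features$present_at_24h[i],
                     features$divided_after_3h[i],
                     pi$pi_positive[i], low_expr[i], have_pi = have_pi),
    character(1))
  if (!have_pi && any(labels == "indeterminate"))
    warning(sprintf(
      "no PI frame: %d surviving non-dividing lineage(s) labelled indeterminate",
      sum(labels == "indeterminate")))
  calls <- data.frame(
    lineage_id = features$lineage_id,
    label = labels,
    divided_after_3h = features$divided_after_3h,
    present_at_24h = features$present_at_24h,
    pi_fold_change = pi$fold,
    expression_percentile = ifelse(is.na(features$tritc_24h), NA_real_,
                                   pop_ecdf(features$tritc_24h)))
  class(calls) <- c("phenotype_calls", "data.frame")
  calls
}

#' Confusion matrix of phenotype calls against ground truth
#'
#' Joins pipeline calls to the generator's per-lineage fates by trench and
#' tabulates truth (rows) against call (columns).  This is the evaluation
#' path; the analysis itself never reads ground-truth fields.
#'
#' @param calls a [classify_cohort()] table whose `lineage_id` is the global
#'   trench id (as produced by [run_experiment()] / [analyze_stack()]).
#' @param cohort the generating `mm_cohort`.
#' @param collapse_susceptible merge the two susceptible sub-fates.
#' @return a table (truth x call).
#' @export
evaluate_calls <- function(calls, cohort, collapse_susceptible = FALSE) {
  truth <- cohort$lineages$fate[match(calls$lineage_id,
                                      cohort$lineages$trench_id)]
  lv <- c("persister", "vbnc", "susceptible_lysed", "susceptible_not_lysed")
  call <- calls$label
  if (collapse_susceptible) {
    truth <- sub("susceptible_.*", "susceptible", truth)
    call <- sub("susceptible_.*", "susceptible", call)
    lv <- c("persister", "vbnc", "susceptible")
  }
  table(truth = factor(truth, levels = lv),
        call = factor(call, levels = c(lv, "indeterminate")))
}

#' @export
print.phenotype_calls <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<phenotype_calls> %d lineage(s): %s\n", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
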