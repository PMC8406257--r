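#' Strain preset: generative parameters for a synthetic cohort
#'
#' A `strain_preset` bundles everything the synthetic-scene generator needs to
#' draw a cohort of mother-machine lineages for one strain/condition: the fate
#' composition of the population, the time-zero intracellular pH distribution
#' of each fate, the mean pH trajectory of each fate over the treatment
#' timeline, the fluorophore expression model, and the end-point propidium
#' iodide (PI) response.
#'
#' Fates are `persister`, `vbnc` and `susceptible`; susceptible lineages are
#' further split into lysed and non-lysed sub-fates by
#' `susceptible_lysed_frac`.  Trajectory anchors are linearly interpolated at
#' the imaging schedule (hourly from 0 to 6 h, then 24 h); per-cell, per-frame
#' Gaussian noise of SD `traj_sd` is added on top for frames after time zero,
#' while the time-zero value is drawn from the fate's mixture distribution.
#'
#' @param name preset identifier.
#' @param fate_probs named numeric of length 3 (`persister`, `vbnc`,
#'   `susceptible`), non-negative, summing to 1.
#' @param t0_ph named list per fate; each element a list with `means`, `sds`
#'   and `weights` describing a mixture of at most two normal components
#'   (pH units).
#' @param anchors named list per fate; each element a data.frame with columns
#'   `time_h` and `ph` giving the mean trajectory, anchor pH within
#'   [6.0, 8.5].
#' @param traj_sd per-cell trajectory noise SD in pH units (frames after 0 h).
#' @param expression_mean,expression_cv log-normal fluorophore production
#'   model (copy-number/expression proxy); mean in arbitrary units, CV
#'   dimensionless.
#' @param expression_24h_factor named numeric: multiplicative change of
#'   expression by the 24 h end point for `persister`, `vbnc` and
#'   `susceptible_not_lysed` lineages (surviving cells keep accumulating
#'   reporter; membrane-compromised cells lose it).
#' @param pi_fold named numeric: multiplicative TRITC change upon PI staining
#'   for `persister`, `vbnc` and `susceptible_not_lysed` (>1 marks membrane
#'   damage).
#' @param susceptible_lysed_frac probability that a susceptible lineage lyses
#'   (disappears from its trench) rather than remaining PI-positive.
#' @param lysis_window numeric length 2, time interval (h) in which
#'   susceptible-lysed lineages disappear.
#' @param division_window numeric length 2, interval (h) in which persister
#'   lineages divide (after drug removal at 3 h).
#'
#' @return an object of class `strain_preset`.
#' @seealso [strain_preset_default()], [read_preset()], [make_cohort()]
#' @export
strain_preset <- function(name,
                          fate_probs,
                          t0_ph,
                          anchors,
                          traj_sd = 0.1,
                          expression_mean = 1,
                          expression_cv = 0.25,
                          expression_24h_factor = c(persister = 2,
                                                    vbnc = 2,
                                                    susceptible_not_lysed = 0.3),
                          pi_fold = c(persister = 1,
                                      vbnc = 1,
                                      susceptible_not_lysed = 3),
                          susceptible_lysed_frac = 0.5,
                          lysis_window = c(1, 6),
                          division_window = c(3, 24)) {
  preset <- structure(
    list(name = name,
         fate_probs = fate_probs,
         t0_ph = t0_ph,
         anchors = anchors,
         traj_sd = traj_sd,
         expression_mean = expression_mean,
         expression_cv = expression_cv,
         expression_24h_factor = expression_24h_factor,
         pi_fold = pi_fold,
         susceptible_lysed_frac = susceptible_lysed_frac,
         lysis_window = lysis_window,
         division_window = division_window),
    class = "strain_preset")
  validate_preset(preset)
}

#' Validate a strain preset
#'
#' Checks the preset invariants and stops with a message naming the violated
#' field on failure.
#'
#' @param preset a `strain_preset` (or plain list with the same fields).
#' @return the preset, invisibly usable, with fields coerced.
#' @export
validate_preset <- function(preset) {
  fates <- c("persister", "vbnc", "susceptible")
  fp <- preset$fate_probs
  if (is.null(names(fp))) names(fp) <- fates
  fp <- fp[fates]
  if (any(is.na(fp)))
    stop("fate_probs: must name persister, vbnc and susceptible")
  if (any(fp < 0))
    stop("fate_probs: probabilities must be non-negative")
  if (abs(sum(fp) - 1) > 1e-9)
    stop(sprintf("fate_probs: must sum to 1 (got %.6g)", sum(fp)))
  preset$fate_probs <- fp

  for (f in fates) {
    mix <- preset$t0_ph[[f]]
    if (is.null(mix))
      stop(sprintf("t0_ph: missing mixture for fate '%s'", f))
    k <- length(mix$means)
    if (k < 1 || k > 2)
      stop(sprintf("t0_ph[%s]: mixture must have 1 or 2 components", f))
    if (length(mix$sds) != k || length(mix$weights) != k)
      stop(sprintf("t0_ph[%s]: means, sds, weights must have equal length", f))
    if (abs(sum(mix$weights) - 1) > 1e-9)
      stop(sprintf("t0_ph[%s]: mixture weights must sum to 1", f))
    if (any(mix$sds < 0))
      stop(sprintf("t0_ph[%s]: component SDs must be non-negative", f))
    an <- preset$anchors[[f]]
    if (is.null(an) || !all(c("time_h", "ph") %in% names(an)))
      stop(sprintf("anchors[%s]: need columns time_h and ph", f))
    if (any(an$ph < 6.0 | an$ph > 8.5))
      stop(sprintf("anchors[%s]: anchor pH values must lie in [6.0, 8.5]", f))
    if (is.unsorted(an$time_h, strictly = TRUE))
      stop(sprintf("anchors[%s]: time_h must be strictly increasing", f))
  }
  if (preset$traj_sd < 0) stop("traj_sd: must be non-negative")
  if (preset$expression_mean <= 0) stop("expression_mean: must be positive")
  if (preset$expression_cv < 0) stop("expression_cv: must be non-negative")
  if (preset$susceptible_lysed_frac < 0 || preset$susceptible_lysed_frac > 1)
    stop("susceptible_lysed_frac: must be in [0, 1]")
  if (diff(preset$lysis_window) < 0)
    stop("lysis_window: must be an increasing interval")
  if (diff(preset$division_window) < 0)
    stop("division_window: must be an increasing interval")
  preset
}

## Mixture weights for a two-component t=0 distribution with modes at lo/hi
## chosen so the mixture mean matches a target population mean.
.bimodal_t0 <- function(target_mean, lo = 7.0, hi = 7.6, sd = 0.1) {
  w_hi <- (target_mean - lo) / (hi - lo)
  list(means = c(lo, hi), sds = c(sd, sd), weights = c(1 - w_hi, w_hi))
}

#' Built-in strain/condition presets
#'
#' Returns one of the four shipped presets describing the parental
#' (indole-positive) E. coli strain, the tryptophanase knockout
#' (`delta_tnaA`), and the knockout under persistent (0.5 mM overnight) or
#' pulse (5 mM for 20 min) indole supplementation.
#'
#' The parental preset encodes: fate fractions 0.01 / 0.04 / 0.95
#' (persister / VBNC / susceptible); a unimodal time-zero pH distribution for
#' persisters centred at 7.04 and bimodal distributions (modes 7.0 and 7.6)
#' with means 7.26 and 7.28 for VBNC and susceptible cells; trajectories in
#' which VBNC/susceptible cells acidify to 7.0 by the end of the 3 h
#' ampicillin window and drift to 6.8 at 24 h, while persisters hold their pH
#' during treatment and alkalinize to 7.3 at 24 h.  The knockout presets
#' encode the single ~7.5 peak, the roughly 3.5-fold higher persister
#' fraction, and its collapse to 0.001 under persistent indole.
#'
#' @param name one of `"parental"`, `"delta_tnaA"`,
#'   `"delta_tnaA_indole_0.5mM"`, `"delta_tnaA_indole_pulse_5mM"`.
#' @return a `strain_preset`.
#' @export
strain_preset_default <- function(name = c("parental", "delta_tnaA",
                                           "delta_tnaA_indole_0.5mM",
                                           "delta_tnaA_indole_pulse_5mM")) {
  name <- match.arg(name)
  anch <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(time_h = m[, 1], ph = m[, 2])
  }
  uni <- function(mu, sd = 0.2) list(means = mu, sds = sd, weights = 1)

  if (name == "parental") {
    return(strain_preset(
      name = name,
      fate_probs = c(persister = 0.01, vbnc = 0.04, susceptible = 0.95),
      t0_ph = list(
        persister   = uni(7.04),
        vbnc        = .bimodal_t0(7.26),
        susceptible = .bimodal_t0(7.28)),
      anchors = list(
        persister   = anch(0, 7.04, 3, 7.04, 24, 7.30),
        vbnc        = anch(0, 7.26, 1, 7.10, 2, 7.03, 3, 7.00,
                           6, 7.00, 24, 6.80),
        susceptible = anch(0, 7.28, 1, 7.12, 2, 7.04, 3, 7.00,
                           6, 7.00, 24, 6.80))))
  }
  if (name %in% c("delta_tnaA", "delta_tnaA_indole_pulse_5mM")) {
    ## pulse indole does not significantly change the knockout's pH profile
    ## or composition, so the pulse preset reuses the knockout parameters.
    return(strain_preset(
      name = name,
      fate_probs = c(persister = 0.035, vbnc = 0.04, susceptible = 0.925),
      t0_ph = list(
        persister   = uni(7.5),
        vbnc        = uni(7.5),
        susceptible = uni(7.5)),
      anchors = list(
        persister   = anch(0, 7.50, 3, 7.55, 24, 7.70),
        vbnc        = anch(0, 7.50, 3, 7.20, 24, 7.20),
        susceptible = anch(0, 7.50, 3, 7.20, 24, 7.20))))
  }
  ## persistent indole supplementation of the knockout
  strain_preset(
    name = name,
    fate_probs = c(persister = 0.001, vbnc = 0.045, susceptible = 0.954),
    t0_ph = list(
      persister   = uni(7.6),
      vbnc        = uni(7.6),
      susceptible = uni(7.6)),
    anchors = list(
      persister   = anch(0, 7.60, 24, 7.60),
      vbnc        = anch(0, 7.60, 3, 7.00, 24, 7.00),
      susceptible = anch(0, 7.60, 3, 7.00, 24, 7.00)))
}

#' Restrict a preset to a single fate
#'
#' Convenience for benchmark cohorts made of one phenotype only (for example
#' a pure-persister cohort): sets the fate probabilities to a point mass.
#'
#' @param preset a `strain_preset`.
#' @param fate `"persister"`, `"vbnc"` or `"susceptible"`.
#' @return a `strain_preset` with degenerate fate probabilities.
#' @export
preset_single_fate <- function(preset, fate = c("persister", "vbnc",
                                                "susceptible")) {
  fate <- match.arg(fate)
  fp <- c(persister = 0, vbnc = 0, susceptible = 0)
  fp[fate] <- 1
  preset$fate_probs <- fp
  preset$name <- paste0(preset$name, "_", fate, "_only")
  validate_preset(preset)
}

#' Read / write presets as flat YAML files
#'
#' Presets are serialized to a small key-value YAML document so conditions can
#' be shipped and edited as plain text.  The four built-in condition files are
#' installed under `extdata/presets/`.
#'
#' @param path file path.
#' @return `read_preset` returns a validated `strain_preset`.
#' @export
read_preset <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in names(raw$anchors))
    raw$anchors[[f]] <- as.data.frame(raw$anchors[[f]])
  preset <- structure(raw, class = "strain_preset")
  preset$fate_probs <- unlist(preset$fate_probs)
  preset$expression_24h_factor <- unlist(preset$expression_24h_factor)
  preset$pi_fold <- unlist(preset$pi_fold)
  preset$lysis_window <- as.numeric(preset$lysis_window)
  preset$division_window <- as.numeric(preset$division_window)
  validate_preset(preset)
}

#' @rdname read_preset
#' @param preset a `strain_preset`.
#' @export
write_preset <- function(preset, path) {
  out <- unclass(preset)
  out$anchors <- lapply(out$anchors, function(a) as.list(a))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.strain_preset <- function(x, ...) {
  cat(sprintf("<strain_preset> %s\n", x$name))
  cat(sprintf("  fate probabilities: persister %.3g, vbnc %.3g, susceptible %.3g\n",
              x$fate_probs["persister"], x$fate_probs["vbnc"],
              x$fate_probs["susceptible"]))
  for (f in c("persister", "vbnc", "susceptible")) {
    mix <- x$t0_ph[[f]]
    cat(sprintf("  t0 pH (%s): means %s, weights %s\n", f,
                paste(format(mix$means), collapse = "/"),
                paste(format(mix$weights, digits = 3), collapse = "/")))
  }
  invisible(x)
}
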