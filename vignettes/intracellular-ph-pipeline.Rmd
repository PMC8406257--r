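---
title: "Measuring single-cell intracellular pH and calling persister/VBNC fates"
author: "mmpH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell intracellular pH and calling persister/VBNC fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A clonal *E. coli* population challenged with a lethal dose of ampicillin is
not homogeneous: most cells die (lysing, or staying intact but
membrane-compromised), a small fraction survive without resuming growth
(viable-but-non-culturable, VBNC), and an even smaller fraction — persisters
— resume division once the drug is removed. `mmpH` implements the
single-cell assay that separates these fates and measures the intracellular
pH of every cell along the way:

* Cells carrying a pHluorin–mCherry translational fusion are trapped in the
  dead-end side channels ("trenches") of a mother-machine microfluidic
  device and imaged in two fluorescence channels — FITC for the pH-sensitive
  pHluorin, TRITC for the pH-insensitive mCherry.
* The experiment timeline is: a pre-treatment frame at t = 0 h, ampicillin
  at 25x MIC for 3 h, fresh medium for 21 h, with frames taken hourly from
  0 to 6 h and once at 24 h; propidium iodide (PI) is flowed through the
  device after the 24 h frame.
* Because pHluorin and mCherry sit on one transcript, the per-cell ratio
  R = I~FITC~ / I~TRITC~ of background-subtracted mean intensities cancels
  cell-to-cell variation in expression level and plasmid copy number, and a
  linear calibration pH = a·R + b (valid over the pHluorin linear regime,
  pH 6.5–8.0) converts R to pH.
* At the end point each time-zero lineage is classified from its own
  history: absent at 24 h → susceptible (lysed); divided after drug removal
  (t > 3 h) → persister; PI-positive or reporter expression lost →
  susceptible (not lysed); otherwise → VBNC.

No raw image data are distributed with the assay, so the package includes a
synthetic-scene generator that renders ground-truthed cohorts with the same
geometry, schedule and noise structure. All validation in the test suite is
against that planted truth.

## The synthetic scene

`make_cohort()` draws lineages from a `strain_preset`. A preset encodes, per
strain/condition:

* **Fate probabilities.** The parental preset uses
  (persister, VBNC, susceptible) = (0.01, 0.04, 0.95). The tryptophanase
  knockout uses 0.035 for persisters (the knockout's persister fraction is a
  bit over three times the parental one) with VBNC unchanged, and the
  persistently indole-supplemented knockout collapses the persister fraction
  to 0.001. Susceptible lineages split 50:50 into lysed and non-lysed; the
  assay reports only the pooled susceptible fraction, so this split is a
  neutral choice.
* **Time-zero pH distributions.** Parental persisters: a single normal
  component at 7.04 (SD 0.2). Parental VBNC and susceptible cells: two
  narrow components at 7.0 and 7.6 (SD 0.1 each) with weights chosen so the
  mixture means are 7.26 and 7.28; the implied population SD (~0.31)
  matches the reported standard errors at the reported sample sizes. The
  knockout presets use a single ~7.5 peak (7.6 with indole).
* **Trajectory anchors.** Mean pH over time is piecewise-linear between
  anchors: parental VBNC/susceptible cells acidify from t = 1 h to a 7.0
  minimum at 3 h and drift to 6.8 by 24 h, while persisters hold 7.04
  through treatment and alkalinize to 7.3 at 24 h. Per-cell, per-frame
  noise of SD 0.1 pH is added around the anchored mean; this cell-level
  variance is a free parameter of the generator (population data constrain
  only the means), chosen small enough that trajectories stay orderly but
  large enough to exercise the statistics.
* **Expression.** Log-normal with mean 1 and CV 0.25 — deliberately wide, so
  that ratio normalization is doing real work in every test. By 24 h,
  surviving cells (persister, VBNC) have accumulated twice their reporter
  level, while intact dead cells have decayed to 0.3 of theirs. The decay
  encodes the observed expression loss in PI-positive cells; the
  accumulation factor keeps an actively expressing cell's 24 h signal
  clearly above the low-expression cutoff (below, "Thresholds").
* **PI response.** TRITC fold change upon staining: 3.0 for
  susceptible-non-lysed cells, 1.0 for persisters and VBNC cells.
* **Event windows.** Persisters divide once at a scheduled frame in
  (3, 24] h; lysed cells disappear at a frame in [1, 6] h.

`render_stack()` places each lineage in its own trench (mother at the closed
end, a post-division daughter abutting below it) and renders two-channel
rasters: expected per-pixel TRITC is `expression x tritc_scale` (1000 counts
by default) above a 100-count in-trench background, expected FITC is the
ground-truth ratio map applied to the cell's true pH times its TRITC. Noise
is Poisson shot noise on expected counts plus additive Gaussian read noise
(SD 2 counts), the standard sCMOS model; counts clip at the 16-bit range.
In `trace` mode the noiseless-equivalent per-cell intensities are emitted
directly, which makes 10^4–10^5-lineage population runs take seconds.

The ground-truth ratio map defaults to pH = 5R + 4, which keeps hand
computations in the documentation exact (pH 7.5 is exactly R = 0.7).

What the generator does **not** emulate: cell elongation between frames
(division appears as an abutting daughter, not as growth-and-split),
bright-field contrast, channel bleed-through or photobleaching (the real
assay acquires the two channels serially, minimizing FRET-type artifacts),
device flow, or indole chemistry — indole conditions exist only as presets.
The point-spread function is available (`psf_sigma_um`) but defaults to 0 so
that the noiseless render–measure–calibrate round trip is exact to machine
precision; with realistic blur both channels are spread identically, so the
ratio — the quantity that matters — is nearly unaffected. Passing tests
therefore demonstrate that the analysis chain is unbiased under this noise
model, not that it is robust to every artifact of real microscopy.

## The analysis chain

**Trench detection** (`detect_trenches`). Medium-filled trenches have a
higher fluorescence background than the PDMS bulk, so the per-column median
profile is a square wave; thresholding it at its range midpoint yields one
run per trench. The along-trench extent uses a quartile-based threshold
instead, because bright cells inflate the profile maximum. Both
orientations are tried and the more periodic one wins, so transposed input
yields the transposed map. Rectangles are 0-based, row-major, half-open.

**Segmentation** (`segment_cells`). Per-trench Otsu threshold on the TRITC
channel (the constitutively bright one — the detection channel is a package
choice, not dictated by the assay), connected components, minimum-size
filter of 0.5 um^2, and a distance-transform watershed split for components
longer than twice the median cell length (division doublets). A
foreground–background contrast floor of 50 counts stops Otsu from
hallucinating cells in empty, noise-only trenches; a saturation guard
errors out when more than 20% of pixels sit at the bit-depth ceiling.

**Tracking** (`link_frames`, `build_lineages`). Hourly sampling in a
confined trench means a cell's mask overlaps its predecessor heavily, so
assignment greedily maximizes pixel overlap, breaking ties by centroid
displacement then label. One deliberate extension: a freshly divided
daughter abuts below the mother without overlapping the mother's previous
footprint, so unmatched new masks within 4 um (about 1.3 cell lengths,
comfortably below the ~5 um spacing at which an unrelated neighbour could
sit) of a tracked cell are assigned as daughters. Unmatched masks beyond
that, toward the open end, are washed-in cells and are excluded. A track
missing for exactly one frame is bridged (robustness to a single
segmentation miss); two consecutive misses confirm a disappearance at the
first missing frame. Only lineages present at t = 0 enter phenotype and pH
analysis. The 6 h → 24 h jump has no intermediate frames; any net increase
in the trench's cell count connected to the resident is treated as division
evidence.

**Photometry** (`estimate_background`, `measure_cell`). Background is the
mean of in-trench, non-cell pixels per channel (median available as an
option); I is the mask mean minus background; R = I~FITC~ / I~TRITC~.
Records with non-positive TRITC carry an undefined ratio and a QC flag
rather than raising; a low-signal floor of 10 counts (5x the default
read-noise SD) flags dying cells whose ratio would otherwise blow up.

**Calibration** (`fit_calibration`, `ratio_to_ph`). The standards emulate
CCCP-equilibrated cells in buffers at pH 6.5, 7.0, 7.5, 8.0. The fit
regresses pH on the per-standard mean ratio — the direction the pipeline
applies, so inversion is never needed — with each standard weighted
equally. Estimates outside [6.5, 8.0] are flagged invalid and excluded from
means and histograms but retained in the tables; clamping instead would
pile probability mass at the range edges and bias distribution tails.

**Phenotyping** (`classify_cohort`). The decision order is fixed: lysis,
then division, then PI/expression, then VBNC. Two thresholds
operationalize qualitative statements:

* *PI fold change >= 2.* The assay established PI response by significance
  testing, not by a cutoff; a fixed fold keeps per-cell calls
  deterministic. At the rendered signal-to-noise (~1000-count signals,
  percent-level relative noise) fold-1 cells essentially never cross 2, and
  fold-3 cells always do.
* *Low expression = 24 h TRITC below the 10th percentile of the time-zero
  population.* This is a stand-in for "significantly lower expression" and
  is documented as such; it is the one knob whose miscalibration could
  bleed VBNC cells into the susceptible-non-lysed class, which is why the
  generator's expression model keeps the two populations well separated.

**Population statistics** (`phenotype_fractions`, `ph_distribution`,
`detect_modes`, `welch_test`). Fractions come with binomial standard
errors. Histograms use 0.1-pH bins over [6.4, 8.1]. Mode detection runs a
Gaussian KDE with Silverman's rule-of-thumb bandwidth and reports local
maxima above 10% of the peak density; candidate peaks not separated from a
taller accepted peak by a valley dropping below 80% of their height are
discarded, which rejects finite-sample KDE ripples without merging genuine
modes 0.6 pH apart. The Welch test is implemented from the closed-form
t / Welch–Satterthwaite formulas and is cross-checked against
`stats::t.test` to 1e-10 in the tests.

## Orchestration and reproducibility

`run_experiment()` chains generate → render → calibrate → analyze →
summarize from a single `run_config()`, echoes the fully resolved
configuration (all stage seeds included) into the run log, and writes the
five output tables plus the serialized calibration. Every stochastic stage
takes an explicit seed, so identical configurations produce byte-identical
outputs. The analysis path never reads ground-truth fields;
`evaluate_calls()` is a separate step that joins calls to truth for
confusion matrices. A thin command-line front end with `generate`,
`calibrate`, `analyze`, `evaluate` and `all` subcommands ships in
`inst/scripts/mmph.R`.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty trenches segment to zero
masks, a lone standard refuses to calibrate, constant samples refuse a
Welch test, a missing PI frame labels surviving non-dividers
`indeterminate` (with a warning) rather than guessing, and invalid presets
fail naming the offending field.

The validation suite runs image-mode cohorts of 12–60 lineages for
structural checks and 60–520 lineages for population means (a 520-trench
render-and-analyze takes well under a minute), and trace-mode cohorts of
3,000–40,000 lineages for fraction recovery — sizes at which the binomial
and SEM error budgets of the planted quantities are several times tighter
than the tolerances being checked. Rare-fate checks size cohorts so the
expected minority count stays comfortably above the required minimum
(e.g. 8,000 lineages for a 1% persister fraction when at least 50
persisters are needed).

## Known limitations

* The classifier's expression cutoff is percentile-based and assumes the
  time-zero population is a fair expression reference; strong global
  expression drift between 0 and 24 h would shift it.
* Tracking assumes at most one division per lineage matters for the call
  (as in the assay, where any regrowth marks a persister); it does not
  reconstruct full division trees over many generations.
* Mode detection reports KDE peak locations, not a mixture fit; component
  weights and overlaps are out of scope.
* The generator's trajectories are anchored to population means; it cannot
  express within-fate subpopulations with qualitatively different dynamics
  (for example the two post-treatment subpopulations the knockout shows),
  only the pooled mean path.
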