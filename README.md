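# mmpH

Single-cell intracellular pH and antibiotic-survival phenotyping for
mother-machine time-lapse data, with a ground-truthed synthetic microscope
for end-to-end validation.

## The problem

When a clonal *E. coli* population is hit with a lethal ampicillin dose
(25x MIC for 3 h, then 21 h of fresh medium), three fates coexist: most
cells are **susceptible** (they lyse, or stay intact but
membrane-compromised), a few percent become **VBNC**
(viable-but-non-culturable: intact, propidium-iodide negative, actively
expressing protein, but not dividing), and about 1% are **persisters**,
which resume division once the drug is removed. Separating these fates and
measuring each cell's intracellular pH along the way requires tracking
every cell individually in a mother-machine microfluidic device.

`mmpH` implements that measurement chain for dual-reporter
(pHluorin/mCherry) fluorescence stacks:

* **trench detection and cell segmentation** (per-trench Otsu thresholding,
  minimum-size filter, watershed splitting of doublets),
* **lineage tracking** (overlap-maximizing frame linking with division,
  lysis and washed-in handling, single-frame gap bridging),
* **ratiometric photometry**: background-subtracted per-cell intensities
  and the ratio R = I_FITC / I_TRITC, which cancels expression and
  plasmid-copy-number variation because both fluorophores sit on one
  transcript,
* **calibration**: a least-squares line pH = a·R + b fitted to
  CCCP-equilibrated standards at pH 6.5, 7.0, 7.5, 8.0 (valid over the
  pHluorin linear regime 6.5–8.0; out-of-range estimates are flagged and
  excluded from summaries),
* **phenotype calling** at 24 h, in fixed order: absent → susceptible
  (lysed); divided after t = 3 h → persister; PI fold change >= 2 or
  reporter expression below the 10th percentile of the t = 0 population →
  susceptible (not lysed); otherwise → VBNC,
* **population statistics**: phenotype fractions with binomial errors, pH
  histograms and KDE mode detection, Welch's unequal-variance t test.

Because no raw images ship with the assay, the package also contains a
first-class **synthetic-scene generator**: seeded cohorts with known
per-cell fates, pH trajectories, expression levels and PI responses,
rendered either as realistic two-channel rasters (Poisson shot noise +
Gaussian read noise, 16-bit) or as fast intensity traces. Four strain
presets encode the parental strain, the tryptophanase (ΔtnaA) knockout,
and the knockout under persistent (0.5 mM) or pulse (5 mM, 20 min) indole
supplementation.

## Worked example

A 3,000-lineage trace-mode experiment with the parental preset, run end to
end (generate → render → calibrate → analyze → classify → summarize):

```r
library(mmpH)
run <- run_experiment(run_config(preset = "parental", n_lineages = 3000,
                                 mode = "trace", seed = 42), quiet = TRUE)
run$fractions
#> <phenotype_fractions> n = 3000
#>   persister   0.0087 +/- 0.0017 (n = 26)
#>   vbnc        0.0400 +/- 0.0036 (n = 120)
#>   susceptible 0.9513 +/- 0.0039 (n = 2854)
```

The classified fractions recover the planted composition
(0.01 / 0.04 / 0.95) within binomial error. The per-phenotype pH time
course shows the signature dynamics — persisters hold their pH through
treatment and alkalinize during regrowth, while VBNC and susceptible cells
acidify to a 7.0 minimum at the end of the ampicillin window and drift to
6.8 by 24 h:

```r
run$summaries[, c("phenotype", "time_h", "n", "mean_ph", "sem")]
#>     phenotype time_h    n  mean_ph         sem
#> 1   persister      0   26 7.130428 0.036586418
#> 2        vbnc      0  120 7.246082 0.028486403
#> 3 susceptible      0 2854 7.282776 0.005899334
#> 4   persister      3   26 7.055882 0.022678270
#> 5        vbnc      3  120 6.991937 0.010208960
#> 6 susceptible      3 2158 6.998696 0.002186916
#> 7   persister     24   26 7.293347 0.017654420
#> 8        vbnc     24  120 6.804129 0.009322107
#> 9 susceptible     24 1462 6.797496 0.002573907
```

(n drops for susceptible cells at later times as lysed cells leave their
trenches.) The t = 0 susceptible distribution is bimodal:

```r
ph0 <- run$analysis$photometry
lab <- run$analysis$calls$label[match(ph0$lineage_id,
                                      run$analysis$calls$lineage_id)]
detect_modes(ph0$ph[ph0$frame_h == 0 & ph0$valid & grepl("susceptible", lab)])
#> [1] 6.999637 7.605984
```

and persisters start significantly more acidic than susceptible cells:

```r
welch_test(ph0$ph[ph0$frame_h == 0 & ph0$valid & lab == "persister"],
           ph0$ph[ph0$frame_h == 0 & ph0$valid & grepl("susceptible", lab)])
#> Welch two-sample t test: t = -4.111, df = 26.32, p = 0.0003432
```

The same chain runs on rendered images instead of traces
(`mode = "image"`), where segmentation, tracking and photometry do real
work; `evaluate_calls(run$analysis$calls, run$cohort)` then gives the
confusion matrix against the generator's truth. A command-line front end
(`inst/scripts/mmph.R`) exposes `generate`, `calibrate`, `analyze`,
`evaluate` and `all` subcommands over YAML run configurations.

## The vignette

`vignettes/intracellular-ph-pipeline.Rmd` documents the generative model
(fate probabilities, time-zero pH mixtures, trajectory anchors, expression
and noise models), every analysis threshold with its default and
rationale, the numerical choices (tie-breaks, gap bridging, out-of-range
policy, KDE peak merging), and what the synthetic benchmark does and does
not demonstrate about real microscopy data.
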