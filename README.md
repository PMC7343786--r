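# plaquesync

Quantifies **motion-synchronisation patterns of carotid atheromatous
plaque** from B-mode ultrasound image sequences, and associates them with
plaque phenotypes.

Vulnerable carotid plaques have been reported to move *asynchronously* with
respect to the pulsating arterial wall (the qualitative "jellyfish sign").
`plaquesync` turns that observation into numbers: it tracks four annotated
interfaces — the anterior/posterior wall–lumen interfaces (AWL, PWL) on the
normal wall and the plaque top/bottom surfaces (PTS, PBS) — through a cine
loop, builds radial and longitudinal displacement waveforms, and measures
phase shifts between tissue regions by normalised cross-correlation:

```
        Σᵢ (x(i) − m_x)(y(i−d) − m_y)
r_d = ─────────────────────────────────────   d = −(N−1), …, N−1
      √Σᵢ(x(i) − m_x)² · √Σᵢ(y(i) − m_y)²
```

From the maximum-|r| peak of each pixel-pair correlation the package reads a
**sign** (in-phase vs out-of-phase) and a **phase shift** `d_max` in
seconds. Three correlation types (plaque deformation vs wall diameter,
PTS vs PBS radial, PTS vs PBS longitudinal) each contribute a
synchronisation percentage and seven phase-shift statistics: a 24-feature
*motion synchronisation signature* per plaque. Downstream, the package
provides grayscale-median (GSM) echogenicity labelling, PCA feature
selection, ADASYN class balancing, Random-Forest classification under
leave-one-out cross-validation, Wilcoxon group comparisons, and an
observer-variability experiment. A synthetic speckle-phantom generator with
exact ground-truth motion makes the whole pipeline testable without
clinical recordings.

## A worked example

A synthetic recording in which the plaque top surface lags the bottom
surface by 0.3 s in the radial direction:

```r
library(plaquesync)

ph <- generate_image_sequence(
  motion_model(top_bottom_delay = 0.3, fundamental_freq = 1, seed = 50),
  phantom_geometry())

feats <- extract_features(ph$seq, ph$contours, n_trim = 12)
round(feats[c("sp_CC2", "mean_CC2", "stdev_CC2", "sp_CC3", "mean_CC3")], 3)
#> # A tibble: 1 × 5
#>   sp_CC2 mean_CC2 stdev_CC2 sp_CC3 mean_CC3
#>    <dbl>    <dbl>     <dbl>  <dbl>    <dbl>
#> 1    100     0.28         0    100     0.28
```

`mean_CC2` — the mean phase shift between the radial displacements of the
plaque top and bottom surfaces — recovers the generator's 0.3 s delay to
within one frame (0.04 s at 25 frames/s); `sp_CC2 = 100` says every pixel
pair still correlates positively (same waveform shape, shifted). The
longitudinal type (CC3) sees the same delay.

Group comparison on a synthetic two-group cohort whose delay distributions
mimic a low- vs high-stenosis split (0.16 vs 0.23 s, sd 0.14 s — a
moderate, overlapping effect):

```r
coh <- generate_cohort(cohort_spec(
  n = c(low = 26, high = 71),
  delay_mean = c(low = 0.16, high = 0.23),
  delay_sd  = c(low = 0.14, high = 0.14), seed = 6))

dplyr::filter(compare_features(coh), significant)$feature
#> [1] "mean_CC2" "mean_CC3"
```

The mean radial phase shift between the plaque surfaces separates the
groups — the designed effect. (At this effect size the rank-sum test
rejects in roughly half of the seeds, matching its theoretical power; a
moderate shift in one of 24 features is also too weak a signal for the
Random-Forest classifier.) With a clearly separated cohort the classifier
pipeline saturates:

```r
coh2 <- generate_cohort(cohort_spec(
  n = c(low = 26, high = 71),
  delay_mean = c(low = 0.08, high = 0.30),
  delay_sd  = c(low = 0.05, high = 0.05), seed = 2))
evaluate_loocv(coh2, seed = 2)
#> <plq_eval: leave-one-out evaluation>
#>  ACC SENS SPEC PREC NPV F1SC AUC
#>    1    1    1    1   1    1   1
```

## Documentation

The methods vignette (`vignettes/plaquesync-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic phantoms do and do not emulate, and the
package's numerical conventions.
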