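---
title: "Quantifying motion synchronisation of carotid plaque from B-mode ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion synchronisation of carotid plaque from B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquesync)
library(dplyr)
```

## The problem

Carotid atheromatous plaques move with every heartbeat. Clinically, an
*asynchronous* rise and fall of the plaque surface relative to the pulsatile
arterial wall (the "jellyfish sign") has been associated with vulnerable,
rupture-prone lesions, but such observations have mostly been qualitative.
`plaquesync` quantifies these synchronisation patterns from ordinary B-mode
cine loops: it tracks four expert-annotated interfaces — the anterior and
posterior wall–lumen interfaces on the normal wall adjacent to the plaque
(AWL, PWL) and the plaque top and bottom surfaces (PTS, PBS) — builds
displacement waveforms, and measures phase shifts between tissue regions by
normalised cross-correlation.

Three cross-correlation types summarise the kinematics per plaque:

* **CC1** — plaque radial deformation (the per-frame absolute radial
  distance of each vertical PTS–PBS pixel pair) against the wall diameter,
  a reference pulsatile waveform;
* **CC2** — radial displacements of vertically paired PTS and PBS pixels
  (intra-plaque radial synchrony);
* **CC3** — the longitudinal displacements of the same pairs.

From each cross-correlation two quantities are read: the **sign** of the
maximum-absolute peak (positive = in-phase, negative = out-of-phase) and the
corresponding absolute lag `d_max` in seconds, the **phase shift**. Per
plaque and per type, the package assembles the **synchronisation
percentage** (share of pairs with a positive peak) and seven histogram
statistics of the phase shifts (max, min, mean, median, standard deviation,
skewness, excess kurtosis): a 24-feature "motion synchronisation signature".

## The cross-correlation statistic

For two series $x(i)$, $y(i)$, $i = 1,\dots,N$, the package computes, for
every lag $d = -(N-1),\dots,N-1$,

$$
r_d \;=\; \frac{\sum_i \bigl(x(i)-m_x\bigr)\bigl(y(i-d)-m_y\bigr)}
{\sqrt{\sum_i (x(i)-m_x)^2}\;\sqrt{\sum_i (y(i)-m_y)^2}},
$$

with $m_x$, $m_y$ the series means and the sum running over the valid
overlap of each lag. The fixed denominator makes the self-correlation at
lag 0 exactly 1 and bounds $|r_d| \le 1$; mean subtraction makes series
from different subjects comparable. The implementation evaluates the sums
directly (no FFT), which keeps the lag-0 normalisation property exact in
floating point; the unit tests compare the full sequence against an
independent double-loop oracle at $10^{-10}$.

Ties in $|r_d|$ are broken toward the smallest absolute lag — conservative,
since it favours the synchrony interpretation. Phase-shift statistics are
computed on **absolute** lags: the clinical quantity is "how far apart in
time", not "which surface leads", and this keeps minima near zero as
reported summaries of real cohorts show.

## From images to waveforms

**Tracking.** Every contour pixel is tracked with adaptive block matching:
a reference block (default $1.6 \times 1$ mm², i.e. wide along the vessel)
is taken around each pixel in frame 1, and each subsequent frame is
searched around the position predicted by a per-pixel constant-velocity
Kalman filter. Similarity is normalised cross-correlation; the integer peak
is refined by a parabolic fit along each axis (skipped when the peak is an
exact match). The reference texture is kept from frame 1, which avoids
drift accumulation; re-centring the search at the Kalman prediction is what
makes the scheme adaptive. Defaults: search radius 5 px, process noise
0.01 px², measurement noise 0.25 px². These defaults smooth fairly
strongly, which is robust for noisy clinical-like data but attenuates
amplitude slightly; phase relations — the quantity of interest — are
unaffected, because both members of every correlated pair pass through the
same filter. For amplitude-accurate tracking (e.g. validating against
ground truth) a more responsive setting such as `process_noise = 0.25,
measurement_noise = 0.1` recovers sub-pixel RMS accuracy on clean phantoms.

**Waveforms.** Six waveform sets are built: the wall diameter (the
AWL–PWL vertical pair showing the clearest cyclic motion), radial and
longitudinal displacements of all PTS and PBS pixels, and the PTS–PBS
radial distances. "Clearest cyclic motion" is operationalised as the
fraction of periodogram power concentrated at the in-band dominant
frequency ±1 bin, maximised over candidate pairs. Twenty-five pixels are
trimmed from each lateral edge of PTS and PBS (default) so no normal wall
enters the plaque analysis; phantom-based tests use smaller trims scaled to
their smaller plaques.

**Filtering.** A 4th-order Butterworth high-pass at 0.6 Hz removes
baseline drift (breathing, probe motion) while leaving heart rates above
~40 bpm untouched. It is applied forward–backward (zero phase) so lags are
not biased, with odd-symmetric end padding and steady-state initial
conditions; without that start-up handling, transients of a 0.6 Hz IIR
filter span several seconds and would contaminate short recordings.

**Cycle window.** Signals are confined to one average cardiac cycle before
correlation: the window length is `round(frame_rate / f0)` with `f0` the
dominant frequency of the wall-diameter waveform, and the window starts at
a diameter minimum (end-diastole) located after the filter warm-up
(~1/0.6 s) whenever the recording is long enough, falling back to the
latest fitting start otherwise. Windowing bounds phase shifts by one cycle
and makes them comparable across plaques.

## Echogenicity

Grayscale is normalised per frame by the standard two-point protocol: the
median of a blood region maps to 0 and the median of an adventitia region
to 190, linearly, clipped to [0, 255]. The plaque is located automatically
in every frame from the tracked PTS/PBS positions (the pixels between the
two interfaces, half-open pixel-centre inclusion), the grayscale median
(GSM) is taken per frame, and the plaque GSM is the mean over frames.
Plaques with GSM < 25 are labelled echolucent, GSM ≥ 25 echogenic (strict
inequality at the boundary).

## Phenotype association

`evaluate_loocv()` implements the association pipeline under leave-one-out
cross-validation. For every held-out plaque, strictly inside the training
fold: features are standardised and PCA-reduced to the fewest components
covering 95 % of variance; the minority class is rebalanced by ADASYN
(k = 5 neighbours, full balance β = 1, implemented in-package); and a
probability Random Forest (ranger) is trained. Fitting PCA and ADASYN
per fold is deliberate — fitting them once on all data would leak the
held-out sample into feature selection and resampling. Synthetic samples
are used only for training, never for testing.

Tuning follows the grid of 100–900 trees in steps of 200 and `mtry` from 2
to the number of retained components, selected by inner 10-fold
cross-validation (`tune = TRUE`). Because that grid costs on the order of
10⁴ forest fits under LOOCV, the default is `tune = FALSE` with 500 trees
and `mtry = floor(sqrt(p))`; the tuned path is exercised on small cohorts
in the test suite, and the permutation-null check uses the untuned path
(the null property does not depend on tuning). Metrics (ACC, SENS, SPEC,
PREC, NPV, F1, and AUC from the pooled held-out class-probability scores)
are computed from the pooled LOOCV predictions; per-fold ROC is undefined
when each fold holds a single sample. Forests grow full trees
(`min.node.size = 1`); probability forests with large minimum node sizes
cannot split the small folds that LOOCV produces.

Group comparisons use the two-sided Wilcoxon rank-sum test with
significance at p ≤ 0.05 (inclusive, so p = 0.05 counts).

## The synthetic-data generator

No clinical recordings ship with the package, so every stage is validated
against a generator with known ground truth.

* **Waveforms** (`generate_waveform_pair()`): the cardiac pulse is a sum of
  `n_harmonics` cosines with 1/k amplitude decay — a simple periodic shape
  with a sharp autocorrelation, chosen for clear cyclic motion, not as a
  claim about true plaque kinematics. Defaults: fundamental 1.1 Hz
  (66 bpm), 3 harmonics, radial amplitude 0.4 mm, longitudinal 0.25 mm,
  25 frames/s, 5 s duration (at least three cycles are enforced; 5 s also
  leaves a settled post-filter analysis window), additive white noise
  0.02 mm, optional slow sinusoidal drift (< 0.3 Hz) emulating breathing
  and transducer motion, which the 0.6 Hz high-pass must remove.
* **Images** (`generate_image_sequence()`): a speckled tissue map (piecewise
  tissue intensities: dark lumen, mid-gray plaque, bright adventitia, with
  low-pass-filtered multiplicative speckle) is warped frame by frame by an
  analytic displacement field. The walls move apart with the pulse; the
  plaque bottom surface follows the posterior wall delayed by
  `wall_plaque_delay`; the top surface is further delayed by
  `top_bottom_delay`. Each interface carries a coherent tissue layer
  (±0.3 mm plateau) moving rigidly with it — as real tissue layers do —
  with linear shear between layers; the warp inverts the forward row map
  exactly, so returned trajectories are exact ground truth. Pixel spacing
  is 12 px/mm, image 96 × 160 px by default.
* **Cohorts** (`generate_cohort()`): either per-group feature distributions
  (for classifier sanity checks) or per-group delay distributions, in which
  case each plaque's 24 features are computed by running synthetic
  PTS/PBS pixel-pair waveforms through the real filtering/windowing/
  correlation pipeline. Plaque delays are drawn from Normal distributions
  censored at zero (phase shifts are non-negative).

One identifiability constraint shapes the defaults used in delay-recovery
studies: a delay is only recoverable from periodic signals when it is below
half a cardiac period, so phantoms probing delays up to 0.4 s draw their
fundamental from 0.8–1.2 Hz (48–72 bpm, ordinary resting heart rates),
keeping half a period ≥ 0.42 s.

**What the generator does not emulate:** real speckle decorrelation from
out-of-plane motion, depth-dependent attenuation and focusing, reverberation
and shadowing artefacts, irregular heart rhythms, and genuinely
heterogeneous intra-plaque motion. Passing tests demonstrate that the
algorithms recover known kinematics under controlled conditions; they do
not certify clinical performance.

## Numerical choices and degenerate inputs

* Cross-correlation of a constant series is undefined (zero denominator)
  and raises an error; pairs whose series degenerate this way are dropped
  from the feature assembly, and only if a whole correlation type loses all
  its pairs does the plaque error out.
* Skewness and kurtosis are moment-based ($g_1$, excess $g_2$); constant
  lag sets yield 0 by convention, and the standard deviation uses the n−1
  divisor.
* The dominant-frequency search band is 0.6–3 Hz (≈36–180 bpm), consistent
  with the 0.6 Hz high-pass rationale; a periodogram peak below 10× the
  median ordinate is treated as "no dominant frequency" (error) rather than
  returning a spurious cycle length.
* Tracker ties in the similarity map break toward the smallest displacement
  magnitude, then lexicographically; a transiently wild Kalman prediction
  is re-centred into the frame, while a target whose last position cannot
  be reached by the search raises a tracking error naming pixel and frame.
* All randomness is routed through one seed per generator call
  (bit-identical outputs under a fixed seed); LOOCV derives per-fold seeds
  from its master seed.

## Observer-variability experiment

Different observers produce slightly different contours, well approximated
as displaced versions of one another (≤ 2 px). `variability_experiment()`
re-runs the full pipeline on repeated phantom recordings with PTS/PBS
contours displaced radially by 0–2 px and compares, per feature, the
per-phantom values against the originals with the rank-sum test. The
comparison is made across repeated recordings (by default on the three
mean phase shifts) rather than within a single recording's pixel pairs:
with dozens of pairs per plaque, a within-recording test would flag
practically negligible sub-sample shifts as significant. At the study
conditions, offsets up to 2 px leave all compared features statistically
indistinguishable, while gross misplacement (tens of pixels, outside the
plaque) breaks the features — the expected failure mode.

## Problem sizes used in the shipped checks

The test-suite studies run at deliberately modest sizes chosen to make
their statistical behaviour clear: 100 seeded waveform phantoms for delay
recovery (mean absolute error ≤ one sample at 25 frames/s); full-image
phantoms of 96–160 px and 4.5–5 s for the end-to-end and variability
studies (6 repeated recordings, offsets 1 and 2 px); 200 replicates for the
Wilcoxon null and power studies (group sizes 26/71, matching a typical
low/high-stenosis split, with means 0.16 vs 0.23 s and sd 0.14 s); and 200
label permutations of a 40-plaque noise cohort for the classifier null
(mean pooled-LOOCV AUC within 0.5 ± 0.05; the slight downward drift of
pooled LOOCV AUC under permutation shrinks with cohort size and is within
that band at n = 40).

## Known limitations

* The tracker is a generic adaptive block matcher; the exact Kalman design
  of dedicated arterial-wall trackers is not reproduced, and its tuning is
  exposed rather than fixed.
* CC1 (plaque deformation vs wall diameter) correlates a difference of two
  nearly equal signals with a reference; its phase is intrinsically more
  sensitive to tracking amplitude errors than CC2/CC3, and behaves
  accordingly in the variability experiment.
* Whether phase-shift statistics should use signed or absolute lags is a
  convention; absolute lags are implemented (see above).
* The Random-Forest implementation behind the original clinical
  analyses (a Weka workbench model) is not re-created; ranger with the same tuning grid stands in
  its place, and clinical table values are not reproduction targets — the
  clinical videos are not available.

## A worked example

```{r example, eval = FALSE}
library(plaquesync)

# a phantom with a 0.3 s radial delay between plaque top and bottom
ph <- generate_image_sequence(
  motion_model(top_bottom_delay = 0.3, fundamental_freq = 1, seed = 50),
  phantom_geometry())

feats <- extract_features(ph$seq, ph$contours, n_trim = 12)
feats$mean_CC2   # ~0.30 s: the generator delay, recovered
feats$sp_CC2     # synchronisation percentage of radial intra-plaque motion

# association on a synthetic two-group cohort
coh <- generate_cohort(cohort_spec(
  n = c(low = 26, high = 71),
  delay_mean = c(low = 0.16, high = 0.23),
  delay_sd = c(low = 0.14, high = 0.14), seed = 1))
compare_features(coh) |> dplyr::filter(significant)
evaluate_loocv(coh, seed = 1)
```
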