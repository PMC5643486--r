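---
title: "Quantifying dye-transit dynamics in video fluorescein angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dye-transit dynamics in video fluorescein angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiodyn)
```

## The measurement

Video fluorescein angiography records the transit of an intravenous
sodium-fluorescein bolus through the vasculature of the retina or — through a
thinned-skull cranial window — the cortical surface. In the rodent protocol
this package targets, video is acquired at 30 frames/s for 60 s, with
recording started 5 s before bolus delivery so that every pixel has a
pre-dye baseline segment.

Each pixel's raw intensity time course is reduced to three indices:

* **half-rise** — the first time (after infusion onset) at which the
  normalized fluorescence reaches 50% of its peak, an index of filling speed;
* **half-fall** — the first time after the peak at which it decays back
  through 50%, an index of washout;
* **offset** — the late remnant fluorescence as a percentage of peak, the
  leakage indicator: dye that has crossed the blood–retinal or blood–brain
  barrier does not wash out and raises the plateau.

Computed pixel-by-pixel these yield parameter maps; arteries fill earliest
and veins latest, so the half-rise map separates vessel classes by timing
alone.

## Curve normalization and index extraction

For each pixel the baseline mean $b$ and standard deviation $s$ are taken
over the pre-bolus window (all frames before infusion onset; this also
cancels any constant pseudofluorescence). The curve is smoothed with a
centered moving average of width 0.5 s (15 samples at 30 fps, replicate
padding at the ends); the peak is located on the smoothed curve over
post-onset times and the curve is rescaled so baseline $\equiv 0$ and
smoothed peak $\equiv 100$. Crossing times use the smoothed curve with
linear interpolation between samples; the offset averages the *raw*
normalized values over the plateau window so smoothing cannot bias the
plateau level.

Numerical and validity rules:

* **Signal threshold.** A pixel with smoothed peak $\le b + 3s$ carries no
  transit signal (`low_snr`, or `no_peak` when the trace is constant) and is
  flagged, never zero-filled. The factor 3 is conventional for excluding
  the pigment-dark retinal background.
* **Saturation.** Any raw sample at the digitizer maximum flags the pixel
  `saturated`.
* **Censoring.** A curve that never falls back through 50% before the
  recording ends (common when leakage is severe) gets a censored half-fall:
  it is excluded from half-fall histograms and medians but its half-rise
  and offset remain valid, and the censored count is reported.
* **Plateau window.** The final 5 s of the recording (t = 50–55 s after
  onset at the default geometry). The window must lie after the peak.
* **Half-fall threshold.** 50% of peak-above-*baseline*, symmetric with the
  half-rise. Defining decay relative to peak-minus-plateau would be the
  main alternative; the symmetric convention is the simpler reading of
  "time to 50% decay" and is what this package implements throughout.

Time zero for all reported indices is the infusion onset, so frames before
it carry negative analysis times. Amplitude scaling and constant offsets of
the raw intensities cancel exactly (the tests assert both invariances).

## Rigid registration

Frames are aligned translation-only — adequate for a head-fixed,
anesthetized preparation. The estimator is FFT cross-correlation: frame and
reference are mean-subtracted, the raw (matched-filter) cross-power
spectrum is inverted for the integer-pixel peak, and the peak is refined to
sub-pixel resolution with a locally upsampled DFT (factor 32) followed by a
parabolic sub-grid step. The raw cross-power is used deliberately instead
of the whitened phase spectrum: whitening weights all frequencies equally,
and on noisy frames the noise-dominated high frequencies corrupt the
sub-pixel peak.

The reference is the mean of the pre-bolus baseline frames — anatomy
without dye-dependent contrast. Because those frames may themselves be
moving, they are first aligned to the first frame (whose position defines
shift zero) and then averaged; a plain average of moving frames would be
blurred and anchored at the mean baseline displacement, biasing every
absolute shift estimate.

Each frame gets a quality score: the Pearson correlation between the
reference and the integer-aligned frame, clamped to [0, 1]. Frames scoring
below 0.2, or frames with no spatial structure at all, are dropped
(flagged, skipped downstream) rather than force-aligned. Alignment
resamples by the negated shift with bilinear interpolation; pixels whose
aligned values would come from outside the frame in any used frame are
recorded in a coverage mask and flagged `out_of_frame` in the maps — a
seventh reason code alongside the six standard ones, kept separate because
neither `background` nor `low_snr` states the true cause.

## Vessel classification by fill timing

When a hand-drawn vessel label map is available it is always used as-is
(`manual_classification()`); the automatic path exists so the synthetic
pipeline runs unattended. Automatic mode segments large vessels by Otsu
threshold on the peak-intensity image, removes 8-connected components
smaller than 20 px, and splits the vessel pixels' half-rise values with 1-D
2-means initialized deterministically at the 10th and 90th percentiles.
The earlier cluster becomes artery, the later vein; remaining foreground
with a valid transit signal is the capillary/extravascular compartment.
Classification is per-pixel (whether the original analyses classified
per-pixel or per-segment is not recoverable; per-pixel is the finer
primitive). A silhouette-style separation score of the two half-rise
clusters is reported as classification quality.

## Statistics

* **Histograms** use half-open bins and are normalized to percent of
  contributing pixels (bin width 0.1 s for the time indices, 1% for
  offset — resolving the inter-sample interval and the percent scale).
* **Median / IQR** summarize each animal × class × parameter; quantiles use
  linear interpolation (R type 7) everywhere a data quantile is taken.
* **Bootstrap confidence limits.** Animals — their medians — are the
  resampling unit, not pixels: pixels within an animal are strongly
  dependent, and the confidence limits describe group-level variation. The
  group of per-animal medians is resampled with replacement 1,000 times;
  the statistic is the mean of the resampled medians and the 95% limits are
  the 2.5th/97.5th percentiles of the bootstrap distribution, taken as
  $(R+1)\alpha$ order statistics (quantile type 6, the canonical
  percentile-bootstrap convention).
* **Control cutoff and index of injury.** The cutoff is the 75th percentile
  of control pixels pooled across all control animals of a site × class ×
  parameter. Each animal's index of injury is the percentage of its valid
  pixels *strictly above* the cutoff — "beyond" is one-sided upward for all
  three indices, since slower filling, slower decay and higher residual
  fluorescence are all the pathological direction. By construction the
  index has expectation 25% when treated pixels come from the control
  distribution, which is the null reference line.
* **Group comparison** uses the two-sided Mann–Whitney rank-sum test
  (exact when the combined sample size is at most 12 without ties, normal
  approximation with tie correction otherwise).

Two choices here were genuinely open and are this package's decisions: the
cutoff is computed from *pooled* control pixels (not per-animal cutoffs
averaged), and the bootstrap statistic is the *mean* of resampled medians
(not the median of medians). Both are the simplest readings consistent with
group-level reference construction.

## The synthetic-data generator

Real angiography data cannot ship with a package, so the simulator is a
first-class module that renders videos with complete ground truth. Each
pixel follows a gamma-variate bolus curve plus a saturating leakage term:

$$I(t) = b + A\,g(t-t_0) + A\,\ell\,\bigl(1-e^{-(t-t_0)/\tau}\bigr),
\qquad g(s) = \left(\frac{s}{\alpha\beta}\right)^{\alpha}
e^{\alpha - s/\beta},$$

zero before arrival $t_0$. The gamma-variate is the standard
indicator-dilution transit model and gives a closed-form peak time
$t_0+\alpha\beta$, which the oracle tests exploit; the saturating term
raises the plateau to a fraction $\ell$ of peak, emulating leakage. The
true functional form of in-vivo intensity profiles is not published; this
model is a parametric stand-in whose *features* (arrival order, decay,
plateau) are what the pipeline measures.

Scene geometry: the retina layout is a spoke pattern of alternating
artery/vein radial vessels around a central disc over a capillary bed, with
a dim background (pigment blocks choroidal fluorescence); the cortex layout
has fewer, larger curvilinear vessels over a bright, diffuse, leaky
extravascular compartment. Per-class curve parameters are drawn per pixel
from Gaussian class distributions whose defaults were calibrated once so
the noiseless class medians land near normal in-vivo values — retinal
artery/capillary/vein half-rise about 6.5/6.7/7.4 s and offsets 10–16%,
cortical half-rise about 5.6/5.8/6.2 s and offsets 34–41% — giving the
artery < capillary < vein filling order and the faster, leakier cortical
transit. Barrier disruption is modeled by `make_disruption_scenario()`,
which shifts the mean leak fraction of the three vascular compartments
upward and touches nothing else.

Noise is additive Gaussian plus an optional signal-proportional term;
8-bit (or 16-bit) quantization with saturation is applied last. Motion is a
smooth random-walk rigid translation with configurable maximum amplitude,
applied by exact Fourier shift so that simulated motion introduces no
interpolation blur into the ground truth. All randomness flows from the
single scene seed; identical configuration and seed reproduce the stack
bit-for-bit.

What the simulator does *not* emulate: photobleaching, pulsatile or
network-resolved hemodynamics, two-compartment choroidal kinetics,
focal-plane effects, non-rigid motion, and the multi-peaked vessel-caliber
mixtures of real cranial windows. Passing tests therefore demonstrate that
the pipeline recovers known transit parameters under realistic noise,
quantization and rigid motion — not that it handles every artifact of real
recordings.

## Validation design and problem sizes

The test-suite studies use 32–64 px scenes at the full 30 fps × 60 s
geometry, sizes at which a simulated 10 + 10-animal study runs in about a
minute while every compartment keeps hundreds of pixels. The acceptance
checks verify, end to end: the 25% null calibration of the injury index
(10 + 10 animals × 10,000 pixels, 100 replicates); agreement of half-rise
and half-fall with a 1-ms root-finding oracle to 1/60 s and of offset with
the analytic plateau to 1 point; recovery of per-class medians from noisy,
motion-corrupted stacks to one histogram bin (0.1 s) and 2 points, with
drifts recovered to 0.25 px; and the leakage-disruption signature — a +0.3
leak-fraction shift drives the offset injury index far above the null while
half-rise stays at it.

## Known limitations

* The percentile bootstrap undercovers at small group sizes: at 10 animals
  the coverage-calibration check measures roughly 89–90% against the
  nominal 95% (the Student-t correction that an $n=10$ mean requires is
  larger than the bootstrap's implicit normal quantile, and finite
  resampling adds quantile noise). The confidence limits are still
  reported exactly as defined; treat them as mildly anti-conservative for
  small groups.
* Thin vessels one or two pixels wide suffer partial-volume mixing with the
  surrounding capillary signal under motion and resampling; median-based
  class summaries absorb most of this, but single-pixel values near vessel
  edges are less reliable.
* Registration is translation-only by design; rotation or non-rigid tissue
  motion is out of contract and will surface as low frame scores.
* Caching between pipeline stages was considered and rejected: at these
  problem sizes every stage re-runs in seconds and determinism under a
  fixed seed makes stale-cache bugs the only thing caching could add.

## A minimal session

```{r example, eval = FALSE}
cfg <- run_config(scene = scene_config("retina", size = 32),
                  n_control = 10, n_treated = 10,
                  offset_shift = 0.3, n_boot = 500, seed = 17)
ex <- run_experiment(cfg)
print(ex)       # per class x parameter injury table vs the 25% null
summary(ex)     # the underlying data.frame
plot(ex)        # dot plot with 2 SEM bars against the null line
```
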