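# angiodyn

Quantitative analysis of **video fluorescein angiography** for the retina
and cortical surface vasculature. After an intravenous fluorescein bolus,
every pixel of a 30 frames/s video traces a dye-transit curve; `angiodyn`
registers the frames, reduces each pixel's curve to three indices, and
turns the resulting maps into group-level leakage statistics. It is aimed
at researchers quantifying blood–retinal / blood–brain barrier integrity
from dynamic angiography, and ships a fully seeded synthetic video
simulator with ground truth so the entire pipeline is testable without
animal data.

## The indices and the injury statistic

Each pixel's curve is baseline-normalized (baseline ≡ 0, peak ≡ 100%) and
reduced to:

* **half-rise** *t*₅₀↑ — first time the curve reaches 50% of peak (filling),
* **half-fall** *t*₅₀↓ — first time after the peak it decays through 50% (washout),
* **offset** — late plateau as % of peak: remnant fluorescence, the leakage marker.

Vessels are labeled artery / vein / capillary-extravascular (manually, or
automatically from fill timing: arteries fill first). Distributions are
summarized per animal by median and IQR (linear-interpolation quantiles);
group confidence limits come from bootstrapping animal medians (1,000
resamples, percentile 95% CL). Barrier injury is scored with the **index of
injury**: the control animals' pixels are pooled and their 75th percentile
becomes a cutoff; a treated animal's index is the % of its pixels strictly
above that cutoff. By construction the index has expectation **25%** when
nothing changed, so 25% is the null reference line; groups are compared
with the Mann–Whitney rank-sum test.

The synthetic simulator renders each pixel as a gamma-variate bolus plus a
saturating leakage plateau,

    I(t) = b + A·g(t−t0) + A·ℓ·(1 − exp(−(t−t0)/τ)),   g(s) = (s/αβ)^α e^{α−s/β},

over retina (spoke vessels, dim pigmented background) or cortex (large
curvilinear vessels, bright leaky background) layouts, with camera noise,
8/16-bit quantization, and smooth rigid motion — all from one seed, with
per-pixel ground truth.

## Worked example

A simulated disruption study — 10 control and 10 treated animals, the
treated group's leak fraction shifted by +0.3:

```r
library(angiodyn)
cfg <- run_config(scene = scene_config("retina", size = 32),
                  n_control = 10, n_treated = 10,
                  offset_shift = 0.3, n_boot = 500, seed = 17)
ex <- run_experiment(cfg)
print(ex)
```

```
Simulated angiography study (retina): 10 control, 10 treated animals

Index of injury (% pixels beyond control 75% cutoff; null = 25%):
  artery     half_rise  control  25.0 +/-  0.8  treated  28.4 +/-  1.5  p = 0.0734
  artery     half_fall  control  25.0 +/-  0.9  treated  75.5 +/-  1.4  p = 0.000151
  artery     offset     control  25.0 +/-  1.3  treated 100.0 +/-  0.0  p = 5.3e-05
  vein       half_rise  control  25.0 +/-  1.3  treated  25.5 +/-  1.2  p = 0.97
  vein       half_fall  control  25.0 +/-  2.1  treated  84.5 +/-  2.0  p = 0.000153
  vein       offset     control  25.0 +/-  1.8  treated 100.0 +/-  0.0  p = 5.34e-05
  capillary  half_rise  control  25.0 +/-  0.8  treated  25.4 +/-  0.5  p = 0.82
  capillary  half_fall  control  25.0 +/-  0.7  treated  72.4 +/-  0.5  p = 0.000154
  capillary  offset     control  25.0 +/-  0.6  treated 100.0 +/-  0.0  p = 5.34e-05
```

Reading it: every control group sits at the 25% null (the calibration is
built into the statistic). The leakage shift drives the **offset** injury
index to 100% in every compartment — dye retention everywhere — and drags
**half-fall** with it (a raised plateau delays the 50% decay crossing),
while **half-rise** stays at the null: filling speed is untouched, exactly
the dissociation the index is designed to expose. `summary(ex)` returns
the table as a data.frame (cutoffs, bootstrap CLs, per-group means ± SEM,
rank-sum p); `plot(ex)` draws it against the 25% line.

Lower-level entry points: `render_video()`, `register_stack()`,
`compute_maps()`, `segment_vessels()` / `classify_by_timing()`,
`build_control_reference()`, `injury_index()`. A thin CLI wrapping the same
functions lives at `inst/cli/angiodyn.R` (subcommands `simulate`,
`register`, `analyze`, `run`).

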