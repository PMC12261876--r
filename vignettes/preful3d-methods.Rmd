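---
title: "Ventilation mapping and repeatability statistics in preful3d: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventilation mapping and repeatability statistics in preful3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preful3d)
```

# What the package computes

Phase-resolved functional lung (PREFUL) MRI reconstructs a full respiratory
cycle from a free-breathing acquisition and derives regional ventilation
maps from the signal change between respiratory phases. `preful3d`
implements the ventilation-weighted analysis chain for such data and the
statistics used to judge its repeatability, intercenter consistency and
field-strength dependence — together with a synthetic cohort generator whose
ground truth is known in closed form, so that every stage of the chain can
be verified without scanner data.

The per-measurement analysis produces eight scalar parameters:

* **Mean RVent** (mL/mL): mean of the voxel-wise regional ventilation
  `RVent = S_Ref/S_Insp − S_Ref/S_Exp`, where `S_Exp` and `S_Insp` are the
  end-expiratory and end-inspiratory signals and the reference phase
  `S_Ref` is the end-inspiratory image (the registration target). Because
  Ref = Insp, the static map reduces to `1 − S_Insp/S_Exp`.
* **CoV RVent** (%): in-mask standard deviation over mean of the static
  RVent map — a heterogeneity measure.
* **VVP_RVent** (%): proportion of parenchyma voxels with RVent strictly
  above 40% of the in-mask 90th percentile (linear-interpolation
  percentile). The complement corresponds to a ventilation defect
  percentage.
* **Mean / CoV FVL-CM** and **VVP_FVL-CM**: each voxel's flow–volume loop
  (volume = RVent over the cyclic phase order starting at end-expiration;
  flow = central cyclic difference of volume) is compared with the
  whole-parenchyma mean loop by a zero-lag Pearson correlation of the
  standardised, concatenated volume‖flow vectors; VVP_FVL-CM thresholds
  this correlation map strictly at 0.9.
* **Tidal volume** (mL): voxel-count difference between the end-inspiratory
  and end-expiratory lung masks times the voxel volume.
* **Breathing frequency** (breaths/min): detected end-inspiration peaks in
  the navigator-derived gating signal, `(n_peaks − 1)` divided by the
  spanned time.

All map statistics are taken over the parenchyma mask with large-vessel
voxels removed.

# Respiratory gating and binning

The gating signal is the spatial mean of a low-resolution navigator series
over a central region of interest, smoothed by a short moving average
(window 3 samples by default). The package convention is *higher amplitude
= more inflated*; an `invert` flag covers navigators with the opposite
polarity. Peak detection uses topographic prominence (threshold 0.2 × the
amplitude interquartile range) with a minimum separation of 1.5 s; both
values are configurable and were chosen for adult resting breathing rates
(roughly 9–18 breaths/min).

Respiratory phase is anchored at detected extrema — 0 at troughs
(end-expiration), 0.5 at peaks — and interpolated linearly in time inside
each half-cycle; samples before the first or after the last extremum have
no defined phase and are dropped with a flag. Phase-based (rather than
amplitude-based) binning was chosen because it separates the inspiratory
and expiratory limbs, which the flow–volume loops require.

Binning sorts acquisitions into equal-width cyclic phase bins,
`n_bins = floor(N / min_count)` capped at 51, merges adjacent bins (ties
toward the smaller index) until every bin holds at least `min_count = 100`
acquisitions, and then borrows `floor(0.2 × core/2)` nearest-in-phase
acquisitions from each cyclic neighbour as view sharing. "20% view
sharing" is interpreted as *each bin borrows 20% of its core count*; the
opposite reading (each bin donates 20%) would be a one-line change and the
fraction is a parameter.

# The synthetic cohort generator

The generator emulates the study design the statistics are meant for: two
centers, one carrying a 1.5-T and a 3-T scanner profile, the other one 3-T
profile; every subject is scanned twice per scanner.

**Geometry.** Two ellipsoidal lungs (default semiaxes 50 × 60 × 95 mm at
the 24³ × 10 mm default grid) minus a branching vessel tree. The
end-expiratory lung is the ellipsoid pair; the end-inspiratory lung adds
exactly `round(tidal volume / voxel volume)` shell voxels in order of
increasing ellipsoidal radius, so the mask-based tidal volume matches the
target by construction.

**Ventilation.** Specific ventilation sv (fractional volume change per
breath) is a smooth Gaussian random field: white noise smoothed to a 30 mm
correlation length, standardised in-mask, scaled to mean `sv_mean`
(drawn 0.2–0.3 per subject) and standard deviation
`0.30 × sv_mean × heterogeneity_scale`, clipped at zero. The 0.30 relative
spread at heterogeneity 1 places the RVent map CoV near the ~30% typical of
healthy lungs. Optional defects zero sv on a contiguous fraction of the
parenchyma.

**Signal model.** Proton-density dilution:
`S(x, p) = signal_scale / (1 + sv(x) · u(p))` inside the parenchyma, with
`u(p) ∈ [0, 1]` a raised-cosine inflation cycle rescaled to attain exactly
0 and 1. This model was chosen because it makes the RVent formula exactly
invertible: the static RVent of a voxel is `sv/(1+sv)`, giving closed-form
expectations for every recovery test. Noise is additive zero-mean Gaussian
with `σ = mean parenchymal signal / snr`; `snr = Inf` defines the
deterministic ideal-phantom condition used by the exactness tests. Rician
bias is ignored: at the SNR levels simulated the distinction is second
order.

**Scanner profiles.** Field strength enters *only* through two knobs: the
effective parenchymal SNR and the heterogeneity multiplier. The defaults —
1.5 T: snr 250, heterogeneity 1.0; 3 T: snr 100, heterogeneity 1.3 — were
calibrated once against the descriptive levels printed for healthy cohorts
(map CoV near 30% vs high 30s, mean FVL-CM in the high 0.9s, VVPs in the
90s) and encode the physics qualitatively: despite nominally higher SNR,
3-T lung imaging loses parenchymal signal to rapid T2* decay and
susceptibility effects, yielding noisier, more heterogeneous
ventilation-weighted maps. No susceptibility or T2* physics is simulated;
the profiles reproduce effect *directions*, not magnitudes.

**Between-measurement physiology.** Repeated scans of a subject share the
same spatial ventilation pattern (subject-level seed substream) but differ
by measurement-level draws that emulate physiological session-to-session
variability, without which repeated measurements would differ only by
thermal noise — an order of magnitude less variable than real repeated
scans:

* a global breathing-amplitude factor (log-sd 0.10) scaling effective sv
  and tidal volume together;
* a smooth multiplicative modulation of the sv field (log-sd 0.14) — the
  ventilation *distribution* is not identical between sessions;
* a smooth regional ventilation-lag field (median sd 0.03 cycle fractions)
  whose amplitude is itself a per-measurement lognormal draw (log-sd
  0.25) — breathing regularity varies between sessions, and this is the
  dominant source of between-scan variability in the FVL-CM tail;
* a breathing-frequency factor (log-sd 0.05).

These magnitudes were calibrated against the between-measurement
coefficients of variation and limits of agreement printed for repeated
healthy-volunteer PREFUL scans (per-subject mean-RVent CoV in the 5–11%
range, VVP limits of agreement of roughly ±5–13%). All physiological
variability is suppressed for `snr = Inf` profiles.

**Habituation scenario.** A perturbation applied to second measurements
scales the cycle amplitude (`tidalFactor`, e.g. 0.85 for a ~15% relative
decrease in RVent) and the breathing frequency (`frequencyFactor`), with
the ground truth updated consistently — the true mean RVent becomes
`mean(sv·f/(1+sv·f))`.

**Seeding.** All randomness derives from one root seed through named
substreams (`cohort/center`, `subject/id`, `subject × scanner × measurement
× {physio, lag, noise, nav}`), so any measurement can be regenerated
independently and identical seeds give identical cohorts.

# Statistics

* **Bland–Altman**: bias = mean difference (condition A − condition B),
  limits of agreement = bias ± 1.96 × sample sd of differences.
* **Between-measurement CoV**: per subject `100·|x1 − x2|/√2 / mean`,
  summarised by the cohort median (zero-mean subjects flagged and
  excluded). The map CoV uses the population (1/n) sd; cohort statistics
  use the sample (n−1) form. Both conventions are explicit arguments.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`, interpreted on the
  Viera–Garrett scale. The single-measurement form was chosen because each
  reported value comes from one scan, not an average of both.
* **Cohen's d (paired)**: `mean(d)/sd(d)` (the d_z form; the
  average-variance denominator is available behind a flag), interpreted on
  the Sawilowsky scale (0.01 very small … 2.0 huge) by magnitude.
* **Wilcoxon signed rank**: two-sided; zero differences dropped before
  midranking (flagged); exact null distribution up to n = 25 (full 2ⁿ sign
  enumeration when ties are present, up to n = 16), otherwise a normal
  approximation with tie and continuity corrections. All-zero differences
  return p = 1 with a flag.
* **Spatial overlap** of binary ventilated-volume maps:
  `2(n_vv + n_dd)/(n_v1 + n_v2 + n_d1 + n_d2) × 100` within the analysis
  mask.
* **Age matching**: optimal one-to-one assignment minimising total |Δage|,
  solved by an order-preserving dynamic program on the sorted age lists
  (optimal for absolute-difference costs on a line); unmatched subjects of
  the larger cohort are reported as excluded.
* **Percent change**: `100 × (comparison mean − reference mean)/reference
  mean` with the 1.5-T (condition A) cohort as reference.
* No multiple-testing correction is applied by default (a Holm option
  exists), deliberately favouring sensitivity in a repeatability setting.

# Numerical and degenerate-input conventions

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7); both VVP thresholds use strict `>` ("above").
* A phase-constant (zero-ventilation) measurement has a zero-variance
  reference loop; FVL-CM is then defined as 0 everywhere with a warning,
  and individual zero-variance voxel loops get FVL-CM 0 with a flag.
* Negative tidal volume (expiratory mask larger) is returned with a
  warning flag rather than an error.
* Non-positive in-mask signal aborts RVent computation with the offending
  voxel-phase count.
* Under-full respiratory bins are merged with the smaller cyclic
  neighbour, ties toward the smaller index.

# Problem sizes

The default configuration (24³ voxels of 10 mm, 12 phases, 4 subjects per
center) runs a full three-scanner study in seconds and is the scale used by
the test-suite fixtures. The replicate simulation studies (habituation and
field-strength direction) use a 16³ grid with 8 phases, 26 and 40 subjects
respectively, and 100 replicates — sizes chosen so that direction estimates
are stable while a complete verification run stays in the minutes range.
Study-scale cohorts (dozens of subjects, larger grids) are reachable
through the same configuration.

# What passing tests do and do not show

The generator shares the analysis chain's signal model by construction, so
closed-form recovery tests verify the *implementation*, not the physical
validity of the model. Features of real data that are deliberately absent:
k-space acquisition and reconstruction artefacts, registration error
(synthetic phases are intrinsically aligned), realistic anatomy beyond
ellipsoids-plus-vessels, Rician noise, cardiac signal components, and any
quantitative link between field strength and the profile knobs. Statistical
conclusions transfer (the repeatability machinery is agnostic to where the
numbers came from); image-chain conclusions are limited to internal
consistency.
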