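---
title: "Methods: non-invasive cerebral autoregulation indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive cerebral autoregulation indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(caindex)
library(dplyr)
```

## The problem

Cerebral autoregulation (CA) keeps cerebral blood flow roughly constant
across a range of arterial pressures. When it fails — as it can after
traumatic brain injury — flow velocity in the middle cerebral artery
(MCA) passively tracks arterial blood pressure (ABP). Two non-invasive
bedside metrics quantify this from transcranial Doppler (TCD) flow
velocity and finger-plethysmography pressure waveforms:

* **nMxa** — the mean moving-window Pearson correlation between
  slow-wave (0.005–0.05 Hz) fluctuations of ABP and of cerebral blood
  flow velocity (CBFV). Values above 0.4 indicate pressure-passive,
  dysfunctional autoregulation; healthy adults average 0.21 (SD 0.16).
* **THRR** — the transient hyperaemic response ratio. After a brief
  (5–7 s) ipsilateral carotid compression, intact autoregulation
  dilates distal resistance vessels, so flow released from compression
  transiently overshoots baseline. The first post-release systolic peak
  is ignored, the next three are averaged and divided by the resting
  systolic baseline; a ratio of at least 1.10 (a >9% flow increase)
  indicates preserved CA.

The raw recordings behind the published cohort numbers are not publicly
deposited, so the package pairs the estimators with a synthetic
waveform generator whose ground truth (the degree of pressure
passivity, the hyperaemic overshoot) is known exactly. Every
quantitative claim the package makes is computed, at run time, from
that generator plus the analysis pipeline.

## The nMxa estimator

The pipeline mirrors the established Mx-family implementation:

1. **Artefact masking.** Samples outside physiological limits (ABP
   outside 20–300 mm Hg, FV outside (0, 150] cm/s), flatline runs of
   2 s or more, and spikes more than 5 robust SDs from a 1-s rolling
   median are masked. No interpolation is performed across masked gaps;
   invalid data are excluded downstream, mirroring the "missing chunks"
   left by manual artefact removal in clinical practice.
2. **Block averaging.** Each channel is reduced to 10-s block means of
   unmasked samples (blocks anchored at the recording start; a block
   with under half its samples unmasked is invalid). A 10-s mean
   attenuates a sinusoid of frequency $f$ by $\mathrm{sinc}(\pi f
   \cdot 10)$ — about 0.94 at the 0.02 Hz band centre and near zero in
   the cardiac/respiratory bands — so block means are the conventional
   slow-wave surrogate. The explicit 0.005–0.05 Hz band-pass variant is
   deliberately not implemented: the block-mean-plus-window scheme *is*
   the definition used by continuous-monitoring software (the 5-min
   window bounds the low end at roughly 0.003 Hz).
3. **Moving-window correlation.** A 300-s window steps one block
   (10 s) at a time; each placement contributes the Pearson correlation
   of its paired valid blocks. Windows with fewer than 25 of the 30
   possible pairs (tolerating ~17% masked data) or zero variance on
   either side are omitted with a logged reason — a zero-variance
   window has no defined correlation and is *not* scored 0.
4. **Summary.** The per-side nMxa is the arithmetic mean of window
   correlations; the combined index is the unweighted mean of the
   available sides (the source protocol reports left/right and a single
   per-participant value without stating a combination rule — the
   unweighted mean is the symmetric choice). Classification is strict:
   impaired if and only if nMxa > 0.4. A recording with no valid
   windows yields an explicit "not obtainable" outcome rather than an
   error, because that is a clinically meaningful result.

nMxa uses block means of *mean* velocity, the conventional Mx input;
systolic-based variants exist but are more noise-sensitive.

## The THRR estimator

Compression episodes come either from manual annotations (the usual
clinical mode) or from auto-detection: maximal runs of beats whose
systolic value stays at or below 70% of the preceding 10-beat median,
lasting 3–10 s (wider than the nominal 5–7 s to tolerate operator
variability; a separate `duration_ok` flag still brackets 5–7 s ± 1 s).
Each episode records four validity flags — `drop_ok` (the compression
achieved the >30% systolic reduction a valid test requires),
`duration_ok`, `spacing_ok` (≥60 s recovery since the previous
episode), and `signal_ok` (enough valid beats). Baseline is the mean
systolic FV of the 5 beats immediately preceding compression onset
(about 4–6 s of rest; the source protocol says "resting flow
velocities" without a count). Episodes failing any flag are excluded
from the session mean but reported with their failed flags, because in
practice missing THRR values are usually due to poor compression
quality and the QC trail must say so.

The preserved threshold is applied inclusively at 1.10, reading the
">9% increase (ratio ≥ 1.10)" convention as one boundary.

## The synthetic generator

`sim_recording()` builds, at 125 Hz by default:

* **ABP** = mean (90 mm Hg) + slow waves + cardiac pulse train. The
  default slow waves are three incommensurate lines at 0.008, 0.021 and
  0.043 Hz with 2.0/1.5/1.0 mm Hg amplitude. The pulse is a gamma-like
  template (fast systolic upstroke, slow diastolic decay, peak ~17%
  into the cycle) scaled to a 40 mm Hg pulse pressure; beat intervals
  are jittered i.i.d. (3% fractional SD) so the train is not strictly
  periodic — beat detectors must face that.
* **FVL/FVR** = mean (55 cm/s, the plausible MCA velocity) + coupled
  slow component + intrinsic slow fluctuation + white noise + cardiac
  pulsatility on the same beat train (one cardiac cycle drives both
  channels). The coupled component is $g \cdot (\bar{FV}/\bar{ABP})
  \cdot ABP_{slow}$ — the mean-ratio scaling keeps $g$ interpretable as
  fractional pressure passivity — and the intrinsic component, sized by
  its SD (1.2 cm/s by default), is built per side from three random
  sinusoids inside the slow-wave band. $g = 1$ is fully
  pressure-passive, $g = 0$ fully decoupled.

With a single slow line and no pulsatility, the block-level correlation
has the closed form
$r = g\sigma_a' / \sqrt{g^2\sigma_a'^2 + (1-g)^2\sigma_i^2 +
\sigma_n^2}$ (with $\sigma_a'$ the scaled ABP slow SD), and the
generator is tested against it. Two departures from idealised theory
are worth knowing about:

* block series of narrowband slow waves are autocorrelated, so
  individual window correlations under $g = 0$ spread wider than the
  i.i.d. $1/\sqrt{n}$ null (their mean is still zero);
* cardiac pulsatility leaves a small shared residue in the 10-s block
  means of both channels, which adds a small positive offset to the
  measured correlation relative to the slow-wave-only closed form.

**The healthy default calibration.** The default coupling gain is
`coupling_gain = 0.15`. It was fixed once, by running 50-seed cohorts
over a small grid of gains through the full pipeline and choosing the
value whose cohort mean nMxa lands on the published healthy-adult mean
of 0.21; it has not been adjusted since. The package's default
configuration therefore *is* its healthy-adult condition, with
per-recording summaries spreading roughly ±0.05 in SD around 0.21.

**THRT sessions.** `sim_thrt_session()` modulates the compressed side
multiplicatively: a cosine-ramped drop to $(1 - \text{drop\_frac})$
during the compression and a post-release overshoot $(1 + h
e^{-\Delta t/\tau})$ that runs until the next compression starts — the
one-minute spacing exists precisely so the autoregulatory system has
recovered before the next test. With $\tau$ long relative to a few
beats, the assessed peaks 2–4 carry nearly the full overshoot and the
recoverable THRR is $1 + h$ to within a couple of percent (with the
default $\tau = 60$ s the decay over ~2 s of assessed peaks leaves
≈ 0.96 h). Compressions alternate left/right with the contralateral
channel untouched, matching the unilateral protocol of two compressions
per side.

**Artefacts.** Dropouts (channel to zero), spikes, and an optional
baseline step are injected from a dedicated RNG substream. Event counts
are deterministic (`round(rate × minutes)`, placements non-overlapping
and random): a stated rate yields an exactly enumerable artefact load,
which makes recall tests sharp. One global seed expands into named
substreams (ABP, each FV side, artefacts, THRT), so toggling one
component never perturbs another's draws, and a fixed config is
bit-reproducible.

**What the generator does not emulate.** No Windkessel/biophysical
ARI-style dynamics, no CO₂ reactivity, no intracranial pressure, no
respiratory line by default (the source protocol states no respiratory
amplitude, so it ships disabled but parameterisable), no
pulse-transit-time lag between ABP and FV, and no non-stationary
autoregulation. Passing tests therefore demonstrate that the estimators
recover known coupling and overshoot under realistic noise, jitter and
artefact load — not that they are robust to every physiological
confound in real recordings.

## Numerical choices and degenerate inputs

* Pearson correlation is `stats::cor` on the paired valid blocks;
  windows are placed on the block grid with half-open intervals, times
  in seconds from recording start, 0-based.
* Beat detection: local maxima with prominence ≥ 25% of the local
  (2-s-grid interpolated) pulse amplitude and a 0.3-s refractory
  period; within the refractory period the higher peak wins. Diastole
  is the minimum between systolic peaks. Beats overlapping any masked
  sample, or with intervals outside 0.3–2.0 s, are invalid.
* Classification boundaries: nMxa impaired strictly above 0.4 (0.4
  itself is intact); THRR preserved inclusively at 1.10.
* The power routine uses the normal-approximation formula
  $n = 2\sigma^2 (z_{1-\alpha/2} + z_{1-\beta})^2/\Delta^2$ plus one
  (the usual t-correction), rounded up; with the healthy mean 0.21,
  boundary 0.40, SD 0.16, α = 0.05 and 90% power this gives 16 per
  group. It is cross-checked against `stats::power.t.test` within ±1.
  The number of study groups is an explicit input: how a total
  recruitment target follows from a per-group size depends on the
  design, so no total is hard-coded.
* Waveform files: tab-separated with a `#`-header (sampling rate,
  channels, units), doubles written with 17 significant digits so a
  round trip is bit-exact; missing cells are masked samples. Timestamps
  must be strictly increasing at 1/fs within 1 µs.

## Problem sizes used in the test suite

The suite exercises the full protocol scale — 40-min recordings at
125 Hz — for the calibration checks (20-seed cohorts at coupling gains
1 and 0, a 50-seed cohort at the healthy default, 20 THRT sessions),
and uses shorter recordings at reduced sampling rates (typically
10–20 min at 25–50 Hz) for property checks where the quantity under
test is sampling-rate invariant; block means, in particular, are
verified to be fs-invariant to within 0.5%. Monte-Carlo properties
(coupling-gain monotonicity, the closed-form correlation check, the
null spread) use 50–100 seeds per condition.

## Known limitations

* The auto-detector for compressions assumes reasonably clean beats on
  the compressed side; heavily corrupted sessions should be annotated
  manually, as in clinical use.
* The combined nMxa is the unweighted left/right mean; if one side has
  materially fewer valid windows a quality-weighted variant might be
  preferable, but the per-side values and window counts are always
  reported so the choice is transparent.
* Episode validity flags are computed, never overridden: a session
  whose every compression fails QC is "not obtainable" by design.
* The generator's artefact model (dropouts, spikes, steps) covers the
  failure modes the detector targets; real probe-motion artefacts are
  richer.
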