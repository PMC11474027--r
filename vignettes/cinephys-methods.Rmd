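---
title: "cinephys: models, statistics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cinephys: models, statistics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinephys)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The recording preparation

The package targets a specific experimental setting: rats performing a
two-choice probabilistic ("bandit") task while striatal units are recorded
on tetrodes surrounding optic fibers, with cholinergic interneurons (CINs)
identified by optogenetic tagging, cortical ECoG monitored for sleep
staging, and dopamine release measured by dLight fiber photometry. Each
trial unfolds as Light On → Center In → (500–1500 ms hold) → Go cue →
Center Out → Side In → (on rewarded trials) Food In. Left and right reward
probabilities are drawn from {10%, 50%, 90%} and change every 35–45 trials
without warning.

All times in the package are seconds on a single session clock starting at
0, and every binned window is half-open `[a, b)`. One convention removes a
whole class of off-by-one-bin disagreements.

## Optogenetic tagging

A unit counts as light-responsive when three criteria hold:

1. **Latency**: for at least one stimulation condition (pulse width ×
   train frequency), the latency from pulse onset to the first following
   spike is shorter than the latency measured from random times in the
   same session (one-sided Wilcoxon rank-sum, p < 0.01).
2. **Reliability**: a spike occurs within 15 ms of pulse onset on at least
   25% of that condition's pulses.
3. **Waveform identity**: the mean waveform of spikes < 10 ms after pulse
   onset correlates at Pearson r > 0.9 with the mean spontaneous waveform,
   guarding against laser-evoked spikes contributed by a different,
   mis-sorted neuron.

Two open parameters had to be fixed here. The number of null latency draws
defaults to the condition's pulse count (matched sample sizes give matched
power to the rank-sum test). Conditions are tested individually, with the
unit tagged if *any* condition passes, mirroring the "at least one
stimulation condition" form of the reliability clause. "Spontaneous"
spikes for the waveform comparison are those with no pulse in the
preceding 100 ms.

Duplicate screening of simultaneously tagged units uses the zero-lag
coincidence fraction — spikes of the sparser train with a partner within
±1 ms, divided by the sparser count — flagged above 0.5, with the
lower-amplitude unit recommended for removal. The published procedure was
visual cross-correlogram inspection; the 0.5/±1 ms rule is this package's
operationalisation and both numbers are config-exposed.

## Unit metrics

`basic_metrics()` returns mean rate, ISI CV and the fraction of analysed
time spent inside ISIs longer than 2 s (the "proportion of time not
spiking" that separates tonically active CINs from sporadically firing
projection neurons). When slow-wave-sleep epochs are available the CV is
restricted to them — only ISIs fully inside an epoch contribute —
because firing regularity is most comparable across units within a
behavioural state.

Postspike suppression is the first 1 ms autocorrelogram bin (lags up to
200 ms, raw counts) whose count exceeds half the mean over all lags. The
maximum lag and the raw-count normalisation are package choices; the bin
centre is returned, which on an absolute-refractory train of refractory
period r lands within a bin of r.

The CIN-enrichment screen is a box filter: rate in [2, 10] Hz and CV ≤
1.9 reflect the reported tagged-CIN ranges; suppression ≥ 40 ms and peak
width ≥ 0.3 ms are package defaults chosen from the published metric
distributions, which do not print cutoffs. All four are config-exposed,
and the screen is documented as enrichment, not ground truth.

## Slow-wave-sleep detection

Per analysis frame, band powers are integrated periodogram power (PSD
integral over the band, not mean per Hz — the flat-spectrum value of k
below is defined by this choice), computed by Welch averaging of
Hann-tapered 4 s sub-segments with 50% overlap. The statistic

$$k = \frac{P(0.5\text{–}8)}{P(20\text{–}60)} - \frac{P(0.5\text{–}4)}{P(8\text{–}12)}$$

is thresholded at 3; epochs shorter than 30 s are discarded. On white
noise the band-width arithmetic gives k = 7.5/40 − 3.5/4 = −0.6875, which
the test suite recovers to within 0.2 (the residual bias comes from the
ratio of noisy band estimates).

Frame length (10 s, 50% overlap) is a package choice: it resolves 0.5 Hz
with ≥ 5 cycles while still tracking state transitions at the 30 s epoch
scale. Single below-threshold frames inside a run are bridged so that one
noisy frame cannot split an epoch across the 30 s rule. k is computed per
frame, not on smoothed power traces.

One property of k worth stating explicitly, because it constrains both
tests and expectations on real data: a *pure* low-frequency oscillation
with no accompanying 8–12 Hz power drives k strongly negative — the
subtracted ratio exists precisely to reject such artifacts. Only
broad low-frequency dominance of the kind the SWS generator produces
(delta plus elevated 4–12 Hz) crosses the threshold.

## Peri-event statistics

PETHs use 10 ms bins sliding in 5 ms steps; bin i is centred at
`t_start + 5 ms + (i−1)·5 ms` and counts spikes in `[c − 5 ms, c + 5 ms)`
in event-relative time. A 3 s window therefore has 599 bins. Counting in
event-relative rather than absolute time makes the half-open boundary
semantics exact regardless of the event's floating-point representation.

Significance uses a session-level pseudo-event null: each of `n_shuffles`
draws places the real trial count of pseudo-events uniformly wherever the
full window fits, and the per-bin mean rate over each pseudo-set forms the
null. Real-event neighbourhoods are not excluded (configurable margin
available). Three correction modes are provided and echoed into every
output:

* **bonferroni** (default): two-tailed with per-tail probability
  α/(2·n_bins). Because even 10,000 shuffles cannot resolve a tail of
  0.005/1198 ≈ 4×10⁻⁶ empirically, the default summarises the null with
  pooled moments across bins — the pseudo-event null is translation
  invariant, so all bins share one marginal — and takes the threshold
  from a Gaussian quantile with a Cornish–Fisher skewness term. The
  skewness term matters: count-based nulls are right-skewed, and a plain
  per-bin Gaussian tail measured at ~2.5× the nominal familywise rate in
  this package's own null calibration, while the pooled Cornish–Fisher
  threshold holds the familywise rate below nominal. With
  `tail = "empirical"` raw shuffle quantiles are used instead and the
  function refuses to run when the shuffle count cannot resolve the
  corrected tail.
* **pointwise**: raw shuffle quantiles at α per tail, no correction across
  bins — per-bin error calibrated, familywise not controlled.
* **maxstat**: the null distribution of the across-bin extremum of the
  standardised rate, α/2 per tail.

**Which mode for which question.** Familywise control is the right default
for claiming "this unit responds". For *onset timing* of a known response
— and for pauses in particular — bonferroni is often unusable at
realistic trial counts: with a ~6 Hz baseline and 300 trials the
per-bin null SD of the mean rate is ≈ 1.4 Hz, so the corrected lower
threshold (≈ 4.5 SD) sits below 0 Hz and *no* pause, however complete,
can be flagged. Onset analyses in the validation suite therefore use
pointwise thresholds inside a restricted search window, where the
expected number of premature false flags before a true onset is a few
percent per unit and the median onset estimate is robust to them.

Onset is the centre of the first flagged bin in the search window; offset
the centre of the last bin of that contiguous run; duration is
offset − onset + bin width. Units with no flagged bin are counted
non-responsive rather than erroring.

The selectivity index is `(M_contra − M_ipsi)/(M_contra + M_ipsi)` over a
response window, with contraversive defined by crossing choice side with
the recorded hemisphere (left hemisphere → right choices contraversive).

Sensory-vs-motor classification compares each unit's response extremum
aligned to Center Out versus aligned to the Go cue (maximum rate for
burst/rebound; baseline-minus-minimum for pause, baseline being the mean
rate 1–0.5 s pre-event, a definition this package had to supply). Windows
are component-specific: Go-aligned burst [0, 120] ms, pause [0, 400] ms,
rebound [200, 500] ms; Center-Out-aligned burst [−400, 150] ms, pause
[−200, 200] ms, rebound [0, 400] ms. Ratio > 1 labels motor; ties label
sensory. Units lacking a significant component of the requested type in
the cue-aligned window are excluded.

## Photometry

The detector trace is demultiplexed by frame: each 10 ms frame's channel
value is the mean of the interior of the 4 ms on-period, discarding the
first and last 0.5 ms as switching transitions, then linearly interpolated
onto a uniform 100 Hz grid per channel. The 405 nm control is rescaled
onto the 470 nm signal by least squares (slope + intercept by default; a
slope-only switch is provided since the published description does not
disambiguate), and

$$\mathrm{dF/F} = \frac{470 - 405_{\mathrm{fit}}}{405_{\mathrm{fit}}}$$

is computed at the channel rate *first*, then resampled to 250 Hz,
5-point median filtered, and z-scored over the whole session (no baseline
window is specified for the z-score, so the session is used). Because
bleaching and motion are shared between channels, the fitted control
removes them: the test suite verifies that dF/F is identically zero when
470 is exactly affine in 405, invariant to common rescaling, and that
bleach-only synthetic sessions stay below |mean dF/F| < 0.01 for time
constants from 300 to 3000 s.

A known, accepted attenuation: a kernel that rises instantaneously at an
event loses ~10% of its peak through the 100 Hz channel grid and the
5-point median filter (which mixes pre-onset zeros into the peak
neighbourhood). Amplitude-recovery checks therefore use a ±20% band.

## The trial-value model

Value is a beta distribution over reward probability whose pseudo-counts
decay each trial: after outcome r ∈ {0, 1},

$$\alpha \leftarrow \gamma\,\alpha + r,\qquad \beta \leftarrow \gamma\,\beta + (1 - r),$$

with uniform prior (1, 1). The trial value V is the *pre-outcome*
posterior mean α/(α+β) — the model's prediction before the outcome is
revealed, which is the quantity a reward-prediction-error analysis needs
at Side In. (The published description states the increments and the
shared decay; decay-then-increment order and posterior-mean readout are
this package's concrete definition, and every worked example in the tests
is computed under it. A post-outcome readout is available as `V_post`.)
At γ = 1 the recursion collapses exactly to the Laplace running mean
`(α₀ + Σr)/(α₀ + β₀ + t)`, which the tests verify to 10⁻¹².

γ is fitted per session by grid search over [0.50, 1.00] in steps of 0.01
(the grid is a package choice), minimising the Pearson correlation between
V and log latency to Center In; ties take the smallest γ. "Reward rate"
in the fitting rule is read as the model value V itself — the model's
only reward-rate quantity; Pearson (not Spearman) on log latency is used
since log latency is the modelled quantity.

Value regressions are OLS of a per-trial signal on V: epoch scope (one
mean per trial, two-tailed F-test at α = 0.05) or per-bin scope
(Bonferroni across bins). Constant signals return coefficient 0 with
p = 1 by convention; constant V is refused as unidentifiable. Terciles
are assigned by within-session value rank with ties broken by trial
order.

## The synthetic-session generator

The generator's defaults are the study conditions, fixed once:

| Parameter | Default | Basis |
|---|---|---|
| Block length | uniform {35…45} trials | task specification |
| Reward probabilities | {0.1, 0.5, 0.9} per side per block | task specification |
| Hold period | uniform [0.5, 1.5] s | task specification |
| Reaction time | log-normal, median 0.161 s, sdlog 0.25 | reported median of session medians |
| Latency model | `exp(0.2 − 1.0·V + ε)`, ε ~ N(0, 0.4²) | package choice; log-normal family assumed since log latency is the modelled quantity |
| Choice rule | probability matching on side values | package choice; choice behaviour is not modelled in the source analyses, any history-sensitive rule suffices downstream |
| ITI | uniform [4, 8] s | package choice; leaves ≥ 3 s of pre-Light-On history for intertrial rate analyses |
| Movement (Center Out→Side In) | uniform [0.2, 0.5] s | package choice, typical travel times |
| Value decay γ_true | 0.7 | mid-grid, recoverable |

Spike trains are gamma-renewal processes generated by time rescaling: the
instantaneous rate (base rate × product of active kernel gains, floored
at 0) is integrated on a 1 ms grid, and unit-mean gamma ISIs drawn in
rescaled time are mapped back through the inverse cumulative intensity.
This gives independent control of rate and CV (CV = 1/√shape), both of
which are analysis targets; kernel-free trains take a direct-ISI fast
path. Kernels are phenomenological boxcar gain factors — burst/rebound
gains > 1, pause gains < 1 — cue-locked to their alignment event or
movement-locked to Center Out, with optional RPE coupling (gain deviation
scaled by 1 + rpe_scale·(outcome − V_true)) and contraversive direction
gain. Per-spike waveform snippets are a fixed biphasic template plus
white noise, so the tagging waveform criterion operates on realistic
inputs; laser-evoked spikes can carry a different template to emulate
sorting contamination.

ECoG is 1/f-shaped Gaussian noise synthesised in the frequency domain per
scheduled state segment: wake adds mild 8–12 Hz (×1.5 amplitude) and
20–60 Hz (×2) emphasis; SWS multiplies 0.5–4 Hz amplitude by 10 and
4–12 Hz by 3. The ×10 delta contrast places wake k around −1 and SWS k
far above the threshold 3, so detection operates with realistic margin on
both sides. Photometry builds a dopamine trace as event kernels convolved
with a 200 ms exponential, shared bleaching (exponential to an asymptote)
and slow multiplicative motion noise across channels, modulated into a
10 kHz detector trace by the 4 ms-on/6 ms-off LED schedule on alternating
frames.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: spike-sorting errors other than the one
contamination scenario, electrode drift and nonstationary rates, bursty
non-renewal ISI structure, REM and transitional sleep states, photometry
hemodynamic artifacts, sensor nonlinearity and saturation, and any
within-session learning beyond the value model itself.

## Validation sizes and determinism

Every generator is a pure function of (spec, seed); the pipeline derives
per-stage sub-seeds from a master seed so stage reruns are stable, and
identical config + seed reproduce outputs byte-for-byte. The validation
suite and `scripts/acceptance.R` use: 150–200 null sessions of ~200
trials for shuffle calibration at 2,000 shuffles (the Gaussian/
Cornish–Fisher tail needs no empirical resolution of the corrected tail;
2,000 resolves the pointwise 0.005 quantile); 20 seeds × 300 trials for
onset recovery; 50 responsive and 1,000 non-responsive unit-sessions for
tagging; 25 × ~1,000-trial sessions for γ recovery; 500 null and 20
signal seeds for regression calibration; three amplitudes × ~160-trial
sessions for photometry recovery; and 6 × 30 min sessions for SWS
recovery. These sizes were chosen to estimate each rate with standard
errors comfortably inside its acceptance band.

## Known limitations

* The pseudo-event null treats the session as stationary; strong slow
  drifts in firing rate widen the null rather than being modelled.
* Bonferroni-corrected pause detection is power-limited at low baseline
  rates (thresholds below 0 Hz are unreachable); use pointwise or
  maxstat modes for pause timing and treat familywise claims separately.
* The duplicate screen is a heuristic stand-in for cross-correlogram
  inspection and only sees ±1 ms coincidence.
* dF/F amplitude is systematically attenuated ~10% for fast transients
  (grid + median filter), uniformly across amplitudes.
* The γ grid bottoms at 0.50; sessions truly governed by faster decay
  pile up at the boundary and should be flagged by inspecting the
  correlation profile, which `fit_gamma()` returns in full.
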