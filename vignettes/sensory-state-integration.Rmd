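---
title: "Quantifying sensory-state integration in spike trains and photometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sensory-state integration in spike trains and photometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensint)
```

## The scientific problem

Consummatory social behaviours require the coincidence of an internal drive
state and a specific sensory cue. In the circuit this package models, a
hypothalamic drive signal (GABAergic output from the medial preoptic area)
and a facial-touch cue (relayed from the spinal trigeminal nucleus) converge
on thalamic projection neurons (in the parvocellular subparafascicular
nucleus, SPFp). The experimental design interleaves three head-fixed trial
conditions — drive stimulation alone, object contact alone, and both — and
asks which units respond to the conjunction more than to either input, and
whether that conjunction is *superadditive*, i.e. larger than the sum of the
unimodal responses.

`sensint` implements the complete quantitative pipeline for this question:
trial alignment and binning, baseline z-scoring, 2σ responsiveness
classification, the cross-region multimodal-enhancement screen,
the integration (superadditivity) index, laterality metrics (selectivity
index and ROC choice probability), latency and response-profile clustering,
and isosbestic-referenced fibre-photometry analysis. Because the underlying
recordings are not publicly deposited, the package ships a synthetic-session
generator with planted ground truth so every stage can be validated end to
end.

## The disinhibition circuit model behind the generator

Interneurons (rate $r_I$) fire tonically and suppress projection cells
(rate $r_P$); the drive input $s_M(t) \in \{0,1\}$ inhibits the
interneurons and the contact input $c(t)$ excites the projection cells.
Both populations are threshold-linear:

$$r_I(t) = \max\!\big(0,\; b_I - w_{MI}\, s_M(t - \tau_I)\big), \qquad
  r_P(t) = \max\!\big(0,\; b_P + w_{SP}\, c(t) - w_{IP}\, r_I(t - \tau_P)\big).$$

Defaults: $b_I = 20$ spikes/s (the high tonic rate characteristic of the
inhibited interneuron population), $b_P = 2$, $w_{MI} = 20$, $w_{SP} = 10$,
$w_{IP} = 0.5$, $\tau_I = 20$ ms $< \tau_P = 60$ ms. With these values the
projection baseline $b_P - w_{IP} b_I = -8$ clips at zero, the two unimodal
responses are 2 spikes/s each, and the multimodal response is 12 spikes/s —
an integration index of $100 \cdot (12 - 4)/4 = 200$.

Two properties of this model matter for interpretation:

* **Superadditivity comes from rectification alone.** If $b_P$ is large
  enough that no $\max(0,\cdot)$ clips, the circuit is linear and the
  *evoked* (baseline-subtracted) responses add exactly; the integration
  index of evoked responses is 0 up to sampling error. Note that with a
  nonzero baseline the raw-rate index of a linear circuit is *negative*
  (the baseline is counted twice in the additive prediction), which is why
  `integration_table(..., baseline_subtract = TRUE)` exists: additivity is
  a statement about evoked rates. In the clipped default regime the
  baseline is 0, so raw and evoked indices coincide.
* **Latency ordering.** The interneuron trough follows stimulation onset by
  $\tau_I$; the projection rise follows the trough by $\tau_P$. With
  $\tau_I < \tau_P$ enforced, simulated interneuron trough latencies are
  strictly shorter than integration-cell peak latencies, reproducing the
  disinhibition signature.

## What the generator emulates — and what it does not

A default session plants, per region, units of six classes (integration,
interneuron, contact-cue-only, state-only, action-locked, unresponsive),
with 40% integration cells in the focal region versus 10% in a control
region and roughly 15% interneurons in the focal region. Trials follow the
head-fixed design: 10 trials per condition, 10-s stimulation epochs, 5-s
contact epochs, a 2-s delay between inputs in multimodal trials
(state-first by default, both orders on request), at least 5 s between
trials, and 5 s of pre-onset coverage so a 4-s baseline window always fits.
Spikes are emitted as inhomogeneous Poisson processes by thinning on a 1-ms
grid — comfortably finer than the 10-ms latency bins. Trial-to-trial
variability is an additive rectified rate offset (s.d. 1 spike/s); per-unit
heterogeneity is a multiplicative gain drawn uniformly in [0.85, 1.15].
Laterality is planted as a per-unit contact gain: contralateral gain 1,
ipsilateral gain uniform in [0, 0.3], applied when a session is generated
with `lateralized = TRUE` (contact epochs then alternate sides).

One global seed fans out to per-unit substreams through a counter-based
hash (`substream_seed()`), so enlarging a session never changes the spike
trains of units already present.

Real data differ in ways the generator deliberately omits: refractory
structure and bursting (spikes here are exactly Poisson), slow drift and
unit instability, correlated noise across units, behavioural variability in
contact quality, and overlap between trial epochs. Passing the planted
recovery tests therefore demonstrates that the *analysis* is correct and
calibrated, not that real recordings will be as clean.

## Baseline σ: what "2σ from baseline" is measured against

Baselines are computed from the 4 s before each trial's first input onset.
The mean rate `mu` is unambiguous; the scale `sigma` is not, and the choice
matters. Condition responses are windowed means (5 s × 10 trials), so their
sampling scale is far smaller than the per-100-ms-bin Poisson scale: for a
20 spikes/s unit the bin-level s.d. is ≈ 14 spikes/s, and even complete
suppression would only reach ≈ 1.5σ — no inhibited cell could ever satisfy
a 2σ criterion measured that way. `baseline_stats()` therefore defaults to
`sigma_mode = "trial_mean"`, the standard deviation across trials of the
per-trial baseline mean, which puts responses and baseline variability on
the same (trial) scale; the bin-pooled variant remains available
(`sigma_mode = "bin_pooled"`) for z-scoring bin-level traces, and
`profile_matrix()` consumes whichever baseline object it is given. A floor
of 0.1 spikes/s on σ keeps silent units from producing unbounded z-scores.

## Classifiers and indices

* **Responsiveness** (`classify_responsive`): $z = (R - \mu_b)/\sigma_b$;
  activated iff $z > 2$, inhibited iff $z < -2$ (strict). Under a Gaussian
  null the two-sided false-positive rate is $2\Phi(-2) \approx 4.55\%$,
  which the test suite verifies by Monte Carlo.
* **Multimodal screen** (`multimodal_screen`): enhancement
  $z = (R_{multi} - \max(R_{state}, R_{contact}))/\sigma_b$. The max of the
  two unimodal responses is the conservative reference — a unit must beat
  its best unimodal response to count as enhanced; `reference = "mean"` is
  provided for sensitivity analysis.
* **Interneuron flag** (`identify_interneurons`): inhibited under state
  stimulation *and* baseline above 10 spikes/s. The flagged population's
  defining feature is a high tonic rate (mean ≈ 20 spikes/s); 10 spikes/s
  is the midpoint between that and typical sparse-firing baselines.
* **Integration index** (`integration_index`):
  $100\,(R_{multi} - R_{state} - R_{contact})/(R_{state} + R_{contact})$ on
  raw 5-s condition means; 100 means double the additive prediction.
  Additive responses below 0.5 spikes/s make the ratio unstable; such units
  are excluded with a message, never silently.
* **Laterality** (`selectivity_index`, `choice_probability`):
  $SI = (C - I)/(C + I)$ with the same 0.5 spikes/s denominator floor;
  contra-selective iff $SI > 0.3$ (strict). Choice probability is the ROC
  area between the two per-trial response distributions, computed through
  the exact Mann–Whitney rank identity (ties ½) — the per-trial summary is
  the 5-s window mean, keeping it commensurate with the other metrics. An
  explicit histogram/trapezoid ROC mode is included and, with one bin per
  distinct value, agrees with the rank identity exactly; it exists to show
  the construction, the rank path avoids choosing a bin width.

## Dynamics

Latency analysis bins at 10 ms, averages over trials, smooths with a
Gaussian kernel (s.d. 50 ms — five latency bins; the kernel and width are
package choices since only "smoothed" is canonical), and takes the first
bin attaining the windowed extremum (earliest-tie rule: latency is first
attainment). Flat traces are excluded as having no extremum. Latencies are
invariant to positive affine transforms of the trace.

Profile clustering concatenates, per unit, the z-scored trial-average
traces of the three conditions over a 20-s trial window (200 bins at
100 ms). k-means uses k-means++ seeding and Lloyd iterations, best of 10
restarts, deterministic given a seed; inertia is asserted non-increasing at
every iteration. It is written in the package (rather than calling
`stats::kmeans`) so the iteration path is observable; the test suite checks
its optimum against `stats::kmeans` on separated data. The default k = 6 is
a configuration choice — the profile taxonomy, not a fitted quantity — and
all-condition concatenation is the default feature set.

Motion coupling (`motion_pc_correlation`) converts an ROI pixel stack to
motion energy (absolute frame-to-frame differences), extracts principal
components by SVD (capped at 500, only the first consumed), orients the
first component to correlate positively with total motion energy, and
reports its Pearson r with the smoothed rate trace.

## Photometry

The isosbestic channel (405-nm excitation) shares motion and bleaching
artefacts with the calcium-dependent 470-nm channel but not the calcium
signal. `fit_isosbestic()` regresses the 470-nm channel on the 405-nm
channel over the whole session (ordinary least squares — the dominant field
convention for this step), and

$$F_n(t) = 100 \cdot \frac{F_{470}(t) - F_{405\mathrm{fit}}(t)}{F_{405\mathrm{fit}}(t)}$$

expresses the residual in percent of the fitted reference. (Parenthesized
this way deliberately: it is the only reading of the normalization that is
dimensionless.) $F_n$ is invariant to common rescaling of both channels and
cancels any artefact that enters both channels affinely; samples where the
fitted reference falls below a floor are masked, not divided. Event-aligned
responses use a 2-s pre / 5-s post window around contact onset (package
defaults; windows are configurable), with the per-event scalar defined as
post-mean minus pre-mean. Group contrasts (e.g. mating vs sated state,
face vs back contact) report means, their difference, and a seeded
1,000-resample bootstrap interval over events.

The synthetic photometry session multiplies a double-exponential bleach
(with a stable asymptote) by (1 + planted contact transients), adds a shared
smoothed-noise motion artefact dominating the independent sensor noise, and
builds the isosbestic channel as an affine image of the same drift and
artefact — exactly the structure the normalization assumes, which is what
makes the planted 8:1 amplitude contrast recoverable within tolerance.

## Numerical conventions and degenerate inputs

* Bins are half-open $[l, r)$; a spike exactly at a window's right edge is
  excluded; counts are conserved within the analysed span.
* Times are seconds in double precision.
* Denominator floors: 0.5 spikes/s for the integration and selectivity
  ratios; 0.1 spikes/s for baseline σ; excluded units are always counted
  and reported.
* Missing per-trial events drop the trial with a warning by default and
  abort under strict mode; baseline windows that would precede the
  recording are an error.
* All generators and stochastic stages (k-means, bootstrap) are
  deterministic given their seed.

## Problem sizes used in validation

The packaged tests validate recovery at desk scale: the planted 40%/10%
enhancement contrast uses two regions of 200 units with 10 trials per
condition; null calibration uses 10,000 Gaussian-null units; the clipped /
unclipped integration regimes use 40 and 60 planted cells; latency ordering
uses 30 + 30 cells; photometry round trips use 20 events per condition.
These sizes put Monte-Carlo error comfortably inside the stated tolerances
while keeping the full suite fast.

## Known limitations

* Poisson spiking has no refractoriness; absolute rates and variances are
  faithful but spike-train autostructure is not.
* The isosbestic fit assumes channel artefacts are affinely related for the
  whole session; slow divergence of the two channels (differential
  bleaching) would need the flagged low-pass prefit variant, which is not
  implemented here.
* The laterality module analyses single units; no population decoding.
* Statistical hypothesis testing (rank tests, ANOVA) is left to standard R
  facilities on the tables this package emits.
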