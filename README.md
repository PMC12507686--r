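# sensint

Analysis of **sensory-state integration** in extracellular spike recordings
and fibre-photometry signals, for systems neuroscientists studying how an
internal drive state and a sensory cue are combined by single neurons.

The experimental design the package targets interleaves three head-fixed
trial conditions — drive (state) stimulation alone, object contact alone,
and both — and asks which units respond to the conjunction, and whether the
conjunction is *superadditive*. The core quantities:

- **Responsiveness (2σ criterion).** With baseline mean μ_b and s.d. σ_b
  from the 4 s before trial onset, a condition response R is *activated* if
  (R − μ_b)/σ_b > 2 and *inhibited* if < −2.
- **Multimodal-enhancement screen.** Enhancement
  z = (R_multi − max(R_state, R_contact)) / σ_b, with per-region fractions
  of units above +2 and below −2.
- **Integration (superadditivity) index.**
  `100 · (R_multi − (R_state + R_contact)) / (R_state + R_contact)` on 5-s
  condition-mean rates; index 100 = double the additive prediction; index
  > 0 (strict) = superadditive.
- **Laterality.** Selectivity index (C − I)/(C + I) with a 0.3 threshold,
  and ROC **choice probability** between the per-trial response
  distributions via the exact Mann–Whitney rank identity (0.5 = chance;
  informative outside 0.3/0.7).
- **Dynamics.** Latency to peak/trough on smoothed 10-ms PSTHs; k-means
  (k-means++ / Lloyd) clustering of concatenated z-scored 20-s condition
  profiles (200 bins each); behaviour-triggered averages; motion-energy
  PC1 vs rate correlation.
- **Photometry.** Isosbestic normalization
  `F_n = 100 · (F470 − F405fit)/F405fit` with F405fit the whole-session OLS
  fit of the 405-nm channel onto the 470-nm channel, event-aligned
  responses (post-mean − pre-mean) and bootstrap group contrasts.

Because the recordings this design comes from are not publicly deposited,
the package includes a synthetic-session generator built on a
rectified-linear **disinhibition circuit**: a drive input silences tonically
active interneurons (baseline 20 spikes/s), releasing projection cells that
a contact input excites. Rate rectification alone makes the joint response
superadditive. Spikes are emitted as inhomogeneous Poisson processes
(thinning on a 1-ms grid) with planted ground truth for every unit, so the
whole pipeline is testable end to end.

## Worked example

```r
library(sensint)

spec <- session_spec(seed = 42)        # 2 regions, 100 units, 10 trials/condition
ses  <- simulate_spike_session(spec)   # spikes + trials + planted ground truth
res  <- run_pipeline(ses, pipeline_config(seed = 42))

res$screen_fractions
#>   region n_units frac_enhanced frac_suppressed
#> 1   SPFp      50           0.4            0.16
#> 2   vPAG      50           0.1            0.04

res$integration_summary
#>   threshold fraction
#> 1         0     0.26
#> 2       100     0.25
#> 3       200     0.16

sum(res$state_classification$putative_interneuron)
#> [1] 10
```

The screen recovers the planted contrast exactly: 40% of focal-region
(SPFp) units are multimodal-enhanced versus 10% in the control region, and
the suppressed fraction picks up the planted interneurons (tonically
active, silenced by state stimulation), 10 of which pass the combined
inhibited + high-baseline interneuron flag. Of all 100 units, 26% have an
integration index above 0 — the planted integration cells (20 + 5 across
regions), whose median index sits near the closed-form circuit value of
200 (double-plus the additive prediction) — and the fractions above 100
and 200 fall off monotonically.

Per-unit tables (`res$screen`, `res$integration`, `res$latency`,
`res$laterality`, `res$clusters`) carry z-values, indices and labels keyed
by `unit_id`, and `write_session()` / `read_session()` round-trip sessions
through a directory of TSV tables with a JSON manifest.

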