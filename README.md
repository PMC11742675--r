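# oligostoich

Tools for inferring the subunit count (stoichiometry) of small protein
aggregates — built around the orthogonal measurements used to size
pre-fibrillar alpha-synuclein oligomers and to distinguish them from
mature fibrils:

- **Stepwise photobleaching**: idealize single-particle fluorescence
  traces into intensity levels (change-point segmentation + level
  merging, with the published quality gates: critical value 15, minimum
  15 points per level, SNR > 5) and count bleaching steps per particle.
- **Polarization-state counting**: cluster cryogenic per-frame
  polarization angles into fixed-dipole states.
- **Binomial model selection**: fit the zero-truncated binomial
  P(k | k ≥ 1) = C(m,k) pᵏ (1−p)^(m−k) / (1 − (1−p)^m)
  to the step/state histogram for each candidate oligomer order m,
  and select m by the labeling error |p̂ − p_exp| / p_exp and the fit
  residual.
- **CODEX spin counting**: fit the symmetric N-site exchange decay
  S(t) = 1/N + (N−1)/N · exp(−N k t), whose plateau 1/N counts the
  spins in a cluster (0.25 ⇒ four spins).
- **Chemical-shift state comparison**: per-residue weighted CSP
  √(¼[(δCα)² + (2.37 δCβ)² + (0.47 δCO)² + (1.30 δN_H)²]) with a 0.7 ppm
  similar/dissimilar cutoff, secondary shifts against a built-in
  random-coil scale, and a simple secondary-structure track.
- **Isotope-dilution cross-peak classification**: at labeled fraction f,
  diagonal-normalized intermolecular peaks scale as f (2-fold reduction
  at 50%) while intramolecular peaks keep full intensity.

A seeded synthetic-data module generates every input the pipeline
consumes (traces, polarization trajectories, CODEX curves, shift tables,
cross-peak tables), so the full analysis chain is testable end to end.

## Worked example

Simulate a tetramer data set at 27% labeling, run the full chain, and
check it against an independent CODEX curve:

```r
library(oligostoich)

ds <- simulate_photobleaching_dataset(1421, m = 4, p = 0.27,
                                      seed = 1, visible_only = TRUE)
codex <- simulate_codex_curve(4, rate_per_s = 1,
                              mixing_times_s = seq(0, 3, length.out = 12))
report <- run_stoichiometry_workflow(traces = ds, p_experimental = 0.25,
                                     codex_curve = codex)
report
#> == Oligomer stoichiometry report ==
#> Histogram: 1411 particles (k >= 1), 0 zero-step traces excluded
#> Selected oligomer order: m = 4 (fitted labeling efficiency 26.7%, experimental 25.0%)
#> CODEX spin count: at least 4 (plateau 0.250)
#> Estimators agree.
```

The report says: of 1421 simulated particles, 1411 passed the SNR filter
with at least one detected step; scanning oligomer orders m = 1..8, the
zero-truncated binomial fit closest to the 25% experimental labeling
fraction is the tetramer, with fitted labeling efficiency 26.7% (truth:
27%); and the CODEX curve independently plateaus at 0.250 = 1/4, so both
estimators point to a tetramer.

Chemical-shift comparison works the same way from data frames:

```r
st <- simulate_shift_tables(segments = data.frame(start = 52, end = 66,
                                                  d_ca = 3))
cmp <- run_state_comparison(st$state_a, st$state_b)
cmp
#> == Chemical-shift state comparison ==
#> 140 residues compared, 15 dissimilar (CSP >= 0.70 ppm)
#>   similar   1-51 (51 residues)
#>   dissimilar 52-66 (15 residues)
#>   similar   67-140 (74 residues)
```

`autoplot()` methods are available for histograms (`step_histogram`),
model scans (`stoich_scan`), CODEX fits (`codex_fit`) and CSP profiles
(`csp_profile`); fitted objects support `tidy()` and `glance()`.

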