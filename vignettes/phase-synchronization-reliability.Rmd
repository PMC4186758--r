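---
title: "Phase-synchronization connectivity and its reliability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization connectivity and its reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaselag)
```

This vignette is the package's own account of the science it implements:
the estimators, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic cohort does and does not
emulate, and the numerical and design decisions taken where the problem
was genuinely open.

## Connectivity estimators

Both measures start from the per-sample analytic signals `a_k`, `b_k` of
a band-passed channel pair, obtained by the frequency-domain construction
(negative FFT bins zeroed, positive doubled); the instantaneous phase is
the complex argument, wrapped to (−π, π].

**PLI.** `pli_pair()` computes `|mean(sign(ΔΦ_k))|` with `sign(0) = 0`.
The estimator is insensitive to the *magnitude* of the lag and to any
symmetric phase-difference distribution — in particular to the zero-lag
relations produced by a common source seen at two electrodes. Its
assumptions: phases are meaningful (the signal is narrowband, which the
preceding band-pass enforces) and the epoch is long enough that the
phase-difference series explores its distribution.

**Debiased wPLI.** `wpli_pair()` uses the imaginary cross-spectral
component `s_k = Im(a_k conj(b_k))` and the debiased squared estimator
`q = ((Σs)² − Σs²)/((Σ|s|)² − Σs²)`. Two conventions are ours: the
returned weight is `sqrt(max(q, 0))`, clipping the (possible) negative
debiased values so outputs lie in [0, 1] and can feed the weighted graph
machinery, which requires non-negative weights; and a degenerate
denominator (every `s_k = 0`, i.e. a pure zero-lag pair) returns 0 rather
than NaN. Cross-terms are computed from the same per-sample analytic
signals as the PLI phases, not from a separate multitaper spectral
estimate, so both measures describe the same underlying phase series.

**Epoch averaging.** `connectivity_matrices()` estimates each measure per
epoch and averages the matrices entrywise; graph measures are computed on
the epoch-averaged matrix only, since averaging first suppresses
momentary and spurious coupling patterns and retains the stable "core"
network.

A consequence of estimating per epoch worth knowing: with a band of width
B Hz and epochs of T seconds, the phase-difference series has roughly
2BT effective degrees of freedom per epoch, so the per-epoch PLI of an
*uncoupled* pair has a positive floor of order `1/sqrt(2BT)` — and
because the subject average is a mean of absolute values, this floor does
**not** shrink as epochs accumulate. Tests of common-source robustness
therefore pool the cross-spectral samples of all epochs into one
estimate, and they use the widest band, where the floor is lowest. This
is a property of the estimator itself, not an implementation artifact.

## Preprocessing

- **Butterworth band-pass**, default design order 4, applied
  forward-backward (`signal::filtfilt`) per channel and epoch. Zero-phase
  filtering matters here: a causal filter's phase lag would bias the very
  quantity the PLI measures. The design is rejected as unstable when the
  band is too narrow for the order at the given sampling rate.
- **Average reference** subtracts the instantaneous channel mean; with
  dense montages this approximates a neutral reference and removes the
  common reference signal that would otherwise appear as zero-lag
  coupling (which the PLI ignores anyway, but the wPLI's weighting is
  cleaner without it).
- **Hann taper** before the analytic-signal FFT is on by default and
  switchable. The taper suppresses spectral leakage from epoch edges but
  slightly perturbs edge-sample phases; with it off, a constant phase
  rotation commutes exactly with the analytic transform, which the exact
  lag-recovery tests exploit. Both behaviours are exposed because the
  procedure's description in the field is ambiguous about where the
  window enters; no claim is made about which variant produced any
  published table.
- Band edges must satisfy `0 < lo < hi < fs/2`; the canonical bands are
  theta 4–8, alpha1 8–10, alpha2 10–13 and beta 13–30 Hz.

## Aggregation levels

From the subject-average matrix: global connectivity (mean over the
strict upper triangle, all channels); regional degree (per region, the
mean weight from its channels to all channels of *other* regions;
midline/border channels marked "excluded" take part in global but not
regional analysis — the default 214-channel montage has 22 regions of 7
or 8 channels covering 170); inter-regional links (mean weight per
unordered region pair; 22 regions give 231 links); distance correlation
(Spearman rank correlation between pairwise weight and straight-line 3D
inter-electrode distance — chord distance, since only template cap
coordinates are available); and the strongest-links summary
(`top_links()`, default 3% of pairs, ties broken lexicographically for
reproducibility, plus per-channel mean weight as nodal degree).

## Graph measures

`weighted_clustering()` implements the intensity form
`C_i = Σ w_ik w_il w_kl / Σ w_ik w_il` (sums over ordered pairs k ≠ l,
both ≠ i), which for symmetric weights in [0, 1] reduces to the familiar
triangle-intensity normalization; `C_i = 0` when the denominator
vanishes (isolated or degree-one nodes). `weighted_path_length()` takes
edge length `1/w` (the "smallest inverse of the sum of weights" reading
of weighted distance), shortest paths via Dijkstra (`igraph`), and the
**harmonic** mean over ordered pairs, so unconnected pairs (infinite
distance) contribute zero instead of breaking the average; a fully
disconnected graph surfaces as an explicit `Lw = Inf` with a
`disconnected` flag, never silently as 0.

**Surrogate normalization.** Surrogates permute the strict-upper-triangle
weights uniformly (preserving size and weight distribution, destroying
structure). The default ensemble is 50 surrogates, independently repeated
5 times, the denominator being the mean over the 5 ensemble means —
numerically equivalent to 250 surrogates. The phrase "50 surrogates
iterated five times" could also mean 5 reshuffle sweeps per surrogate;
both interpretations converge for large ensembles, and both counts are
configurable, so neither is guessed. The constant-weight complete graph
is a useful exactness check: reshuffling is then the identity and
gamma = lambda = SWI = 1 to machine precision.

## Reliability statistics

- **CoV** = sample SD (n−1) / mean across subjects at baseline; undefined
  (flagged, not silently dropped) when the mean is zero.
- **ICC** from the two-way subject × session mean squares. The default
  form is ICC(3,1) — two-way mixed, single measure, consistency:
  `(MS_subj − MS_err) / (MS_subj + (T−1) MS_err)` — with (2,1) and (1,1)
  selectable, since the form behind any given published table is
  generally unknowable from its text. Subjects missing a session are
  dropped listwise (with a message), mirroring completer-only analyses.
- **Bootstrap CIs** resample *subjects* with replacement (10 000
  resamples by default, percentile 2.5/97.5). The phrase "bootstrapping
  with replacements and 10 000 permutations" is read as a subject-level
  nonparametric bootstrap — "with replacement" identifies a bootstrap,
  not a permutation test. Negative ICC replicates are retained, so the
  lower CI bound may be negative.
- **Categories**: excellent ICC > 0.75, good 0.60–0.75, fair 0.40–0.60,
  poor < 0.40. Because "excellent" is a strict inequality, 0.75 itself is
  "good" and 0.60 is "good", 0.40 is "fair".
- **Band comparisons**: one-way repeated-measures ANOVA of a measure
  across bands with subject as blocking factor (`F = MS_band/MS_error`),
  plus uncorrected paired t-tests between band pairs (the exact post-hoc
  correction used in the field's reports being unstated, none is
  imposed). Fully degenerate layouts (no band variability at all) return
  F = 0, p = 1.
- **Topographic permutation test**: per-channel RM-ANOVA F across bands;
  the null permutes band labels *within subject* (one relabeling per
  subject per permutation, shared across channels, preserving the spatial
  correlation structure); family-wise control via the max-F distribution;
  corrected p uses the add-one convention `(1 + count)/(n_perm + 1)`,
  which cannot return 0 and is exactly valid for randomly sampled
  permutations.

## The synthetic cohort

What it emulates: narrowband oscillatory sources with *exact* imposed
phase lags (sources are white noise brick-wall-limited to the band in the
frequency domain; lags are imposed by constant phase rotation of the
spectrum, so the lag is identical at every in-band frequency and the
ground-truth PLI is analytic); a zero-lag common source mixed into every
channel as a volume-conduction surrogate; independent broadband
background activity per channel (optional, on in the demo cohort) so that
*every* analysis band contains genuine stochastic signal; and a cohort
whose coupling strength decomposes as
`clip01(template + b_i + w_is)`, `b_i ~ N(0, σ_between)`,
`w_is ~ N(0, σ_within)` — giving a known target ICC
`σ_b²/(σ_b² + σ_w²)` for strength-driven measures. Strengths outside
[0, 1] are clipped rather than redrawn; at extreme σ this biases the
realized variance components, which is documented rather than hidden.

What it does not emulate: no forward head model (zero-lag scalar mixing
stands in for volume conduction), no 1/f spectral shape, no artifacts
(ocular, muscle, line noise) — artifact handling is out of scope — and no
spatial correlation structure beyond the common source. Passing tests on
this cohort therefore validate the *estimators and statistics*, not the
robustness of any preprocessing chain against real-world contamination.

The montage places channels on a Fibonacci spiral over the upper half of
an ellipsoid with full axis lengths 15.3 × 19.5 × 19.3 cm (the template
cap's outer dimensions read as full axis lengths); regions are contiguous
anterior–posterior strips per hemisphere, with midline and lower-border
channels excluded from regional analysis. This is a deterministic,
machine-readable stand-in for an anatomical region map; real montage
files can be supplied via `read_montage()`.

### Demonstration cohort defaults

`pipeline_config()` describes a cohort sized to exercise every stage in
minutes on one CPU: 8 subjects × 3 sessions, 32 channels (6 regions),
12 epochs of 1024 samples at 256 Hz (the same 4-s epochs as the
study-scale geometry of 4096 samples at 1024 Hz, which remains the
`simulate_recording()` default), 20 × 2 surrogates, 1000 bootstrap
resamples, 500 permutations. Two demo-design choices deserve their
rationale:

- **Coupling density and band.** Every channel joins exactly one coupled
  pair (16 of 496 pairs), and coupling lives in the beta band. With only
  a handful of coupled pairs, global connectivity is dominated by the
  uncoupled pairs' noise floor and cannot track the cohort's strength
  gradient; and the beta band, being widest, has the lowest PLI noise
  floor, giving the cleanest strength-to-connectivity mapping. Under
  these defaults the Spearman correlation between realized coupling
  strength and global beta PLI is ≈ 0.95.
- **Broadband background (gain 0.5, 4–30 Hz).** Without it, bands away
  from the coupling band contain only band-pass filter transients, which
  produce large artifactual PLI values; with it, they show honest
  noise-floor connectivity.

Sampling-rate, epoch, ensemble and resample counts in the test-suite are
deliberately modest (e.g. ICC recovery uses 50 replicates × 1000
bootstrap resamples; the permutation calibration uses 200 null
simulations × 500 permutations); these are the package's chosen problem
sizes for routine validation, with all counts configurable up to
study-scale settings.

## Numerical choices and degenerate inputs

- Phases wrap to (−π, π]; `sign(0) = 0` in the PLI; `wpli_pair()` clips
  negative debiased values to 0 and defines the all-zero-imaginary case
  as 0.
- Scaling a weight matrix by α scales `C_i` by α and `Lw` by 1/α; gamma
  and lambda are scale-invariant because surrogates scale identically —
  all three asserted in tests.
- Seeds: every stochastic routine takes an explicit integer seed,
  preserves the caller's RNG state, and derives per-(subject, session)
  seeds deterministically within 32-bit range; identical seeds give
  bit-identical output end to end.
- `bootstrap_ci()` flags (rather than hides) statistics undefined on more
  than 10% of resamples; degenerate all-equal data collapse the CI onto
  the estimate.
- TSV round-trips carry ~15 significant digits; comparisons across a
  write/read cycle should use tolerances ≈ 1e−9, not machine epsilon.

## Known limitations

- The debiasing of the wPLI assumes approximately independent samples;
  with strongly autocorrelated narrowband series its finite-sample floor
  is governed by the time-bandwidth product, as discussed above.
- Graph measures are computed on full weighted matrices only — no
  thresholding, no minimum spanning tree, no betweenness-type
  second-order measures, and no graph analysis of the 22-node regional
  matrices (too small for meaningful graph topology).
- The ICC is a relative reliability index; it says nothing about absolute
  agreement unless form (2,1) is chosen, and it can be inflated by large
  between-subject spread. The bootstrap CI tempers but does not remove
  this.
- EDF ingest is not implemented; `epoched_recording()` accepts any
  channels × epochs × samples array, so external readers can be plugged
  in front of the pipeline.
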