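# phaselag

Phase-synchronization functional connectivity from high-density EEG, and
how reliable it is: PLI/wPLI connectivity, weighted graph measures with
surrogate normalization, and cross-sectional / longitudinal reliability
statistics, exercised end to end on a synthetic cohort with known ground
truth.

## The problem

Scalp EEG mixes genuine source interactions with volume conduction and
reference effects: one source seen by many electrodes induces spurious,
*zero-lag* coupling. Phase-based connectivity measures built to ignore
zero-lag relations address this:

- **Phase lag index (PLI)** — for two channels with instantaneous phase
  difference ΔΦ_k at samples k = 1…N,

      PLI = | < sign(ΔΦ_k) > |

  the absolute mean of the signum of the phase differences. Symmetric
  (including zero-centred) phase-difference distributions give PLI ≈ 0; a
  consistent non-zero lag gives PLI → 1.
- **Debiased weighted PLI (wPLI)** — weights each sample by the magnitude
  of the imaginary cross-spectral component s_k = Im(z_k),
  z_k = a_k · conj(b_k) of the analytic signals, with the debiased squared
  estimator

      q = ((Σ s_k)² − Σ s_k²) / ((Σ |s_k|)² − Σ s_k²)

  reported as sqrt(max(q, 0)) so weights live in [0, 1] like the PLI.

Subject-average weight matrices (per-epoch estimates averaged over
epochs) feed:

- **Weighted graph measures** — the intensity-based weighted clustering
  coefficient C_i (mean Cw), the harmonic-mean weighted path length Lw
  with edge length 1/w, their ratios **gamma** = Cw / ⟨Cw_surrogate⟩ and
  **lambda** = Lw / ⟨Lw_surrogate⟩ over edge-reshuffled surrogate
  networks, and the **small-world index** SWI = gamma/lambda.
- **Reliability statistics** — inter-subject variability as the
  coefficient of variation (CoV = SD/mean at baseline), test-retest
  reliability over sessions as the intra-class correlation (ICC, forms
  (1,1)/(2,1)/(3,1)), both with subject-level percentile bootstrap 95%
  CIs; repeated-measures ANOVA of global connectivity across frequency
  bands; and max-F permutation tests for topographic band differences
  with family-wise error control.

Because no public cohort accompanies this kind of analysis, the package
ships a first-class synthetic-cohort generator: narrowband sources with
exact imposed phase lags, a zero-lag common source (volume-conduction
surrogate), broadband background activity, and controlled between- /
within-subject variance components — so every downstream statistic can be
validated against known ground truth.

## Worked example

```r
library(phaselag)

# two coupled channels (phase lag pi/4, strength 0.8) among four, plus a
# zero-lag common source emulating volume conduction
mont <- make_montage(4, c(15.3, 19.5, 19.3), n_regions = 2, n_regional = 4)
beta <- band_spec("beta", 13, 30)
spec <- coupling_spec(
  pairs = list(list(a = 1, b = 2, lag = pi / 4, strength = 0.8)),
  common_source_gain = 0.5, band = beta, snr = 5)
rec <- simulate_recording(mont, spec, n_epochs = 12, n_samples = 4096,
                          fs = 1024, seed = 1)

ae <- analytic_signal(average_reference(rec), beta)
cm <- connectivity_matrices(ae, c("pli", "wpli"))
round(cm$pli$average, 3)
#>       E001  E002  E003  E004
#> E001 0.000 0.623 0.250 0.266
#> E002 0.623 0.000 0.250 0.298
#> E003 0.250 0.250 0.000 0.074
#> E004 0.266 0.298 0.074 0.000
```

The coupled pair (E001, E002) stands out at PLI 0.62; the remaining
entries sit at the narrowband noise floor, and the shared zero-lag source
adds no coupling of its own. The wPLI sharpens the same contrast:

```r
round(cm$wpli$average[1, 2], 3)
#> [1] 0.864

gm <- graph_pipeline(cm$pli$average, n_surrogates = 50, n_iterations = 5,
                     seed = 1)
gm$normalized
#> <graph metrics> Cw = 0.3639, Lw = 3.2923 | gamma = 1.2401,
#>                 lambda = 1.0221, SWI = 1.2133

# test-retest reliability of a 40 x 3 cohort with true ICC 0.8
Y <- draw_cohort_strengths(cohort_spec(40, 3, sigma_between = 0.1,
                                       sigma_within = 0.05, seed = 2), 0.5)
icc(Y, n_boot = 1000, seed = 3)
#> <reliability> estimate = 0.807, 95% CI [0.688, 0.888], excellent
```

The true ICC of this design is 0.1² / (0.1² + 0.05²) = 0.8; the estimate
and its bootstrap CI recover it.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the
demonstration cohort (8 subjects × 3 sessions × 32 channels, 4 bands,
both measures) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # montage + cohort ground truth
Rscript analysis/02_connectivity.R  # preprocessing -> PLI/wPLI -> graphs -> tables
Rscript analysis/03_reliability.R   # reliability recomputed from the on-disk table
Rscript analysis/04_report.R        # summary report over the bundle
```

The whole sequence takes a few minutes on one CPU. Every stage is
deterministic under the configured master seed, and stage 3 verifies that
the statistics recomputed from the written long-format table match the
pipeline's own output.

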