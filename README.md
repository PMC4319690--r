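# tremorlock

Does rhythmic stimulation entrain physiological tremor? `tremorlock` is an R
package for answering that question from tri-axial accelerometry recorded
during block-designed transcranial alternating current (tACS) or photic
stimulation sessions. It provides the full phase-synchronization analysis
pipeline, a synthetic-data generator with known ground-truth coupling for
validating the pipeline end to end, and a quasi-static voxel solver for
comparing the current densities induced by different electrode montages.

It is written for motor-control and non-invasive brain stimulation
researchers who record limb tremor with accelerometers and need a
reproducible, testable alternative to ad hoc lab scripts.

## The statistic at its core

Entrainment is quantified by the phase synchronization index (PSI, also
known as the phase-locking value). Given the instantaneous phase difference
φ_t between the tremor oscillation and a reference waveform,

```
PSI = | (1/N) Σ_t exp(i φ_t) |
```

so PSI = 0 when the phase difference is uniformly distributed (no coupling)
and PSI = 1 when it is constant (perfect synchronization). The per-block
pipeline is:

1. first principal component of the three accelerometer axes (the plane of
   maximal tremor power);
2. Thomson multitaper spectrum (K = 12 DPSS tapers) and peak-frequency
   detection in the 4–14 Hz physiological band, to the nearest 0.1 Hz;
3. zero-phase band-pass: third-order high- and low-pass Butterworth filters
   at peak ± 1 Hz, each applied forward and backward (2 Hz passband, zero
   net phase shift);
4. Hilbert analytic signal → instantaneous phase and amplitude envelope;
   the envelope is variance-stabilized per block with a maximum-likelihood
   Box–Cox transform;
5. phase-stability profile: PSI against artificial sinusoidal references on
   a 0–20 Hz grid (0.1 Hz steps) with 1 Hz smoothing; the profile maximum is
   the block's entrainment statistic, and 20-bin phase-difference histograms
   plus an amplitude-modulation PSI describe how tremor amplitude depends on
   the phase alignment;
6. condition means are expressed as percent change of maximum PSI against
   the mean of the sham blocks, and group effects are tested with one-sample
   t contrasts (with Cohen's d), exact Wilcoxon signed-rank tests for
   ordinal phosphene ratings, and Benjamini–Hochberg FDR correction.

The `current_density` module solves ∇·(σ∇φ) = 0 on labelled voxel phantoms
(finite-volume, harmonic-mean face conductivities, conjugate gradients),
derives E = −∇φ, J = σE and |J|, rescales to a 1 mA source, and contrasts
electrode montages over regions of interest.

## Worked example

Simulate one subject's session (12 condition blocks; only the right-shoulder
return montage is truly coupled, κ = 0.1) and analyse it:

```r
library(tremorlock)
library(dplyr)

params <- tremor_params(f0 = 8.1, seed = 42)
kappa_map <- c(FO = 0, cM1 = 0, LSh = 0, RSh = 0.1, sham = 0, photic = 0.05)
exp <- generate_experiment(params, kappa_map = kappa_map,
                           block_duration_s = 60, initial_duration_s = 120,
                           fs = 256)
recs <- exp$recordings[setdiff(names(exp$recordings), "initial")]
res <- analyze_experiment(recs, subject_id = "s01")
res$summary
#> # A tibble: 6 × 7
#>   subject_id condition n_blocks mean_max_psi sham_baseline pct_change
#>   <chr>      <chr>        <int>        <dbl>         <dbl>      <dbl>
#> 1 s01        FO               2        0.135         0.142      -4.83
#> 2 s01        LSh              2        0.166         0.142      16.8
#> 3 s01        RSh              2        0.190         0.142      33.9
#> 4 s01        cM1              2        0.160         0.142      12.9
#> 5 s01        photic           2        0.173         0.142      21.8
#> 6 s01        sham             2        0.142         0.142       0
#> # ℹ 1 more variable: mean_amp_mod_psi <dbl>
```

The coupled montage shows the largest percent change of maximum PSI over the
sham baseline; single 60 s blocks are noisy (see `LSh`), which is why the
protocol averages two blocks per condition and twelve subjects. The exact
signed-rank test reproduces its textbook behaviour on ordinal ratings — with
eleven positive nonzero ratings out of twelve the statistic is the full
positive-rank sum:

```r
wilcoxon_signed_rank(c(0, 8, 7, 9, 5, 6, 10, 4, 3, 2, 1, 7))
#> # A tibble: 1 × 4
#>   statistic n_nonzero p_two_sided method
#>       <dbl>     <int>       <dbl> <chr>
#> 1        66        11    0.000977 exact
```

Each result type has `autoplot()` (profiles, spectra, histograms, field
slices) and broom-style `tidy()`/`glance()` methods. A command-line front
end is installed at `inst/cli/tremorlock` with subcommands `simulate`,
`analyze`, `profile`, `fieldsolve` and `report`; every run writes a
`run_log.json` with the resolved configuration and seed.

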