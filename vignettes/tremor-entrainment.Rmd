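---
title: "Quantifying tremor entrainment by rhythmic stimulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tremor entrainment by rhythmic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorlock)
```

## The problem and the model

Physiological tremor is the normal 4–14 Hz oscillation of an outstretched
limb. When a rhythmic stimulus — scalp-applied sinusoidal current (tACS) or
flickering light — is delivered near the tremor frequency without being
phase-locked to it, the two rhythms drift slowly in and out of alignment. If
the stimulation biases the tremor's phase, the phase difference between
tremor and stimulus spends more time at some alignments than others. That
preference is what this package measures.

The measurement object is the phase synchronization index of the
phase-difference series $\varphi_t$ between the band-passed tremor signal
and a reference waveform:

$$\mathrm{PSI} = \left| \frac{1}{N}\sum_t e^{i\varphi_t} \right| \in [0, 1].$$

We normalise by the sample count (the standard phase-locking-value
convention); without the $1/N$ the quantity is unbounded, and the bounds
"0 = uncoupled, 1 = perfectly synchronized" that give the index its meaning
hold only for the normalised form.

Rather than evaluating PSI only at the delivered stimulation frequency, the
pipeline substitutes artificial sinusoidal references with phase
$2\pi f t$ at every $f$ on a 0–20 Hz grid (0.1 Hz steps), giving a
*phase-stability profile* per block. This tolerates small discrepancies
between the stimulated and expressed frequency, exposes harmonic
entrainment, and makes the per-block statistic — the maximum of the smoothed
profile — robust to frequency drift between blocks. Because PSI is invariant
to a constant phase offset, a zero initial phase for the references loses no
generality; the same invariance justifies using the reference at the block's
scheduled stimulation frequency for the amplitude-modulation analysis even
in sham blocks, where the recorded stimulation channel is silent after the
ramp-down (an active stimulation sinusoid's Hilbert phase equals the
artificial reference phase up to a constant).

## The per-block pipeline and its tunables

| Stage | Parameter (config key) | Default | Why |
|---|---|---|---|
| Axis reduction | — | first principal component | captures the plane of maximal tremor power regardless of sensor placement |
| Spectrum | `n_tapers` | 12 | Thomson multitaper with DPSS tapers; K = 12 balances variance and leakage for 180 s blocks |
| | `time_bandwidth` | (K+1)/2 = 6.5 | the standard K = 2NW − 1 relation when only K is specified |
| Peak search | `peak_band_hz` | 4–14 Hz | physiological tremor range; an automated argmax needs a band to exclude low-frequency drift that a human reader would ignore |
| Band-pass | `passband_half_width_hz` | 1 Hz | separate 3rd-order high-/low-pass Butterworth filters at peak ± 1 Hz, each run forward and backward (zero net phase; 2 Hz passband) |
| Edge handling | `edge_trim_s` | 2 s | discards filter and Hilbert edge transients at both block ends before phase extraction |
| Ramp exclusion | `exclude_ramp` | off | optionally drops the first 2 × `ramp_s` so the current ramp (and the sham ramp-down) never enter the statistics |
| Stabilization | `boxcox_lambda_*` | grid −2…2, step 0.01 | per-block profile-ML Box–Cox of the amplitude envelope |
| Profile | `profile_*` | 0–20 Hz, 0.1 Hz | 201-point stability profile |
| Smoothing | `smoothing_width_hz`, `smoothing_kernel` | 1 Hz, gaussian | regularises the profile; see below |
| Histograms | `hist_bins` | 20 | phase-difference likelihood and amplitude histograms |

Two filter-design points deserve emphasis. First, the cutoffs are applied
*as designed*: forward–backward filtering squares each magnitude response,
and we do not widen the cutoffs to compensate the squared response's −3 dB
points, because the method is defined by the filter design, not by a net
bandwidth target. A consequence worth knowing is that the net amplitude gain
of the cascade at the passband centre is $|H_{hp}|^2|H_{lp}|^2 \approx
0.46$, not unity. This attenuation is harmless here: PSI depends only on
phase, which the forward–backward cascade leaves untouched, and the Box–Cox
stage renormalises amplitude scale per block. `bandpass_gain()` returns the
exact net response so users can verify both facts. Second, the zero-phase
property is checked operationally (cross-correlation between input and
output sinusoids peaks at lag 0), not just by construction.

### Why the default smoothing kernel is gaussian

The profile smoother has "total width 1 Hz" (11 grid points), with edges
reflected. With a *boxcar* kernel, a strongly entrained block — whose raw
profile is essentially a single-bin spike at the locked frequency — smooths
to an 11-bin *plateau* of equal values, and the location of the maximum
within that plateau is then decided by the noise floor: the argmax becomes
uniform over ±0.5 Hz around the true locked frequency. A peaked (gaussian,
sd = width/4) kernel preserves the location of the maximum while averaging
the same neighbourhood, so the per-block argmax stays at the locked
frequency. Both kernels are available (`smoothing_kernel`); the gaussian is
the default for this reason. Smoothing is a convex combination, so it can
never raise the profile maximum above the raw maximum — a property the test
suite asserts.

### Box–Cox placement and the amplitude histogram

Two details of the amplitude-modulation analysis are genuinely open in the
method's verbal description, and the package fixes them as follows:

* **Ordering.** The envelope is extracted first and then Box–Cox
  stabilized (`boxcox_target = "envelope"`). The alternative reading —
  transform first, then extract the envelope — is available as
  `boxcox_target = "signal"` (the band-passed trace is shifted positive
  before transforming), but the envelope-first order is the default because
  the transform's domain is naturally the positive envelope.
* **Histogram normalisation.** The amplitude histogram uses the *mean*
  envelope per phase-difference bin, normalised to sum to one. Mean-per-bin
  (rather than summed amplitude) removes the occupancy of the bins — which
  is exactly what the entrainment PSI already measures — leaving a pure
  amplitude-versus-phase profile. Stabilized envelopes can be negative (the
  log of values below one), so the pipeline shifts the stabilized envelope
  by its minimum before binning; PSI of a probability-normalised histogram
  is shift-scale sensitive in general, and this convention pins it down.

### Numerical conventions

* Phases are wrapped to $(-\pi, \pi]$ everywhere.
* Peak frequencies are rounded half-up to the nearest 0.1 Hz; ties at
  spectral or profile maxima break toward the *lower* frequency.
* Box–Cox uses the natural log branch when $|\lambda| < 10^{-8}$; inputs
  containing non-positive values are a domain error unless a shift is given.
* Degenerate inputs fail loudly with classed conditions: constant series
  (no phase), zero-variance channels, all-zero envelopes, empty masks and
  empty bands are errors, never silent NaNs.
* DPSS tapers come from the symmetric tridiagonal formulation, solved
  exactly up to length 1024 and spline-interpolated (then re-normalised)
  onto longer grids — the classical large-N construction; tapers are cached
  per session.

## The synthetic-data generator

No public accelerometry exists for this protocol, so the generator is a
first-class module with known ground truth, and every end-to-end claim the
test suite makes is a claim about data *from this generator*.

Tremor is modelled as a stochastic phase oscillator with a Kuramoto-style
forcing term,

$$d\theta = 2\pi f_0\,dt + 2\pi\kappa \sin(\varphi_{stim} - \theta)\,dt +
2\pi\,\sigma_f\,dW,$$

integrated by Euler–Maruyama at the recording rate. The amplitude envelope
is an Ornstein–Uhlenbeck process reflected at zero (mean 1, relaxation time
5 s, stationary SD 0.3), so the Box–Cox stage sees realistic right-skewed
positive amplitudes. The scalar oscillation is projected on the three
accelerometer axes through a fixed unit vector, with white sensor noise
(SD 0.05) per axis. Subject peak frequencies are drawn from
Normal(8.28, 1.52²) Hz truncated to [4, 14] — the group SD recovered from a
standard error of 0.44 Hz at N = 12. The phase-diffusion intensity
$\sigma_f = 0.05$ Hz·s$^{-1/2}$ is a convention chosen so that a block's
spectral peak stays within ±0.3 Hz of $f_0$ while the phase decorrelates
over tens of seconds, giving the slow alignment drift the open-loop design
relies on; the amplitude-distribution and drift parameters are conventions,
since no empirical characterisation exists to fit them to.

The stimulation waveform is a sinusoid with no DC offset, 2000 µA
peak-to-peak, a 10 s linear ramp-up, and — in sham blocks — a ramp-down over
the following 10 s, after which the channel is exactly zero. Photic blocks
use a rectangular pulse train (duty ≤ 10%) at the same frequency, with the
train's fundamental phase as the forcing phase and a separate (typically
weaker) coupling gain. A full session is one 360 s stimulation-free initial
recording plus two cycles of six randomly interleaved 180 s blocks; the
caller maps conditions to coupling gains (the default couples only the
right-shoulder montage, κ = 0.1, and photic at 0.05).

What the generator does *not* emulate: biomechanical limb resonance and
multi-component tremor spectra, EMG or movement artifacts, electrode
impedance drift, phosphene-mediated behavioural responses, and any
amplitude-dependence of coupling. Passing tests therefore demonstrate that
the pipeline recovers known coupling from data with this phase/amplitude
structure — not that any particular montage entrains real human tremor.

Under strong coupling ($2\pi\kappa \gg \sigma_\theta^2/2$, e.g. κ = 0.2 at
the default diffusion) the oscillator locks and the raw profile approaches
a spike at the stimulation frequency; the stationary phase spread follows
the usual von Mises balance between pull and diffusion. κ = 0 blocks are
exchangeable with sham, which is what makes the sham-baselined percent
change a valid null.

## The voxel current-density solver

The montage comparison requires only the quasi-static, isotropic Laplace
problem $\nabla\cdot(\sigma\nabla\phi) = 0$. The package solves it by a
finite-volume scheme on the labelled voxel grid itself — a deliberate
methodological simplification relative to tetrahedral FEM on a segmented
scan: for isotropic conductivities on phantom geometries the two agree, and
the voxel scheme is radically simpler and testable against closed forms.

* Tissue conductivities (S/m): skin 0.43, bone 0.0064, gray 0.33, white
  0.142, CSF 1.79, saline 0.367, remaining soft tissue 0.08, air $10^{-4}$.
  Air is a genuine (very poor) conductor rather than an excluded domain, so
  no boundary special-casing is needed; one or two voxels of air padding
  make the exterior effectively insulating.
* Electrode pads (default 50 × 70 mm) sit on a 2 mm saline layer inserted
  over the skin; the pad layer itself is a Dirichlet set held exactly at
  ±1 V.
* Face conductances use the harmonic mean of the two adjacent voxel
  conductivities (exact flux continuity for piecewise-constant σ).
* The SPD system is solved by Jacobi-preconditioned conjugate gradients
  from a deterministic zero start to relative residual $10^{-9}$ (config
  `solver_tol`); non-convergence is an error that reports the residual.
* $E = -\nabla\phi$ by central differences, $J = \sigma E$, and the
  injected current is the conductance-weighted flux out of the source pad.
  Solutions are rescaled to a 1 mA source after the fact; the alternating
  stimulus is treated as an amplitude-scaled steady-state map, and the
  rescaling is defined purely by the computed injected current (the nominal
  load impedance plays no further role).

Validation design: the uniform parallel plate and the two-layer slab have
exact discrete solutions (the scheme reproduces linear and piecewise-linear
potentials at any voxel size), so they check correctness but cannot probe
convergence; grid-refinement is instead tested on a conductivity-graded
plate whose continuous solution is logarithmic, where the discretisation
error is $O(h^2)$ and falls from 4 mm to 2 mm to 1 mm voxels. A two-shell
concentric sphere with small antipodal pads is compared against the
analytic Legendre-series solution (odd harmonics, coefficients solved per
degree in a scaled basis); at 2 mm voxels the potential at half the outer
radius agrees to within a few percent, dominated by the stair-step surface.

## Group statistics

Per-subject percent changes are tested against zero with two-tailed
one-sample t contrasts, reported with Cohen's d because planned contrasts
inflate the type-I risk. Ordinal phosphene ratings use an exact Wilcoxon
signed-rank test: zeros are dropped, midranks handle ties, and for n ≤ 25
the two-sided p comes from the exact null over all $2^n$ sign assignments
(computed by a shift-algorithm convolution, so ties remain exact); beyond
that a tie-corrected normal approximation is used. FDR adjustment is
Benjamini–Hochberg over a user-declared family — which p-values form a
family is an analysis decision the package does not guess; `contrast_table()`
adjusts within the table it is given.

## Problem sizes used by the test suite

The suite validates the pipeline at the protocol's own scale where that is
what the property is about — 180 s blocks at a 256 Hz analysis rate (the
package optionally decimates higher acquisition rates; all validation runs
at 256 Hz), 10 seeds for profile recovery, 20 synthetic subjects for the
end-to-end discrimination, 20 seeds per coupling gain for monotonicity, and
a 54³-voxel sphere at 2 mm for the solver — and at reduced scale (tens of
seconds, coarser voxels) for unit-level properties where duration only adds
variance.

## Known limitations

* The generator is a single phase oscillator; it cannot express
  amplitude-dependent entrainment, harmonic generation, or bimodal tremor.
* `signal::filtfilt`'s simple edge handling makes the zero-phase identity
  hold only away from the block edges; the pipeline's 2 s edge trim is
  calibrated to the 2 Hz passband and should be increased for narrower
  bands.
* The exact signed-rank null is computed to n = 25; larger families fall
  back to the normal approximation.
* The voxel solver is isotropic and quasi-static by design; anisotropic
  white-matter conductivity and capacitive effects are out of scope, and
  head phantoms are idealised ellipsoids, not segmented anatomy — ROI
  contrasts between montages on a phantom are methodological demonstrations,
  not subject-specific predictions.
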