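---
title: "Dose weighting of cryo-EM movies: model, estimation and design notes"
author: "doseweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose weighting of cryo-EM movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseweight)
```

## The damage model

Electron exposure degrades a frozen-hydrated specimen as it is imaged.
Empirically the degradation at a given spatial frequency is well described
by a single-exponential loss of spectral signal-to-noise ratio with
accumulated exposure $N$ (e⁻/Å²):

$$\mathrm{SNR}(k, N) = \mathrm{SNR}(k, 0)\, e^{-N/N_e(k)},$$

where $N_e(k)$ is the *critical exposure* at spatial frequency $k$ (Å⁻¹):
the exposure after which SNR has fallen to $1/e$. Because frame noise is
essentially exposure-independent, signal *amplitudes* decay at half the
log-rate,

$$q(k, N) = e^{-N / 2 N_e(k)},$$

which is the per-frame attenuation factor the exposure filter uses. The
frequency dependence of $N_e$ is captured by an offset power law

$$N_e(k) = a\,k^{b} + c,$$

with package defaults $a = 0.245$, $b = -1.665$, $c = 2.81$ (the published
300 kV calibration; exposures in e⁻/Å²). Two conventions matter and are
deliberate:

* **The independent variable is spatial frequency in Å⁻¹, not resolution
  in Å.** Only this reading produces the strongly resolution-dependent
  curve seen experimentally ($N_e \approx 45$ e⁻/Å² near 22 Å falling to
  $\approx 5$ near 4 Å); with resolution as the variable the curve would be
  nearly flat. All package interfaces take Å⁻¹.
* **Voltage scaling multiplies $N_e$**: 1.0 at 300 kV, 0.75 at 200 kV
  (damage per electron is higher at lower voltage). Other voltages are
  rejected rather than interpolated, because only the 25% figure is
  established; pass a custom `dose_model()` if you have your own
  calibration.

The *optimal exposure* — the exposure that maximizes accumulated signal at
frequency $k$ — is $2.5\,N_e(k)$ (`optimal_ratio`, configurable). Slight
over-exposure costs less than under-exposure, because SNR accrues faster
below the optimum than it decays beyond it.

## The exposure filter

Given aligned frames $F_i(k)$ with accumulated exposures $N_i$, the
per-shell SNR-maximizing (matched-filter) sum is

$$\tilde F(k) = \frac{\sum_i q_i(k) F_i(k)}{\sqrt{\sum_i q_i(k)^2}},
\qquad q_i(k) = q(k, N_i).$$

**Why the square root in the denominator.** With independent unit-variance
frame noise, the numerator's noise variance at $k$ is $\sum_i q_i^2$;
dividing by its square root makes the output noise variance exactly one at
every frequency, so the filter re-weights signal without inflating or
deflating the noise floor — features are altered as little as possible
while SNR is maximized shell by shell. The non-root denominator
$\sum_i q_i^2$ is kept available (`variant = "nosqrt"`); it equals the
large-SNR limit of the Wiener form below and is useful for restoration
comparisons, but it does not preserve the noise floor. This choice is
asserted by a Monte-Carlo test of output noise variance.

Two generalizations are provided: the Wiener-style sum with denominator
$\sum_i q_i^2 + 1/\mathrm{SNR}(k)$ (for a known unattenuated single-frame
SNR; zero SNR is handled as its analytic limit, never as a division by
zero), and the CTF-aware per-voxel combination with numerator
$\sum_i \mathrm{CTF}_i^* q_i F_i$ and denominator
$\sum_i (|\mathrm{CTF}_i| q_i)^2 + 1/\mathrm{SNR}$, a generic weighted
combine rather than a reconstruction engine. With CTF ≡ 1 the chain of
reductions (CTF-aware → Wiener → matched filter) holds numerically and is
tested.

Weights are evaluated per Fourier voxel at the voxel's exact radial
frequency; the DC term, for which the power law is undefined, is assigned
the attenuation of the smallest nonzero frequency present so it is never
up-weighted relative to its neighbours. A per-shell weight table is
available for diagnostics.

The model-predicted SNR of an *unweighted* $n$-frame sum relative to the
filtered sum, $(\sum_i q_i)^2 / (n \sum_i q_i^2)$, equals 1 when all
frames are equally damaged (Cauchy–Schwarz) and drops to ~0.33 at 3 Å for
a 38-frame, 53 e⁻/Å² acquisition — long unweighted exposures mostly add
noise at high resolution.

## Frame alignment

Beam-induced motion is largest in the first frames and settles to a slow
plateau. `align_frames()` estimates one rigid shift per frame by iterating:
each frame is cross-correlated against the sum of all *other* currently
shifted frames (leave-one-out, so a frame cannot "find itself"), shifts are
updated, and after each full pass the X and Y trajectories are centered
(zero mean — the global position is unobservable) and smoothed with a cubic
smoothing spline. Iteration stops when the largest per-frame shift change
falls below `tol` (default 0.1 px) or after `max_iter` (default 20) passes,
in which case a warning flags non-convergence.

Parameter choices, all configurable through `alignment_config()`:

* **Band-pass 1/200–1/8 Å⁻¹ with a 1500 Å² B-factor** on the correlation:
  gradients larger than ~200 Å carry no registration information, and
  frequencies beyond ~8 Å are noise-dominated in single frames; the
  Gaussian B-factor smoothly de-emphasizes the upper band. These are
  common-practice values for this algorithm family.
* **Sub-pixel peaks** by parabolic interpolation over the 3×3 peak
  neighbourhood — accurate to well under 0.1 px on noiseless data and
  cheap. Ties between equal maxima resolve towards the previous iteration's
  shift (zero initially).
* **Spline smoothing** with effective degrees of freedom ≈ `n_frames/4`
  (at least 4): enough flexibility for the fast-early/slow-late shape of
  real drift while suppressing per-frame jitter. Smoothing is applied after
  each full pass over frames. Linear drift passes through the spline
  unchanged.
* **Initial shifts are zero.** First-pass behaviour may therefore differ
  from implementations that seed with progressive pairwise estimates; the
  fixed point reached is the same in our tests.
* Leave-one-out sums are maintained incrementally (total minus current
  frame), which is algebraically identical to explicit recomputation.

Per-particle alignment is the same operation applied to cropped stacks;
there is no separate code path. `apply_and_sum()` re-sums any frame range
with stored shifts (sub-pixel, Fourier phase ramp), and shifts round-trip
through a plain-text file.

## Estimating the critical-exposure curve

The pipeline inverts the damage model from data: exposure-resolved
half-map pairs → FSC per shell (`compute_fsc`) → SNR via
$\mathrm{SNR} = 2\,\mathrm{FSC}/(1-\mathrm{FSC})$ → per-shell regression of
$\ln \mathrm{SNR}$ on $N$, whose slope is $-1/N_e(k)$ → power-law fit of
the per-shell $N_e$. Numerical choices:

* **Noise floor and censoring.** The standard deviation of a pure-noise
  FSC in a shell of $n$ Fourier voxels is taken as $1/\sqrt{n/2}$ (the 2
  accounts for Hermitian symmetry; divide $n$ further by the symmetry
  order for symmetrized maps). Each shell's regression uses the points
  from `start_exposure` up to — not beyond — the first point whose FSC
  falls below `noise_sigma_mult` (default 3) times that floor.
  Truncating at the first crossing rather than dropping below-floor points
  individually matters: pointwise censoring would retain only the upward
  noise fluctuations of the decayed tail and bias slopes shallow.
* **Plain OLS on ln SNR** by default. A variance-weighted variant is
  available (`weighted = TRUE`), but for half-map FSC data the variance of
  ln SNR is nearly constant across the usable range, so OLS is close to
  optimal and simpler to reason about.
* **Shells are dropped, with reasons recorded**, when they have fewer than
  3 usable points or a non-negative slope; `start_exposure` exists to skip
  early frames whose motion has not yet plateaued (in the plateau,
  per-frame motion no longer confounds the damage measurement).
* **Power-law fit**: bounded Levenberg–Marquardt with constraints
  $a > 0$, $b < 0$, $c > 0$, initialized at $c_0 = 0.9\min N_e$,
  $b_0 = -1.5$, and $a_0$ from the highest-frequency shell. $R^2$ is
  reported on the $N_e$ values directly (not log-transformed). In the
  packaged estimator each shell enters with weight $1/\mathrm{se}(N_e)^2$,
  the delta-method variance propagated from its regression slope. This
  matters at desk scale: on 2D maps the low-frequency shells are thin
  rings of a few dozen voxels whose $N_e$ estimates carry ~10% noise, and
  an unweighted fit lets them destabilize the prefactor $a$ badly (tens of
  percent across seeds); inverse-variance weighting is the standard remedy
  for heteroscedastic nonlinear least squares and recovers all three
  constants reliably. `fit_power_law()` itself defaults to unweighted.
* **Frequency band**: shells below 1/22 Å⁻¹ are excluded from the
  power-law fit by default — at very low resolution exposure-resolved FSC
  curves are too noisy to regress usefully (few voxels per shell, and
  long-range contrast changes unrelated to damage). The band is
  configurable, not tied to any particular dataset.

`fit_critical_exposure()` returns a classed fit with `print`, `summary`,
`coef`, `predict` (critical or optimal exposure at any frequency),
`residuals` and `plot` methods, plus a ready-to-use `dose_model` carrying
the fitted constants.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage has a ground-truth test without
any external download. `make_reference()` builds a deterministic, band-rich
test object (Gaussian blobs plus rings) and by default *whitens* its radial
power spectrum: a blob mixture otherwise has a steeply falling spectrum
that starves high-frequency shells of signal, and a flat spectrum lets one
noise level exercise all shells equally. `simulate_movie()` applies, per
frame, the exact per-voxel amplitude decay $q(k, N_i)$, a sub-pixel shift
along a drift path whose speed decays exponentially from `initial_rate`
(default 2 Å/frame) to `plateau_rate` (default 0.2 Å/frame, time constant
16 frames, emulating typical beam-induced motion that settles near frame
28 of a 130-frame movie), and i.i.d. Gaussian pixel noise.
`simulate_half_map_series()` produces two independently noised copies of
the damage-attenuated reference per exposure.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* **Noise is Gaussian and exposure-independent**, matching the measurement
  model (additive noise of constant variance), not Poisson counting
  statistics or detector MTF/DQE effects.
* **Damage is deterministic amplitude attenuation**, not stochastic bond
  breaking; chemically specific decay (carboxyl groups fading before
  aromatics, etc.) is not modelled.
* **No CTF, no gain/defect structure, no magnification distortion, no
  non-rigid (local) motion, no rotations.** Real movies need external CTF
  estimation, and particles additionally rotate slightly (a ~0.02°
  rotation moves a 350 Å-radius surface by ~0.12 Å — negligible for
  translational analysis, which is why rigid translation suffices here).

Study conditions used by the heavier tests (chosen once, as desk-scale
analogues of a real acquisition): the estimation keystone uses 128² maps
and 40 exposure windows of 2.307 e⁻/Å² each (3-frame sums of a 130-frame,
0.769 e⁻/Å²-per-frame movie), half-map noise σ = 0.02 against a
unit-variance whitened reference — low-resolution FSC starts near 1, as in
practice for well-populated reconstructions; the alignment keystone uses a
32-frame, 1.65 e⁻/Å²-per-frame movie (a 53 e⁻/Å² acquisition) at
unit noise. Each completes in seconds.

## Degenerate inputs and edge cases

* `k = 0`: infinite critical exposure; on grids the DC weight is tied to
  the smallest nonzero shell.
* FSC = 1 (self-correlation or noiseless data) maps to infinite SNR with a
  warning; FSC ≤ −1 is a domain error.
* An FSC curve that never crosses the threshold reports the Nyquist
  resolution flagged `crossed = FALSE`.
* A flat SNR series (no decay) drops the shell rather than reporting an
  unstable near-infinite $N_e$; data with no frequency dependence at all
  produce a power-law fit flagged `degenerate`.
* Sub-pixel shifting is exact for band-limited images; content at exactly
  the Nyquist frequency is not representable under fractional shifts and
  is attenuated rather than aliased.
* Exposure bookkeeping: a frame's accumulated exposure refers by default
  to the **end** of the frame (the damage state its signal reflects);
  a mid-frame convention is available. Pre-summed inputs should use the
  sub-sum's mean accumulated exposure.

## Known limitations

Rigid whole-frame (or whole-particle) translation only; no estimation of
the unattenuated per-shell SNR from data (the Wiener variant expects it
from refinement software); no movement-dependent attenuation in the filter
(motion blur is corrected by alignment, not modelled in the weights); MRC
input limited to classic headers, modes 0/1/2/6. The default calibration
constants are printed-precision values; refitting on your own data with
`fit_critical_exposure()` and passing the result as the `dose_model` is
the supported route when they do not apply.
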