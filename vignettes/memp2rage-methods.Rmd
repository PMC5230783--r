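---
title: "Models and methods behind memp2rage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memp2rage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memp2rage)
```

This vignette is the package's own account of the science it implements:
the signal model and its assumptions, the estimation procedures, the
numerical choices made where the design was genuinely open, and what the
synthetic phantom does and does not demonstrate.

## The two-inversion multi-echo signal model

An (ME-)MP2RAGE sequence period consists of an adiabatic inversion pulse
followed by two spoiled gradient-echo (GRE) readout blocks of `n` low-flip
excitations each, separated by idle gaps `T_A`, `T_B`, `T_C`, with the
k-space centre of each block acquired at the inversion times `T_I_1` and
`T_I_2`. Every event acts *affinely* on the longitudinal magnetization:

* inversion: `mz -> (1 - 2*eta) * mz`, with `eta` the inversion efficiency
  defined through the magnetization just before and after the pulse;
* free relaxation over `t`: `mz -> M0 + (mz - M0) * exp(-t/T1)`;
* one readout line: `mz -> mz * cos(alpha) * E1 + M0 * (1 - E1)`,
  `E1 = exp(-T_R_gre/T1)`.

The composition of one full period is therefore `mz -> a*mz + b`, and the
steady state is the fixed point `b / (1 - a)`. `steady_state_mz()` composes
the period symbolically (powers and geometric sums, no iteration);
`block_signals()` propagates the steady state to the k-space centre of each
block and multiplies by the echo-wise factor
`scanner_scale * sin(alpha) * exp(-T_E_i/T2*)`. The model assumes ideal
spoiling (no transverse coherences), mono-exponential recovery and decay,
and no magnetization transfer or water/fat phase modulation — the standard
assumptions at this level of description, and explicitly the regime in
which fat contributes negligibly to brain signal.

Two conventions deserve a note because the printed closed forms in the
literature are ambiguous about them:

* **Inversion factor.** We use `(1 - 2*eta)` throughout, which follows
  directly from the definition of `eta`; at `eta = 1` (the default — the
  adiabatic efficiency is rarely known) it coincides with the `-eta`
  shorthand some papers print.
* **Centre-line bookkeeping.** The k-space centre is the
  `(n_before + 1)`-th excitation, `n_before = round(center_fraction * n)`,
  occurring exactly at `T_I`; the gaps follow from that. Printed
  expressions with `n/2 - 1`-type exponents embed a half-line convention
  that is never stated; rather than guess it, the package treats agreement
  with a brute-force time-stepped Bloch simulation (`bloch_signals()`,
  a literal event loop) as the definition of correctness. Closed form and
  simulation agree to better than `1e-9` relative, and the gaps always
  reconstitute the full period exactly.

`center_fraction` exists because the reference multi-echo protocol's
timing is *infeasible* with a symmetric centre (`n/2` lines before the
centre do not fit into `T_I_1`); with 6/8 partial Fourier along the block
direction the centre sits a third of the way in, which is the bundled
protocol's default (`1/3`).

The bias-cancelling uniform image is
`rho = Re(conj(S1) * S2) / (|S1|^2 + |S2|^2)`, bounded in `[-0.5, 0.5]`.
Scanner gain, `M0` and the echo's `T2*` decay are common factors and cancel
exactly, which is what makes `rho` a pure function of `T1` (and the flip
angles) and hence invertible.

## T1 lookup inversion

`build_rho_lookup()` tabulates `rho(T1)` on a 1 ms grid over
`[0.1, 5] s` by default — far finer than any structure in the curve — and
selects the largest strictly monotonic branch containing 1.6 s, the
midpoint of the expected white/gray-matter range. The anchor matters:
`rho(T1)` is non-monotonic outside a protocol-dependent window, and for
short-`T_R_seq` protocols the window closes near 3 s, so CSF-like voxels
(`T1 ~ 4 s`) are *not invertible*. `invert_rho()` clamps such voxels to the
branch endpoint and flags them in a companion mask instead of dropping
them: that reproduces how those voxels appear in practice (present, but
underestimated) and keeps downstream masks intact. If two equally long
monotonic branches both contained the anchor the builder would refuse;
for strictly monotonic branches this cannot happen.

B1+ sensitivity is analysed at the protocol level
(`b1_sensitivity_curves()`, `b1_t1_error()`), scaling both flip angles by
`1 + offset`: no voxelwise B1+ correction is applied anywhere, matching
the design philosophy of relying on protocol-level insensitivity. The
level of the steady-state magnetization is the dominant driver; protocols
with longer `T_R_seq` are measurably less sensitive (with the bundled
reference protocols, the maximum T1 error over `[1.2, 2.0] s` under a +20%
B1+ offset roughly halves going from `T_R_seq = 5 s` to `8 s`).

## T2* mapping

`fit_t2star()` is the plain unweighted least-squares line through
`log(magnitude)` versus echo time — the simplest reading of "log-linear
polynomial fit". A magnitude-squared-weighted variant is available but off
by default. Degeneracies are masked, never raised: non-positive magnitudes
are excluded echo-wise, fewer than two usable echoes invalidate the voxel,
and a non-negative slope is reported as the `Inf` sentinel and masked.
Magnitude noise is treated as additive Gaussian, consistent with the
Monte-Carlo module and accurate at moderate-to-high SNR; the Rician floor
at low SNR biases log-domain fits and is documented rather than corrected.

## The susceptibility pipeline

The QSM chain is deliberately the simplest spectral pipeline that is
exact on its own forward model:

1. **Laplacian unwrapping** solves
   `lap(phi) = cos(phi)*lap(sin phi) - sin(phi)*lap(cos phi)` by FFT,
   dividing by `-|k|^2` with the zero frequency pinned to 0. The output
   equals the true phase up to a harmonic component, which the next step
   removes anyway.
2. **SHARP** exploits the spherical-mean-value property of harmonic
   fields: convolution with (delta − sphere-mean kernel) annihilates any
   field whose sources lie outside the brain, the filter is deconvolved
   with truncation, and the result lives on the mask eroded by the kernel
   radius.
3. **ppb conversion** divides by `1e-9 * gamma * T_E * B0`
   (gamma `2.675e8 rad/s/T`, `B0 = 7 T` by default; at the 14.77 ms echo
   one ppb is about 0.0277 rad).
4. **Thresholded dipole inversion** divides by the unit dipole kernel
   `D = 1/3 - kz^2/|k|^2` where `|D| >= kthresh` and by
   `sign(D) * kthresh` inside the ill-conditioned cone — the standard
   thresholded-k-space-division rule, which bounds noise amplification at
   `1/kthresh` while retaining cone content. `D(0) = 0` makes the
   susceptibility offset unidentifiable, so maps are re-referenced to zero
   mask mean; all susceptibility values are relative.

Voxel anisotropy is honoured by building `|k|^2` from physical
frequencies, so anisotropic grids work unchanged.

**Parameter defaults.** `kthresh = 0.2` is the conventional inversion
threshold. For SHARP we ship `radius = 3 mm`, `threshold = 0.02`. The
radius must be large enough to average over several voxels (at 0.6 mm, a
3 mm sphere spans five) but every millimetre of radius costs a millimetre
of eroded brain; the deconvolution threshold controls how much
low-spatial-frequency content of *internal* sources survives. On the
package's own zero-noise 64-cube round trip (forward field, wrap, unwrap,
SHARP, inversion, Gaussian-blob susceptibility), 3 mm / 0.02 yields a
regression slope near 0.80 with r-squared above 0.9, whereas 4 mm / 0.05
truncates enough low-frequency content to pull the slope to ~0.70 — that
measurement is why the smaller radius and threshold are the defaults.
The residual slope deficit (~0.8 rather than 1.0) is the known systematic
contrast underestimation of thresholded dipole inversion; no attempt is
made to correct it. All three parameters are exposed in every entry point.

## Monte-Carlo precision analysis

`run_t1_mc()` / `run_t2star_mc()` replay the classic estimator-precision
design: for `n_values` true relaxation times in a range, synthesize the
noise-free signals, add Gaussian noise of SD
`(maximum noise-free signal over the range) / SNR` — one normalization for
both inversion images, so SNR 25/50/100 mean the same thing across
protocols — and summarize the per-value SD of the estimates (`sigma_T`),
plus its mean and population SD over the range (`mc_summary()`).

The T1 default estimator is the two-parameter magnitude fit (scale
profiled out analytically over a dense T1 grid), which discards the sign
of the first-inversion signal and is therefore a *lower bound* on the
accuracy of the complex uniform-image route; the `t1_rho_lookup` variant
adds noise to the signed signals and runs the production lookup chain, and
quantifies how much the complex combination buys. For the T2* case the
log-linear fit's precision agrees with first-order error propagation
through the unweighted regression (the package tests this at SNR 50 within
±15%); the familiar design rule that the echo train should straddle the
T2* of interest (`T_E_1 < T2* < T_E_max`) falls out of the same
simulations.

Replicate counts: the test and acceptance suites run `N = 2000`
replicates per value (and 10–30 values per sweep), a size chosen so each
sweep completes in seconds while keeping the Monte-Carlo standard error of
`sigma_T` near 1.6%; `N` is configurable up to 20000 for
publication-grade curves. All randomness flows from the config seed and
results are bitwise reproducible.

## The digital phantom and what it shows

`make_phantom()` builds a deterministic nested-ellipsoid "brain": a
cortical gray-matter shell around white matter, a central CSF core, and
bilateral putamen, caudate and thalamus. Class values are 7 T ROI
literature values (WM `T1 = 1219 ms`, `T2* = 25.85 ms`, `chi = 7.0 ppb`;
caudate `chi = 26.3 ppb`, the strongest paramagnetic contrast). CSF is
assigned `T1 = 4.3 s` — deliberately beyond the short-window protocols'
invertible range, to exercise the clamping path — and a field-typical
`T2*` of 100 ms; per-class proton densities are synthetic
(0.75/0.85/1.0). `simulate_acquisition()` composes the closed-form block
signals (with a per-voxel B1+ multiplier) with the forward dipole field of
the susceptibility truth, wraps the accrued phase, and adds independent
complex Gaussian noise.

What passing phantom tests demonstrate: internal consistency of the whole
chain — model, lookup, fits and spectral operators invert each other at
the stated tolerances, with realistic tissue values, geometry-induced
dipole fields, wrap-around phase and complex noise. What they do not
demonstrate: robustness to everything the phantom does not contain —
k-space undersampling and reconstruction artifacts, coil-combination pole
artifacts, motion and physiological noise, multi-compartment relaxation,
background fields beyond the optional smooth polynomial, and anatomically
realistic texture. Claims about real scanner data rest on the published
in-vivo literature, not on these tests.

## Agreement statistics

`diff_stats()` implements the voxel-by-voxel accuracy/precision summaries
with `D = reference - test`: `mu_D`, population-SD `sigma_D`, `mu_|D|`,
and `r2` (squared Pearson). One subtlety is preserved on purpose: the
printed definition of the SD of `|D|` centres `|D|` on `mu_D` rather than
on `mu_|D|`. Whether that centring is intended or a typographical slip is
undecidable from the text, so the printed form is the default output
(`sigma_absD`) and the conventional form is returned alongside
(`sigma_absD_centered`); on the two-voxel example `x = (0,0)`,
`y = (1,-1)` they are 1 and 0 respectively, which pins down exactly which
is which. Mis-registration sweeps (`apply_rigid()`, axial rotations about
the FOV centre and axial sub-voxel translations, trilinear resampling with
out-of-volume voxels invalidated) and QSM noise sweeps reproduce the
qualitative sensitivity ordering — finely textured T2*-like maps lose
correlation much faster than smooth T1-like maps for the same sub-voxel
offset. Recovering an unknown transform (registration proper) is out of
scope; only known transforms are applied.

## Numerical choices, in one place

* Lookup grid 1 ms over `[0.1, 5] s`; inversion by linear interpolation of
  the monotone branch; round-trip error is bounded by one grid step.
* Geometric sums `1 + c + ... + c^(k-1)` switch to the exact limit `k`
  when `|1 - c| < 1e-12` to avoid 0/0 at `cos(alpha) * E1 -> 1`.
* A period map with `|a| >= 1` (non-contractive, unphysical) is an error,
  not a warning.
* Flip angles are scaled by `flip_accuracy` before *any* signal
  computation; rounding to integer degrees (a console constraint) happens
  only on protocol export.
* T2* fits flag slopes above `-1e-9 1/s` (T2* beyond 1e9 s) as "no decay"
  so that float-noise-flat voxels mask cleanly.
* Spectral operators pin the zero-frequency coefficient to 0 wherever a
  division would be singular (Poisson solve, dipole kernel).
* Histograms default to 128 bins over each map's central 99% range.
* Phase is always stored wrapped to `(-pi, pi]`; complex volumes are
  written as magnitude/phase NIfTI pairs (the scanner convention), with
  units and provenance in a JSON sidecar (the NIfTI-1 description field
  holds only 80 bytes).

## Known limitations

* Total acquisition times require the outer-loop step count (oversampling
  and partial-Fourier bookkeeping of the second phase-encoding direction),
  which is acquisition software territory; `total_time()` therefore takes
  `n_outer` explicitly rather than guessing.
* The thresholded dipole inversion underestimates contrast by design
  (slope ~0.8 at `kthresh = 0.2`); nonlinear or regularized inversions are
  out of scope.
* Gaussian (not Rician) magnitude noise biases T2* estimates at low SNR.
* The magnitude-fit T1 estimator is unstable near the first-inversion
  zero crossing; its bias there is inherent to discarding phase, which is
  the very point the complex route makes.
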