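# memp2rage

Quantitative brain MRI with the multi-echo MP2RAGE (ME-MP2RAGE) sequence:
simultaneous mapping of the longitudinal relaxation time T1, the effective
transverse relaxation time T2\*, and the magnetic susceptibility χ from a
single two-inversion multi-echo gradient-echo acquisition — plus everything
needed to study such a protocol at the desk, without scanner data: a
closed-form signal model with a brute-force Bloch cross-check, Monte-Carlo
precision analysis, a digital brain phantom, and voxel-by-voxel
test-retest statistics.

The package is aimed at quantitative-MRI methodologists and sequence
developers who want to (a) choose ME-MP2RAGE acquisition parameters with
quantified B1+ sensitivity and estimator precision, and (b) run the full
T1/T2\*/χ reconstruction chain on synthetic or exported scanner volumes
(NIfTI-1).

## The models

**Signal model.** One sequence period — inversion, gap `T_A`, a GRE block
of `n` excitations with flip angle α₁, gap `T_B`, a second block with α₂,
gap `T_C` — acts affinely on the longitudinal magnetization, so the steady
state is the fixed point of the period map, `Mz,ss = b/(1−a)`. The two
block signals at echo time `TE_i` carry a common factor
`ξ · M0 · sin α · exp(−TE_i/T2*)` and combine into the bias-free uniform
image

    ρ = Re(S₁* · S₂) / (|S₁|² + |S₂|²)  ∈ [−0.5, 0.5],

in which scanner gain, proton density and T2\* decay cancel, leaving a
function of T1 alone that is tabulated and inverted on its monotonic
branch (`build_rho_lookup()`, `invert_rho()`).

**T2\*** comes from unweighted least squares of `log|S|` against echo time
(slope `−1/T2*`), voxelwise over the second-inversion echoes.

**χ** comes from the phase of the longest echo through a spectral chain:
Laplacian (Fourier) unwrapping → SHARP spherical-mean background removal →
conversion to ppb (`φ / (10⁻⁹ γ TE B₀)`) → thresholded dipole inversion
with the unit kernel `D(k) = 1/3 − k_z²/|k|²`, re-referenced to zero mask
mean.

## Worked example

Simulate a 64³ digital brain phantom at image SNR ≈ 50 with the bundled
0.6 mm 7 T multi-echo protocol, reconstruct all three maps, and compare
the T1 map with the ground truth:

```r
library(memp2rage)

p <- me_mp2rage_protocol()
p
#> <mri_protocol: me_mp2rage>
#>   T_R_seq 6 s | T_I 0.75/2.9 s | alpha 4/6 deg | n 114
#>   T_R_gre 0.0181 s | 4 echo(es):  2.35,  6.49, 10.63, 14.77 ms

lut <- build_rho_lookup(p)
lut
#> <rho_lookup: 4901 points, invertible T1 range [0.116, 5.000] s, rho decreasing>

ph    <- make_phantom(phantom_spec(shape = c(64, 64, 64)))
clean <- simulate_acquisition(ph, p, noise_sd = 0)
snr50 <- max(Mod(clean$inv2[seq_len(64^3)])) / 50
acq   <- simulate_acquisition(ph, p, noise_sd = snr50, seed = 7)
maps  <- recover_maps(acq, lut = lut)

roi_stats(maps$t1 * 1e3, ph$labels, c("wm", "gm", "caudate"))
#>     label     n     mean       sd
#> 1      wm 40498 1219.967 48.47488
#> 2      gm 43296 1802.290 73.76142
#> 3 caudate   240 1437.548 53.33003

diff_stats(maps$t1, ph$truth$T1, mask = ph$mask & ph$truth$T1 < 3)
#> <diff_stats (N = 84848): mu_D = -0.0006274, sigma_D = 0.06282, mu_|D| = 0.04917, sigma_|D| = 0.06332, r2 = 0.9551>
```

The ROI means land on the tissue ground truth (WM 1219 ms, GM 1802 ms,
caudate 1441 ms) within a few milliseconds; the agreement statistics show
an essentially unbiased T1 map (`mu_D ≈ −0.6 ms`) with a noise-driven
spread of ~63 ms and r² ≈ 0.96 against the truth. `maps$t2star` and
`maps$chi` hold the simultaneously recovered T2\* and susceptibility maps;
`maps$t1_clamped` flags voxels (CSF, here) whose ρ fell outside the
protocol's invertible branch.

A thin command-line front end wraps the same functions for shell use
(`simulate`, `signal`, `map-t1`, `map-t2star`, `map-qsm`, `mc`, `compare`,
`config`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "memp2rage.R", package = "memp2rage"))') \
    signal --protocol proto.yaml --t1 0.5,3.5,0.01 --out rho_table.csv
```

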