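---
title: "cestph: models, parameters and design choices"
author: "cestph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cestph: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cestph)
```

This vignette is the package's own account of its science: the forward
models, the learning problem, every tunable parameter that matters (with
units and defaults), the numerical choices, and the limits of what a green
test establishes.

## 1. The problem

Intracellular pH (pHi) in brain tissue is measured by ³¹P-MRS through the
chemical-shift distance δ between inorganic phosphate (Pi) and
phosphocreatine (PCr), converted by the modified Henderson–Hasselbalch
equation

$$\mathrm{pH} = pK_a + \log_{10}\frac{\delta - \delta_{HA}}{\delta_A - \delta},$$

with the brain calibration $pK_a = 6.77$, $\delta_{HA} = 3.29$ ppm
(H₂PO₄⁻ limit) and $\delta_A = 5.68$ ppm (HPO₄ limit). ³¹P voxels are
30 × 30 × 25 mm³; CEST voxels are 3 × 3 × 4 mm³ — a factor of 625 in
volume. Amide-proton CEST is pH-sensitive because amide exchange is
base-catalyzed, but no closed-form map from a Z-spectrum to pHi exists at
3 T in vivo. The package's central object is therefore a small
probabilistic regression network trained voxel-wise to predict
³¹P-calibrated pHi (with uncertainty) from CEST + T1 features, plus the
synthetic world needed to exercise it end to end.

## 2. Forward physics

### 2.1 Bloch-McConnell simulator

`simulateZspectrum()` propagates the coupled magnetization of water plus up
to three exchange pools through the literal saturation train: rectangular
pulses of duration $t_p$ at amplitude $B_1$, separated by gaps $t_d$,
using the matrix exponential of the augmented Bloch-McConnell generator for
each piecewise-constant segment. Transverse magnetization is zeroed in the
gaps (crusher-gradient spoiling). The readout is the longitudinal water
magnetization after the last pulse, normalized to equilibrium.

Fixed constants: $\omega_1 = 2\pi\,\gamma B_1$ with
$\gamma = 42.577$ MHz/T; offsets convert as
$1\,\mathrm{ppm} = 2\pi\,\gamma B_0$ rad/s at $B_0 = 3$ T.

Key defaults (all configurable):

| parameter | default | unit | why |
|---|---|---|---|
| schedule preset | ±8 ppm @ 0.5, ±(3–4) @ 0.1, B₁ = 1 μT, t_p = t_d = 250 ms, 10 startup pulses | — | the emulated 3 T protocol |
| amide pool | +3.5 ppm, fraction 9·10⁻⁴, R₂ = 30 s⁻¹ | — | ~70 mM backbone amides vs 111 M water protons |
| exchange law | k(pH) = 30 · 10^(pH−7.0) | s⁻¹ | base-catalyzed; 30 s⁻¹ is the magnitude of published amide rates; no in vivo calibration exists for the emulated protocol, so this is a package default |
| MT pool | −2.4 ppm, fraction 0.02–0.10 by class, R₂ = 1.1·10⁵ s⁻¹, k = 40 s⁻¹ | — | semisolid pool; super-Lorentzian lineshape approximated by a very short-T₂ Lorentzian |
| NOE pool | −3.5 ppm, fraction 1–3·10⁻³, R₂ = 40 s⁻¹, k = 16 s⁻¹ | — | aliphatic rNOE baseline |

The offset schedule reconstructed from the stated increments has **49**
unique offsets; the protocol text elsewhere quotes 51. We use the 49-offset
reconstruction (feature dimension 49 + 11 + 1 = 61) and leave the
discrepancy documented rather than resolved; the schedule is configurable.

**Coherent nutation sidebands.** A 250 ms rectangular pulse leaves ripples
of period $2\pi/t_p \approx 0.03$ ppm in the post-pulse longitudinal
magnetization. These are genuine for a perfectly homogeneous voxel but are
washed out in vivo by intravoxel B0 spread. `intravoxelSd` (ppm) averages Z
over a Gaussian offset distribution with 21-point Gauss-Hermite quadrature
and suppresses the ripples by >10³; the default is 0, and the phantom
renderer instead works on the smooth spline envelope of a densely sampled
spectrum (section 3). The continuous-wave method (`method = "cw"`,
duty-cycle-scaled B₁) is a faster smooth approximation, accurate away from
strong saturation; it is also what the B0-roundtrip accuracy check uses,
because no coarsely sampled interpolation can track sub-0.03-ppm ripples.

### 2.2 T1 and ³¹P models

The VFA module uses the ideal-spoiling SPGR equation
$S = M_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR/T_1}$, and
the standard two-point linearization (slope = $E_1$); published
insufficient-spoiling corrections are *not* reimplemented — their
coefficients live in external work, and the phantom generates data under
the same ideal model, so the omission is self-consistent (and documented as
a limitation for real data). Voxels with non-physical slopes are masked,
never inverted to negative T1.

The ³¹P module synthesizes two Lorentzians (PCr at 0 ppm, Pi at
`phToShift(pH)`) and fits them by nonlinear least squares with a constant
baseline, replacing prior-knowledge time-domain fitting: only the Pi–PCr
distance feeds downstream, and the simplified fit recovers it to 1e-4 ppm
noiselessly and with |pH bias| < 0.005 at SNR ≥ 50. The conversion errors
outside the open interval (δ_HA, δ_A) rather than returning ±∞, and the
supported pH range is clamped to [6.0, 7.8].

## 3. The synthetic world

`buildPhantom()` labels an ellipsoidal brain (WM core, GM shell, two CSF
ventricles) with one spheroidal tumor (rim + necrotic core) in one
hemisphere, on a 64 × 64 × 20 grid of 3 × 3 × 4 mm voxels (25,232 masked
voxels at defaults — the mask is the eroded brain minus CSF).

Stated-world defaults, chosen once:

* per-class pH: WM 7.00, GM 7.03, tumor rim 7.15, necrotic core 7.25
  (inside the physiological 7–7.2 band, tumor elevated; per-class values
  are package defaults, not measured quantities);
* within-class pH variation: Gaussian random field, sd 0.02, correlation
  ~2 voxels;
* relaxation at 3 T: T1 = 1.1/1.6/4.3/1.8/2.2 s and T2 = 70/90/1500/110/250
  ms for WM/GM/CSF/rim/core — literature-typical;
* ΔB0: smooth random quadratic, max |ΔB0| = 0.3 ppm in-brain;
* CEST noise: Gaussian, sd 0.005 on the normalized Z scale;
* ³¹P target noise: Gaussian, sd **0.01 pH** per coarse voxel. This is the
  realistic precision of 10-fold-averaged in vivo ³¹P-MRS; it was fixed
  before any end-to-end run and matters for interpretation (section 6);
* ³¹P PSF: Gaussian with FWHM equal to the 30 × 30 × 25 mm pitch,
  emulating zero-filled-CSI leakage ("box" = plain volume average is the
  alternative); CSI k-space itself is not synthesized — partial volume and
  leakage are the target-data limitations that matter here.

`renderCest()` simulates one spectrum per (class, pH-bin) — pH quantized at
0.005, which perturbs Z by < 2·10⁻⁴ — on a densified offset grid, and
evaluates each voxel's ΔB0-shifted offsets with a monotone cubic spline of
that cached curve. The per-voxel exact path (`exact = TRUE`) agrees with
the cache to ~10⁻² in Z away from water (the residue is dominated by the
sideband aliasing of section 2.1) and is hundreds of times slower; the
cache *is* the rendered world, and the processing chain is self-consistent
on it.

## 4. Processing and learning

Raw volumes are normalized by M0 (voxels below 10⁻⁹ of the M0 maximum are
masked), re-centred per voxel by monotone cubic interpolation at
`offsets − ΔB0` (the WASSR-style correction; edge offsets that would
extrapolate are nearest-filled and flagged), and summarized as
MTRasym/MTRrex/AREX. The MTRrex reference is the opposite-side Z value
(asymmetry-based), not a Lorentzian-fit reference — the asymmetry
reference keeps the module self-contained and matches the
MTRasym-centric pipeline; a Lorentzian reference is a possible extension, not
implemented. `z_floor = 0.05` guards the 1/Z terms; floored voxels are
reported, not silently dropped.

Features per masked voxel: 49 Z values, 11 MTRasym values (3.0…4.0 ppm),
one qT1 value — qT1 is treated as one more standardized dimension rather
than being scaled separately. Targets are the coarse ³¹P pH
values pasted onto the CEST grid by nearest-neighbour containment,
mirroring the reslicing of measured maps.

Training follows the published recipe exactly: 10-20-10 ReLU layers, a
probabilistic head (linear mean; variance through a softplus map plus a
10⁻⁶ floor — a positive map avoids invalid variances), Gaussian negative
log-likelihood `0.5·(log σ² + (y−μ)²/σ²)`, Adam (lr 0.001, β = 0.9/0.999),
batch 256, 80/20 voxel-wise random split, 1000 epochs by default with no
early stopping (best-validation checkpointing is opt-in). Standardization
statistics come from the training split only and are frozen into the model
— computing them on all data would leak the validation split.
Initialization, shuffling and the split all derive from one seed; two runs
with the same seed are bitwise identical. The once-tried 64-128-256-512
architecture is reproducible via `netConfig(hidden = …)` but overfits and
is not the default.

## 5. Evaluation

`downsampleToTarget()` shares its separable PSF machinery with the
phantom's ³¹P renderer (bit-identical by construction); coarse voxels with
under 50% in-mask support are excluded (the stand-in for eroding
skull-adjacent ³¹P outliers). SSIM uses a Gaussian window (sd 1.5 voxels),
K₁ = 0.01/K₂ = 0.03, the reference map's range as dynamic range, windows
renormalized over in-mask voxels, computed per axial slice and averaged
(3D windows behind a flag). R² is reported as the squared Pearson r of the
scatter — matching the paired r/R² convention — rather than
1 − SSres/SStot about the identity line. Bland–Altman uses the n−1 sd and
±1.96 sd limits. The metric ladder downsamples every map to the ³¹P grid,
z-scores it over the shared coarse mask (making the ranking invariant to
affine rescaling) and correlates with the coarse truth.

## 6. What the green tests do and do not establish

At the defaults (seed 1, 400 of the 200–1000 epoch band — a runtime
scaling, not a tuning): held-out RMSE 0.0141 pH, 1σ coverage 0.705,
ladder order prediction > AREX > MTRasym > MTRrex > qT1, T1-attack median
|ΔpH| 0.0031 < median σ 0.0101 with zero change outside the ROI, and
preserved tumor contrast (predicted rim 7.054 vs WM 7.012).

Two honest caveats.

**The held-out Pearson r is structurally capped near 0.55, not 0.7+.**
The coarse targets vary for two reasons: tissue differences (which voxel
features carry) and partial-volume mixing that depends on *where* a voxel
sits inside its 625-fold-larger ³¹P cell (which no voxel-wise feature can
carry). An oracle predictor given the true class and fine pH of every voxel
— the information ceiling for any voxel-wise model, with noise-free
features — reaches r = 0.54 on this world; the trained network reaches
r ≈ 0.51, i.e. ~95% of the ceiling, and the RMSE sits at the same 0.014
floor as the oracle. Patient cohorts, with many heterogeneous tumors each
spanning several coarse cells, have a larger feature-predictable share of
target variance; cohort-level correlations are therefore not reproduced
here and are not asserted.

**The synthetic world is easier than real data.** One scanner "session",
exact class-piecewise relaxation, no motion, no B1 inhomogeneity of the
saturation train, Gaussian noise (no Rician floor at this SNR, hence the
omission), ideal spoiling, and targets generated by the same PSF model used
in evaluation. A green suite establishes internal correctness and the
stated synthetic-analog properties — not clinical performance.

## 7. Numerical choices and degenerate inputs

* Matrix exponentials via `Matrix::expm`; Z clamped to [0, 1] against
  1-ulp excursions.
* Monotone cubic (Fritsch–Carlson) interpolation for all Z re-gridding:
  no overshoot on saturation dips; linear interpolation for Z at unsampled
  ±Δω inside the densely sampled APT band, where higher order is
  immaterial.
* The ΔB0 sign convention: a voxel whose water minimum appears at +δb0 on
  the nominal axis is corrected by evaluating its measured spectrum at
  x + δb0; the simulator's `zspectrumWithB0Shift(db0)` and the corrector
  are exact inverses of each other by this convention (verified to 1e-3 in
  the roundtrip test on smooth spectra).
* Zero-variance feature columns are pinned to sd 1 with a warning;
  m0 = 0, slope ≥ 1 (VFA), Z below the spillover floor, T1 ≤ 0 and empty
  coarse cells are all masked, never propagated as Inf/NaN.
* `nls`'s port algorithm flags perfect (zero-residual) Lorentzian fits as
  "singular convergence"; the fit is accepted on its residual norm, and a
  genuine failure (single peak, separation below one linewidth) raises a
  diagnostic error.

## 8. Known limitations

No super-Lorentzian MT integral, no B1 map estimation (b1Scale is an
input), no WASSR acquisition simulation (ΔB0 maps are consumed, not
estimated), no Lorentzian multi-pool fitting, no spatial/convolutional
models, no transfer to scanner data, no DICOM. The CLI covers the pipeline
verbs; anything finer-grained is the R API.
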