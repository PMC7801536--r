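---
title: "From dynamic PET-CT to EQDX(α/β): models and numerical choices"
author: "tatdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dynamic PET-CT to EQDX(α/β): models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatdose)
```

`tatdose` computes per-voxel absorbed dose and equieffective dose maps
for targeted radionuclide therapy from a CT volume and a dynamic PET
series. This vignette is the package's account of the science: the
models, their assumptions, the tunable parameters, and the numerical and
design choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Why equieffective dose

For an α emitter such as ²¹¹At the absorbed dose (Gy) is a poor
predictor of biological effect on its own: densely ionizing α tracks
kill cells far more efficiently per Gy than the X-rays behind the
clinical dose-response archive, the effectiveness itself depends on
dose, the exposure is protracted over the effective decay of the
radiopharmaceutical, and the dose inside any organ or tumor is strongly
heterogeneous. The equieffective dose EQDX(α/β) — the total dose of a
reference treatment in fractions of size X producing the same surviving
fraction — expresses all of this on the scale radiation oncology already
uses. With the defaults X = 2 Gy and α/β = 0.251/0.0615 ≈ 4.08 Gy the
package's maps are EQD2(4.08); X → 0 gives the biologically effective
dose as a special case.

## The model chain

**Surviving fraction.** The microdosimetric kinetic model (MKM) with
saturation and dose-rate corrections:

$$ S(D) = \exp\!\big[ -(\alpha_0 + \beta z^{*}_{1D})\,D - G\,\beta D^2 \big],
\qquad \mathrm{EQDX} = \frac{-\ln S}{\alpha + \beta X}. $$

`alpha0` is not a free input: it is derived as
$\alpha_0 = \alpha - \beta z^{*}_{1D,\mathrm{ref}}$ from the LQ
parameters of the reference radiation, so that reference-quality
radiation at an acute fraction of size X maps to EQDX = X exactly (the
suite checks this to 1e-9). The user-facing parameters are those a
radiobiology lab can actually measure: α (Gy⁻¹), β (Gy⁻²), the recovery
rate μ (h⁻¹), and X (Gy). Defaults (α = 0.251, β = 0.0615, μ = 1.5,
X = 2) are the HSG-cell values widely used with the MKM.

**Microdosimetry.** The radiation-quality input is the saturation-
corrected dose-mean specific energy of a spherical domain of radius
`r_d` = 0.282 µm,

$$ z^{*}_{1D} = \frac{y^{*}}{\pi r_d^{2}}, \qquad
   y^{*} = y_0^{2}\!\int \frac{1 - e^{-y^{2}/y_0^{2}}}{y}\, d(y)\,\mathrm{d}y, $$

with the saturation parameter `y0` = 93.4 keV/µm discounting lineal
energies in the overkill regime. Both values, like α and β, are
cell-line properties; they are exposed through `domain_geometry()` and
the JSON parameter file. `z*_1D` is linear in the dose density d(y), so
the per-voxel spectrum mixture
$d(y) = (D_\alpha d_\alpha + D_\beta d_\beta)/(D_\alpha+D_\beta)$
reduces to a dose-weighted mean of the two component `z*_1D` values —
the per-voxel EQDX map needs only two scalars per nuclide.

**Spectra.** `compute_dose_pd()` estimates d(y) by Monte Carlo with a
*segment-LET × chord-length* site model: an emission line is drawn with
probability ∝ yield × energy, a point on the slowing-down track is drawn
uniformly in deposited energy, the local LET (embedded water
stopping-power tables, log-log interpolation) is multiplied by an
isotropic chord of the sphere, capped by the residual energy, and tallied
with dose weight. Lineal energy uses the ICRU convention ε divided by the
mean chord 4r_d/3. Photon lines enter through sampled secondary
electrons (Klein–Nishina Compton electrons, photoelectrons at low
energy); β spectra are sampled from an approximate allowed shape with the
tabulated endpoint. This deliberately replaces a track-structure-fitted
microdosimetric function: there is no δ-ray escape or energy-dispersion
broadening here. The spectra are therefore approximate in shape; what the
package relies on — and what the acceptance script recomputes — are the
saturation-integrated summaries, which are far less sensitive to the
fine shape than the spectra themselves. The y grid default is 250
log-spaced bins on [0.01, 1000] keV/µm; the lower edge sits well below
0.1 because the chord-LET model puts real dose weight there for fast
electrons.

**Reference radiation.** The model needs `z*_1D,ref` for the radiation
that produced the α and β inputs. Clinical reference data are hard-photon
beams, whose secondary electrons are a few hundred keV, so the package's
default reference spectrum is monoenergetic 300 keV electrons in the same
domain (`reference_z_star()`, deterministic default seed). With the
default geometry this evaluates to ≈1.0 Gy, giving α₀ ≈ 0.19 Gy⁻¹. The
choice matters most for the low-LET (¹⁸F) end: the low-dose EQD2/dose
ratio moves by roughly β/(α+βX) ≈ 0.16 per Gy of `z*_ref` shift, which
is why `z_star_ref` is exposed as a direct input for anyone with a
better-characterized reference beam.

**Dose rate.** Dose rates are assumed to decay mono-exponentially with
the voxel's own fitted λ_phy + λ_bio, giving the Lea–Catcheside-type
factor G = (λ_phy+λ_bio)/(μ+λ_phy+λ_bio) on the quadratic term. μ = 0
(no recovery) and instantaneous delivery both give G = 1. Cross-voxel
smoothing of decay constants is deliberately *not* applied: α self-dose
dominates in TAT, and a smoothed λ field would silently couple voxels.

**VOI aggregation.** Because EQDX is nonlinear in S, organ values use the
mass-weighted mean surviving fraction S_VOI = ΣS_i m_i / Σm_i supplied to
the EQDX formula (equivalent-uniform-dose logic), alongside dose-mass
histograms. Voxels below the dose floor (default 1e-9 Gy) contribute
survival exactly 1 — a cold subvolume legitimately dominates S_VOI; the
floor only zeroes the per-voxel EQDX map. Two consequences the suite
verifies: heterogeneity can only lower the VOI EQDX relative to the
uniform field at the same mass-weighted mean dose, and switching off the
dose-rate correction can only raise it.

## Kinetics

Frame activities are assumed decay-uncorrected, so the mono-exponential
fit A(t) = A₀e^(−λ_eff t) estimates λ_eff = λ_phy + λ_bio directly; a
`decay_corrected` flag restores the physical decay first, since vendors
differ. Frame midpoints are the time coordinate. The cumulated activity
is Ã = A₀/λ_eff, i.e. the fitted exponential is its own tail model.
Single-curve fits use Levenberg–Marquardt (`minpack.lm`) from a
log-linear start — deterministic, no random restarts; the voxelwise map
uses a vectorized Gauss–Newton solver with the same model and bounds
(one LM call per voxel would dominate the runtime), and the suite pins
the two to each other. λ_eff is bounded below at 0.1 λ_phy (λ_bio ≥
−0.9 λ_phy covers tracer accumulation, flagged) and above at 50 h⁻¹, far
beyond any tracer clearance. Voxels whose peak is below 1e-4 of the
volume maximum, whose fit fails, or whose fitted intercept extrapolates
beyond 10× the observed peak (sparse Poisson spikes can do this) fall
back to trapezoidal integration with a physical-decay tail and are
flagged per voxel.

## Phantom and dose engine

CT numbers map to density through a continuous, monotone piecewise-linear
correlation in the spirit of stoichiometric (Schneider-type)
calibrations: linear air→water below 0 HU, a soft-tissue/bone ramp to
1600 HU, a flatter mineral segment above; out-of-range HU clamps with a
counter. A coarse configurable bin table (air/lung/soft tissue/bone)
classifies materials. Voxel mass is exactly density × volume — the mass
bookkeeping that Eq-6-style aggregation and DMHs rest on.

The transport model is deliberately simple and fully auditable:

- **α and electrons deposit locally.** α ranges (tens of µm) and the β
  ranges of these nuclides (≲2 mm) are below typical PET-CT voxels; an
  optional Gaussian β-range blur is available but off by default.
- **Photons spread by a point kernel**: exp(−µρr)·(1+k·µρr)/(4πr²),
  normalized analytically so an infinite medium absorbs exactly the
  emitted energy; FFT convolution on a uniform medium at the phantom's
  mass-weighted mean density, with per-voxel mass division at deposit
  time. Escape from the finite grid is reported from the energy balance.
- **The buildup coefficients k(E)** were fitted once against the
  package's analog Monte Carlo oracle in uniform water and embedded
  (10/4.25/2.25/1.75/1.25 at 0.08/0.208/0.364/0.511/0.898 MeV). At
  0.511 MeV the kernel tracks the oracle within ~9% voxelwise where the
  oracle is statistically solid; at the two softest lines the
  linear-buildup form cannot do better than ~25% near the source — an
  accepted limitation, since those lines carry a small fraction of the
  β-component energy for the supported nuclides.
- **The MC oracle** (`mc_oracle()`) is an independent check, not the
  engine: Woodcock tracking through the heterogeneous density grid,
  photoelectric/incoherent split from embedded water coefficients,
  Klein–Nishina electron sampling with kinematically consistent
  scattering angles, batch-based uncertainties. Photon coefficients are
  water-composition for all tissues (density differences only); bone
  photoabsorption below ~100 keV is therefore underestimated.

Decay data are compact per-decay inventories (¹⁸F, ²¹¹At with its
Po-211/Bi-207 branches, ¹³¹I, ¹⁷⁷Lu) compiled from published
ICRP-107-style tables into a human-readable JSON file; photons and all
electrons tally into the β dose component, α lines into the α component.
Daughters with half-life beyond 24 h (Bi-207, Xe-131m) are truncated by
default — negligible dose on treatment timescales — and reported, since
the appropriate policy is a clinical judgment, not a physics one.

## The synthetic study generator

`phantom_spec()` emulates what the pipeline actually consumes: a torso
CT (body, two −700 HU lungs, kidneys, bladder, tumor as ellipsoids of
known HU), organ-wise mono-exponential kinetics with known A₀ and λ_bio,
nine PET frames over 90 minutes, a 4 mm FWHM PSF blur and Poisson
counting noise at a sensitivity (0.2 counts per Bq·h) chosen to give
~10⁴–10⁴·⁵ counts per kidney per frame — clinical dynamic-PET count
statistics at the organ level. Every random step is seed-controlled and
the ground-truth table makes Ã, local-dose and EQDX limits computable in
closed form for noise-free settings.

What it does *not* emulate: sinogram-level reconstruction (so no
reconstruction artifacts or correlated noise), scatter/randoms, partial
volume beyond the Gaussian PSF, respiratory motion, or intra-organ
kinetic heterogeneity. Passing tests on these phantoms therefore
demonstrates the correctness of the pipeline's mathematics and plumbing,
not robustness to everything clinical data can do. One consequence shows
up in testing: with organ-level counting statistics, low-uptake organs
have ~1 count per voxel per frame, so voxelwise λ maps are meaningful
only where uptake is high; the recovery tests fit organ-level TACs for
all organs and voxel medians only in the kidney.

## Problem sizes and determinism

Defaults were chosen so a full synthetic study runs in well under a
minute on one core: 64×64×48 voxels at 4 mm, 2×10⁵ spectrum samples
(statistical spread of z*₁D well under 1%), MC oracle checks at 32³ with
2–3×10⁵ histories. All public samplers require a seed and are
bit-reproducible; `run_pipeline()` writes a provenance record (config
hash, seeds, warning counters) and identical configs give bit-identical
outputs.

## Known limitations

- The chord-LET spectra omit δ-ray dispersion; absolute d(y) shapes are
  approximate, summaries are the supported quantities.
- Water-equivalent photon coefficients everywhere; density is the only
  material property the photon engine sees.
- No microscopic (sub-voxel) activity heterogeneity model: MKM
  parameters measured under uniform external irradiation may misstate
  TAT cell survival where radionuclides cluster within cell compartments.
- Mono-exponential kinetics only; no compartmental models, no PET
  reconstruction effects.
- The supported nuclide set is the four therapy-relevant labels named
  above; `nuclide()` lets a user supply custom inventories.
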