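---
title: "Energy-window optimization for iodine-124 PET: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-window optimization for iodine-124 PET: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgfpet)
```

## The physics being modeled

^124^I decays to a positron in only 23% of disintegrations, and its decay
scheme emits high-energy gamma photons (602 keV at 60%, 722 keV at 10%,
1691 keV at 11% per decay) in cascade with the positrons. A 602 keV gamma
falls inside any acquisition window whose upper level discriminator (ULD)
reaches much past 550 keV, so it can pair with one of the two 511 keV
annihilation photons and be recorded as a coincidence. These *prompt gamma
coincidences* carry almost no spatial information — the gamma is not
collinear with the annihilation pair — and behave as a diffuse background.

The analysis this package implements asks: given that widening the window
gains true coincidences but admits more prompt gammas, which window gives the
best *reconstructed image*, and does that answer differ from the classical
count-rate (NECR) answer?

## The PGF estimator

The prompt gamma coincidence fraction (PGF) of a window is estimated by
comparing ^124^I against ^18^F, a pure positron emitter, under the standard
sensitivity protocol (low-activity line source, counts well below 1%
dead-time loss, long separate background scan for the lutetium crystal
background). After dividing each measured sensitivity by its branching ratio,
both isotopes should be equally sensitive per positron; any excess on the
^124^I side is prompt gamma contamination:

$$\mathrm{PGF} = \frac{S^{corr}_{124I} - S^{corr}_{18F}}{S^{corr}_{124I}},
\qquad S^{corr} = S / \mathrm{BR}.$$

Normalizing by the ^124^I sensitivity (rather than the ^18^F one) is the form
that reproduces every independently checkable published value: 0.03, 0.13,
0.24, 0.31 for ULDs 550–750 keV at LLD 350 keV and 0.02 at 400~590 keV, all
at two decimals (`tests/testthat/test-pgf.R`). Decay of the source during the
scan is corrected with the isotope half-lives even though it is
negligible over 5 minutes. The aluminum-sleeve self-attenuation step of the
sensitivity protocol is implemented as the conventional log-linear
extrapolation of count rate to zero sleeve thickness
(`sleeve_zero_extrapolation()`).

## The correction chain and prompt-gamma subtraction

Corrections are applied in a fixed, recorded order: normalization →
dead time → randoms subtraction → attenuation → scatter / prompt-gamma
subtraction → decay. The prompt-gamma correction reuses the scatter estimate
as a spatial template:

$$\text{corrected} = \text{emission} - \text{scatter} \times \mathrm{PGF},$$

and the nested correction sets are AC (attenuation only), AC+SC (scatter also
subtracted) and AC+SC+PGF (scatter × (1+PGF) subtracted). Two deliberate
choices:

* **Negative bins are preserved.** Published spillover ratios of fully
  corrected images go as low as −6.47% in the air chamber; clipping negatives
  would make such values impossible and bias every cold-region statistic
  upward.
* **Both subtraction variants are exposed.** Whether the PGF term should be
  subtracted from the scatter-corrected or the uncorrected emission sinogram
  is ambiguous; `prompt_gamma_correct(subtract_scatter =)` covers both, with
  the literal single-subtraction form as the default.

Scatter itself is estimated either as the simulator's stored component
("truth" mode, for isolating downstream behavior) or by tail fitting: a
Gaussian in the radial coordinate is fitted (weighted by counts, since the
log of a Poisson profile has variance ≈ 1/counts) to the angle-averaged
emission outside the object support and interpolated beneath the object. On
the simulated uniform phantom the fitted scatter mass lands within 15% of the
stored component. Tail fitting requires radial bins beyond the object; with
the default phantom-sized field of view it raises an explicit error instead.

## Reconstruction

2D filtered backprojection per axial slice: frequency-domain ramp filter
(optional Hann apodization, off by default), linear interpolation in the
backprojection, 0.776 mm pixels, cutoff at Nyquist. The operator is linear,
so negative sinogram bins propagate to negative image values — required for
negative spillover ratios. The projector samples lines at half-voxel steps
with bilinear interpolation; a uniform disk projects onto the analytic
chord-length profile within 2% RMS, and the projector → FBP round trip
recovers the disk value within 3% inside the disk.

## NEMA NU 4-2008 metrics

* Nonuniformity: 100 × SD/mean of a 22.5 mm × 10 mm VOI centred in the
  uniform region. Sample SD (n−1) throughout, the NEMA convention.
* Recovery coefficients: slices spanning the central 10 mm of the rod section
  are averaged; in a circular ROI of twice each rod's diameter the maximum
  pixel is located; the axial line profile at that position gives
  RC = mean(profile)/uniform mean, with
  %SD = 100·sqrt(CV²(profile) + CV²(uniform)). A "max/uniform-mean" variant
  is available behind `method = "max"`.
* **Rod discernibility.** A rod is dropped (as the 1 mm rod is on real ^124^I
  images) when its maximum in the averaged image falls below the
  uniform-region *noise amplitude*, `k · NU/100 ×` uniform mean with k = 3 by
  default. A rule of the form "max < mean × (1 + 3·NU/100)" cannot work here:
  every ^124^I rod recovers less than the uniform mean (published RCs top out
  at 0.68), so a threshold above the uniform mean would discard all five
  rods rather than just the 1 mm one.
* Spillover ratios: mean of a 4 mm × 7.5 mm VOI centred in each cold chamber
  (half the chamber, keeping clear of positron-range contamination at the
  edges) over the uniform mean; may be negative.
* Weighted SOR: wSOR = sqrt(f_air·SOR_air² + f_water·SOR_water²) with fixed
  mouse-carcass volume fractions f_air = 0.027, f_water = 0.973. The optimal
  window minimizes wSOR; ties break toward the wider window, since a wider
  window buys sensitivity at no wSOR cost.

## The synthetic acquisition model

The simulator generates, per window, the four sinogram components the
corrections act on. It emulates the *statistical structure* of the problem,
not photon transport:

* **Trues**: discrete Radon transform of the voxelized phantom (direct 2D
  planes; no oblique sinograms, so no Fourier rebinning), attenuated by
  analytic line integrals of the 511 keV attenuation map (water 0.096/cm,
  PMMA 0.112/cm, aluminum 0.227/cm), scaled to activity × duration ×
  branching ratio × sensitivity × photopeak acceptance².
* **Scatter**: the true sinogram blurred radially with a wide Gaussian
  (σ = 12 bins) and scaled to mass SF/(1−SF) × trues. The scatter fraction is
  10% at the 350~750 keV reference window and is rescaled per window by the
  spectral model below.
* **Prompt gamma**: flat across the field of view by default — the
  contamination acts as spurious background activity; an object-shaped
  alternative (broadly blurred emission) exists because the true spatial
  distribution is not pinned down. Its mass is set so PG/(T+S+PG) equals the
  window's PGF.
* **Randoms**: flat, rate = coefficient × activity², with the coefficient
  defined at the reference window and rescaled by the squared singles
  acceptance.
* **Poisson noise** on the summed prompts, under explicit seeds (default
  20160322); the noiseless components are retained so corrections can be
  tested against ground truth.

**The energy-window response model.** Window dependence enters through an
analytic detected-energy spectrum: a Gaussian photopeak at 511 keV with 14.5%
FWHM energy resolution, a uniform scatter continuum between 250 and 540 keV,
and Gaussian-smeared cascade lines. From these the model derives the
photopeak acceptance p(w) (trues ∝ p²), the scatter acceptance (scaling the
scatter fraction), and an isotope singles acceptance (scaling randoms). This
is the part of the simulator that carries the study's qualitative physics:
the 400~590 keV window cuts scatter and randoms hardest and has the smallest
PGF, so it wins on NECR, while wide windows win on corrected image quality.

**Dead time and randoms defaults.** Dead time is non-paralyzable (the model
is otherwise unspecified), τ = 2×10⁻⁷ s, with randoms coefficient
2000 cps/MBq² at the reference window. The pair was chosen jointly so that
the sensitivity protocol's sources (506 and 673 kBq) sit below the 1%
dead-time-loss ceiling the protocol demands, while the NECR curve still turns
over inside the studied 1–50 MBq range — randoms reach roughly 40% of trues
at mid-range activities, typical of high-activity preclinical scans.

**The desk-scale operating point.** The study conditions are a 14.4 MBq,
4700 s acquisition (matching the positron count of a standard 3.7 MBq /
20 min ^18^F scan); `count_scale` multiplies all expected counts so the
simulated study runs at desk scale. The default 0.1 places the uniform-region
nonuniformity of attenuation-corrected images at 5.5–6.4%, inside the 5–10%
band where the scanner operates, with Poisson noise standing in for all
scanner noise sources. Two consequences worth being explicit about:

* At this operating point the seed-averaged nonuniformity varies by under
  one percentage point across the eleven windows, as on the scanner — but the
  *ordering* is inverted: simulated NU rises with ULD because the flat
  prompt-gamma background is DC-suppressed by the ramp filter (it adds noise
  but almost no mean), whereas the scanner shows its worst NU at the
  narrowest window. The across-window spread, not the ordering, is the
  property the tests assert.
* The simulated spillover ratios do not reproduce the published ones (those
  reflect single-scatter-simulation bias and positron range, neither
  modeled); what the simulation does reproduce is the *behavior* of the
  correction — prompt-gamma subtraction strictly shrinks |SOR(water)| — and
  the metric machinery itself. Published SORs are therefore shipped as a
  reference table and the window-selection arithmetic is exercised on them
  directly.

## The NECR model

The printed form of the prompt-gamma-augmented NECR,
NECR = T²/(T + S + 2fR + fPGF), is dimensionally ambiguous in its last term.
The adopted reading treats it as a rate: f × P_g with
P_g = PGF/(1−PGF) × (T+S), the prompt-gamma coincidence rate implied by the
window's PGF, with T the prompt-gamma-corrected trues rate. The literal
reading (f × PGF as a dimensionless addend) is implemented behind
`pgf_term = "literal"` for sensitivity analysis; neither is asserted as
ground truth. At PGF = 0 both reduce exactly to the classical
T²/(T + S + 2fR). The object fraction f is the mean over angles of the
fraction of radial bins intersecting the object (≈ 0.7 for the 25 mm mouse
phantom in the 37 mm default FOV, slightly above the 25/37 support ratio
because voxelized edges widen the projected support).

## Numerical and geometric choices

* Voxel membership is centre-in-region: simple, deterministic, and adequate
  for metric VOIs; partial-volume weighting was rejected as unnecessary.
  Voxelized volumes converge to analytic ones as voxels shrink (tested at two
  resolutions).
* Coordinates: right-handed, scanner z = phantom axis, physical mm
  everywhere; regions are grid-independent.
* The IQ phantom wall is 2 mm PMMA (configurable); the standard does not fix
  it. Cold chambers sit at ±7.5 mm from the axis; the standard fixes their
  dimensions but not their lateral placement.
* Default sinogram geometry: 96 angles over 180°, 48 radial bins of 0.776 mm
  (a 37 mm transaxial FOV sized to the 34 mm phantom), 0.776 mm pixels
  matched to the published reconstruction. The radial bin size and angle
  count are not published; both are configurable.
* Sinograms are stored as raw little-endian doubles with a JSON sidecar
  (dimensions, window, component, correction ledger); volumes as NIfTI with a
  mm affine; configs as YAML.

## Problem sizes

The default study profile simulates 11 windows × 3 correction sets on a
64 × 64 × 20 grid (2.5 mm slices), reconstructing only the slices the VOIs
need; it completes in well under a minute, and the full test suite — including
the 20-seed nonuniformity sweep and 10-seed correction comparisons — in about
a minute. Setting `count_scale = 1` and a finer axial grid runs the
full-count configuration at proportionally higher cost.

## Known limitations

* No photon transport: scatter is a blurred-trues model, prompt gamma a flat
  background, randoms a rate law. Passing tests demonstrate the analysis
  chain and its bookkeeping, not scanner-accurate absolute metrics.
* No positron range or detector blur, so recovery coefficients saturate for
  rods ≥ 3 mm instead of following the published partial-volume curve; only
  the monotone ordering (5 mm > 2 mm) and the 1 mm rod's non-discernibility
  are asserted.
* Direct 2D planes only; no oblique sinograms, no Fourier rebinning, no
  scanner list-mode or normalization file formats.
* The lutetium crystal background is a constant rate, not a spectrum.
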