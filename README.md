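# pgfpet

Energy-window optimization and prompt-gamma correction for iodine-124
small-animal PET.

## The problem

^124^I is attractive for longitudinal PET (half-life 4.18 d) but is a messy
positron emitter: only 23% of decays produce a positron, and high-energy
gamma photons (602, 722, 1691 keV) are emitted in cascade with them. When a
cascade gamma and an annihilation photon are recorded together they form a
*prompt gamma coincidence* — a spurious event that adds background to the
image. How wide the acquisition energy window should be is therefore a real
trade-off: a wide window collects more true coincidences but also more prompt
gamma contamination.

`pgfpet` implements the analysis chain used to settle that trade-off on image
quality rather than raw count rates, for preclinical scanners of the Siemens
Inveon class:

- **PGF estimation.** The prompt gamma coincidence fraction per energy window
  is estimated from paired sensitivity measurements of ^124^I and ^18^F
  (a prompt-gamma-free reference). With branching-ratio-corrected
  sensitivities S = S_measured / BR,

      PGF = (S_124I − S_18F) / S_124I .

- **Prompt-gamma correction** (sinogram domain):

      corrected emission = emission − scatter × PGF ,

  applied after normalization, dead-time, attenuation and scatter
  corrections; negative bins are preserved.

- **Reconstruction.** 2D filtered backprojection with a plain ramp filter,
  0.776 mm pixels.

- **NEMA NU 4-2008 image-quality metrics.** Nonuniformity (%SD of the uniform
  VOI), recovery coefficients with quadrature-propagated %SD, spillover
  ratios of the cold air and cold water chambers, and the
  tissue-fraction-weighted spillover ratio that drives window selection:

      wSOR = sqrt(f_air · SOR_air² + f_water · SOR_water²),
      f_air = 0.027, f_water = 0.973 (mouse lung/water volume fractions).

  The optimal window is the wSOR minimizer.

- **PGF-augmented NECR.** Noise-equivalent count rate with a prompt-gamma
  penalty, NECR = T² / (T + S + 2·f·R + f·P_g), where f is the fraction of
  the projection occupied by the object and P_g the prompt-gamma coincidence
  rate implied by the window's PGF.

- **A synthetic acquisition simulator** (NEMA NU 4 image-quality and mouse
  phantoms, per-window trues/scatter/randoms/prompt-gamma sinogram components
  with Poisson noise, analytic attenuation, an energy-window response model)
  so the entire pipeline runs without scanner data.

## Worked example

```r
library(pgfpet)

# PGF at 350~750 keV from published sensitivities (2.26% for 124I, 6.61% for 18F)
s_i <- branching_ratio_correct(2.26, isotope("I124"))  # 9.83 %
s_f <- branching_ratio_correct(6.61, isotope("F18"))   # 6.81 %
compute_pgf(s_i, s_f)
#> [1] 0.3065387        # 31% of coincidences are prompt gamma events

# weighted spillover ratio for the same window (published SORs -5.54 / 0.26)
weighted_sor(-5.54, 0.26, f_air = 0.027, f_water = 0.973)
#> [1] 0.9456969        # the smallest wSOR of all eleven windows

# select the optimal window over the published table
sor <- published_sor_table()
sor$wsor <- weighted_sor(sor$sor_air_pct, sor$sor_water_pct)
window_label(select_optimal_window(sor))
#> [1] "350~750"
```

A full synthetic study — simulate the IQ phantom at all eleven windows,
reconstruct the AC / AC+SC / AC+SC+PGF correction sets, compute the metrics
and select a window — is one call:

```r
bundle <- run_study(study_config())
write_report(bundle, "results/iq_study")
```

On the simulated phantom the prompt-gamma correction shrinks the mean cold
water spillover from 9.16% (attenuation-corrected only) through 4.06% (plus
scatter correction) to 2.87% (plus prompt-gamma correction); the
seed-averaged nonuniformity of the attenuation-corrected images varies by
less than one percentage point across windows (a property exercised in the
test suite). The NECR track reproduces the count-rate view of the trade-off: the
highest NECR at 5 MBq occurs at 400~590 keV and normalized NECR falls as the
ULD rises past 600 keV, yet the image-quality criterion picks the much wider
350~750 keV window (wSOR 0.95 vs 1.67) — count rates and image quality
genuinely disagree here.

## Analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_pgf_sensitivity.R    # PGF from sensitivities (published + simulated)
Rscript analysis/02_iq_phantom_study.R   # IQ phantom study across windows
Rscript analysis/03_necr_curves.R        # NECR curves and normalized NECR vs ULD
Rscript analysis/04_window_selection.R   # wSOR table and optimal-window selection
```

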