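# photonsar

Desk-scale modelling for implantable photonic neurostimulators: pulsatile
tissue reflectance for operating-wavelength selection, resonant
wireless-power-transfer (WPT) link design, and quasi-static electromagnetic
dosimetry against the 2 W/kg localized SAR limit.

An implanted light source for deep-brain photobiomodulation has to satisfy
two independent constraints at once: its wavelength must be chosen where the
optical signal is most sensitive to hemodynamics (blood volume pulsing with
the cardiac cycle modulates hemoglobin absorption), and its wireless power
link must not deposit unsafe electromagnetic energy in the surrounding
tissue. photonsar implements both analyses, plus the synthetic phantoms that
make them reproducible without any external data, for researchers modelling
implantable biophotonic devices.

## Models

**Pulsatile reflectance.** A four-layer brain slab (polyurethane, CSF,
gray/white matter, cerebellum; 7.3 mm total) carries a vessel whose blood
volume fraction follows a piecewise cardiac pressure waveform,
P(t) = (1−α)·sin(π(t−t₀)) during a numerical ramp and
(1−α)·cos(2π(t−t₀)) during the 1 s pulsatile phase (α = 1/3). Blood
absorption is the saturation mixture
μₐ = S·μₐ(HbO₂) + (1−S)·μₐ(Hb) on a packaged 400–890 nm table. Reflectance
comes from a modified Beer–Lambert model,
R = S_alb · exp(−2Σ μₐᵢ dᵢ/cosθᵢ − L_rt·(f/f_ref)·μₐ,blood), and from an
independent 2D Monte Carlo radiative-transport engine (Henyey–Greenstein
scattering, exact energy bookkeeping). The per-wavelength cardiac
reflectance variation ΔR = max R − min R over the cycle selects the
operating wavelength per band.

**WPT link.** The implant coil (L = 15 µH) is tuned by
C = 1/(L(2πf₀)²) for f₀ = 1.35 MHz and analyzed as a series R-L-C against
50 Ω: S11(f) = (Z−z₀)/(Z+z₀), return loss −20·log₁₀|S11|, delivered power
1−|S11|².

**SAR dosimetry.** On a voxelized head phantom (hemispherical brain +
shell + 1 cm³ implant, 2 mm voxels), the receiving coil's vector potential
is computed by finite-segment Biot–Savart, the induced field is
|E| = ω|A| (magneto-quasistatic), pointwise SAR is σ|E|²/ρ, and the
compliance quantity is the peak of the 10 g mass-averaged SAR map using an
air-excluding hemispherical kernel (10 g at 1007 kg/m³ ↔ 1.33 cm sphere).

## Worked example

```r
library(photonsar)

# 1. wavelength selection: scan the pulsatile reflectance on the 10 nm grid
scan <- spectral_scan(make_phantom_2d())
bands <- band_analysis(scan)
bands[[3]]
#> <band_summary> 600-800 nm: argmax dR at 660 nm (dR=0.0737), min mean R at 600 nm

# 2. tune the wireless link and check the match
design <- wpt_design(coil_spec(), f_target = 1.35e6,
                     nominal_capacitance = 100e-12)
design$capacitance * 1e12       # back-calculated tuning capacitor, pF
#> [1] 926.577
design$min_return_loss_db       # resonance dip depth, dB
#> [1] 29.88628
design$delivered_power_fraction # 1 - |S11|^2 at resonance
#> [1] 0.998974
design$nominal_consistent       # a 100 pF capacitor does NOT hit 1.35 MHz
#> [1] FALSE

# 3. dosimetry: peak 10 g-averaged SAR of the implant's induced field
dosimetry <- sar_analysis(make_phantom_3d())
dosimetry$report
#> SAR compliance report (mass-averaged 10 g):
#>  region averaging_mass_g   avg_sar max_avg_sar limit pass
#>   brain               10 7.373e-10   2.583e-08     2 TRUE
#>    head               10 2.530e-09   1.550e-07     2 TRUE
```

Reading the output: in the 600–800 nm band the cardiac-cycle reflectance
variation peaks at 660 nm (ΔR ≈ 0.074) — the wavelength where the signal is
most sensitive to blood-volume pulsation while hemoglobin absorption is
already decaying. The link needs ≈ 927 pF (not the nominal 100 pF) to
resonate at 1.35 MHz, where the −29.9 dB dip means 99.9% of incident power
enters the coil. The induced-field dosimetry at the default 23.7 mA RMS
drive yields a peak 10 g-averaged SAR of ≈ 1.5 × 10⁻⁷ W/kg, far below the
2 W/kg localized-exposure limit.

The end-to-end driver `run_pipeline(run_config(), out_dir)` runs all stages
and writes band summaries, a Touchstone `.s1p` file, the SAR report and a
`summary.json` with the headline numbers. See the vignette in `vignettes/`
for the model assumptions, calibration constants and limitations.

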