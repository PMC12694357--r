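---
title: "Methods: coupled optical, wireless-power and SAR modelling for an implantable photonic neurostimulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled optical, wireless-power and SAR modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonsar)
```

photonsar models three linked questions about an implantable light-delivery
device for deep-brain photobiomodulation: which wavelength gives the most
useful optical signal in pulsating, blood-perfused tissue; how the implant's
receiving coil should be tuned for resonant inductive powering; and whether
the electromagnetic field induced by that coil keeps the tissue's specific
absorption rate (SAR) inside the 2 W/kg localized-exposure limit. This
vignette explains each model, its assumptions, the tunable parameters, and
what the package's synthetic phantoms do and do not emulate.

## 1. Blood optics and the pulsatile drive

### Hemoglobin spectrum

The normative spectral dataset is a 400–890 nm, 10 nm-step table of
absorption coefficients for oxygenated (HbO~2~) and deoxygenated (Hb)
hemoglobin, exposed by `default_hemoglobin_spectrum()`. The HbO~2~ column
peaks at 1.7 /m at 580 nm and both columns decay monotonically into the red.
Two caveats are inherited deliberately from the source data and are *not*
corrected:

* the magnitudes (0.1–1.7 /m) are orders of magnitude below physiological
  whole-blood values — the table is treated as a normalized, normative scale
  rather than a physical one (see the path-length calibration below);
* the Hb column has no 760 nm feature.

Blood absorption at saturation $S$ is the convex mixture
$\mu_a(\lambda) = S\,\mu_{a,\mathrm{HbO_2}}(\lambda) +
(1-S)\,\mu_{a,\mathrm{Hb}}(\lambda)$ (`blood_mua()`), with piecewise-linear
interpolation between grid wavelengths; queries outside 400–890 nm are
errors rather than extrapolations. The default saturation is 0.97
(arterial blood).

### Cardiac pressure waveform

The normalized pressure drive (`pressure_waveform()`) covers 1.5 s: a
0.5 s numerical ramp $P(t) = (1-\alpha)\sin(\pi (t - t_\mathrm{start}))$
with no physiological meaning, then a 1.0 s pulsatile phase
$P(t) = (1-\alpha)\cos(2\pi (t - t_\mathrm{start}))$. The phases are
continuous at the boundary for every $\alpha$ because
$\sin(\pi/2)=\cos(0)$. $\alpha$ defaults to 1/3, the approximate systolic
fraction of the cardiac cycle. Two printed-form ambiguities were resolved
as design choices: the phase arguments are read as
$\sin(\pi\,(t-t_\mathrm{start}))$ (the only reading that is continuous),
and although the pulsatile phase is sometimes described as triangular, the
cosine is the default with a triangular alternative behind
`shape = "triangle"`. As written the pulsatile period is 1.0 s even though
a 75 bpm heart beats every ~0.8 s; the waveform is implemented as printed.
The default sampling step is 0.01 s.

Pressure maps to blood volume fraction through `modulation_model()`:
$f(t) = f_0\,(1 + \beta P(t))$ with defaults $f_0 = 0.05$ and
$\beta = 0.15$. These are calibration constants of this package (no
mapping is given by the design source); they keep $f$ within
$[0.045, 0.055]$ over the pulsatile phase at $\alpha = 1/3$.

## 2. Reflectance engines

### Layered phantom

`make_phantom_2d()` builds the four-layer slab — polyurethane encapsulant
(0.8 mm), cerebrospinal fluid (0.5 mm), gray/white matter (2.5 mm),
cerebellum (3.5 mm), total 7.3 mm — with a vessel embedded in the
gray-matter layer. The vessel diameter is nowhere stated in the design
inputs; the default is 0.5 mm, configurable. Interfaces are flat by
default, which is the geometry every analytic oracle assumes; a curvature
radius can be recorded for demonstration geometry, but the transport
engines require flat interfaces (the Monte Carlo engine refuses curved
phantoms).

### Modified Beer–Lambert model

`analytic_reflectance()` is a double-pass exponential attenuation along
the Snell-refracted ray with a wavelength-independent backscatter albedo:

$$R(\lambda) = S_\mathrm{alb}\,
  \exp\!\Big(-2\sum_i \mu_{a,i}\, d_i/\cos\theta_i \;-\;
  L_\mathrm{rt}\,\tfrac{f}{f_\mathrm{ref}}\,\mu_{a,\mathrm{blood}}(\lambda)\Big).$$

The layer term uses the per-layer coefficients (1/m) against mm
thicknesses converted to metres; with the packaged table it is numerically
negligible, which is faithful to the normalized data. **The blood term is
the calibrated heart of the model**: because the spectral table is on a
normalized scale, the blood path is expressed in the same normalized units
through two documented constants, the round-trip blood path
$L_\mathrm{rt} = 1.64$ and the reference volume fraction
$f_\mathrm{ref} = 0.05$. At the reference volume fraction the blood
exponent is exactly $L_\mathrm{rt}\,\mu_{a,\mathrm{blood}}$, and it scales
linearly with $f$. $L_\mathrm{rt}$ was chosen once so that the product of
pulsatile sensitivity and attenuation — the per-wavelength cardiac
$\Delta R$ below — peaks inside the 650–670 nm bracket on the packaged
table; it is not fitted to any test outcome and both $S_\mathrm{alb}$
(default 1) and the calibration cancel in $\Delta R$ ratios and argmax
selection.

### Monte Carlo engine

`mc_simulate()` is a 2D radiative-transport Monte Carlo: photon packets
enter at the source incidence angle (20° by default) with a single
unpolarized Fresnel specular loss at entry, free paths are sampled from
the local $\mu_t$, a fraction $\mu_a/\mu_t$ of the packet weight is
deposited into a gridded absorption map at each interaction, and new
directions are drawn from the 2D (wrapped) Henyey–Greenstein phase
function with anisotropy $g$ (default 0.9; the design source states no
$g$). Internal index steps refract the ray (Snell, with total internal
reflection) but partial internal reflections are ignored by default.
Numerical choices:

* *Termination.* Packets below the weight threshold ($10^{-4}$) play
  Russian roulette with survival probability 0.1. Survivors are **not**
  re-amplified; a killed packet deposits its residual weight at its
  current position. This keeps the energy ledger exact —
  `r_specular + r_diffuse + transmittance + side_escape + absorbed`
  equals 1 to better than $10^{-9}$ by bookkeeping, not sampling — at the
  cost of a bias bounded by the threshold ($10^{-4}$ absolute), far below
  the Monte Carlo standard errors of any quantity the package reports.
* *Deep mirror.* `mc_config(bottom_albedo = s)` installs a specular
  mirror of albedo $s$ at the deep boundary. This is the transport
  realization of the analytic model's double-pass-with-albedo geometry:
  in the scattering-free limit the two engines agree exactly in
  expectation, which the test suite exploits as a cross-engine oracle.
* *Determinism.* The engine consumes R's RNG; a fixed seed reproduces
  results bitwise. Time-series runs derive per-step seeds from the master
  seed by counting.
* *Scale.* With the packaged (normalized) layer coefficients, mm-scale
  layers are essentially transparent to the MC engine; meaningful diffuse
  reflectance requires synthetic coefficients on a physical scale, which
  is what the MC-specific tests use. The vessel medium bridges the
  normalized scale by assigning the per-mm absorption that accumulates
  the analytic blood exponent over a normal-incidence double pass through
  the vessel diameter (`vessel_mua_per_mm()`).

`penetration_depth()` reduces an absorbed-energy map to the depth at
which the cumulative (surface-down) absorption reaches 90% of the total,
linearly interpolated within the crossing bin.

## 3. Delta-R metrics and wavelength selection

Two variation metrics coexist because the design source uses both:

* the per-wavelength cardiac metric (`delta_r()`): max − min reflectance
  over the pulsatile window $[0.5, 1.5]$ s (the ramp is excluded). Its
  closed-form counterpart `delta_r_theoretical()` evaluates the analytic
  model at the two volume-fraction extremes
  $f_0 (1 \pm \beta\,(1-\alpha))$. With the analytic engine the two are
  identical to floating point, since the cosine attains its extremes on
  the sample grid — a deliberate redundancy that the tests assert;
* the per-band spectral range (`band_spectral_range` in
  `band_analysis()`): max − min of cycle-mean reflectance across the
  band's wavelengths.

The per-wavelength cardiac metric drives wavelength selection. On the
defaults, the 600–800 nm band's argmax lands at 660 nm: blood absorption
decays monotonically above 600 nm, and the calibrated two-exponential
$\Delta R(\mu)$ is concave with its interior maximum near
$\mu \approx 0.61$ — the 660 nm mixture value. Ties break toward the
lowest wavelength, deterministically. Bands default to 400–500, 500–600
and 600–800 nm, half-open on the right except the last. The co-criterion
"lowest overall reflectance" is reported (`argmin_mean_R`) but not used
for selection: under a pure Beer–Lambert model the cycle-mean reflectance
in 600–800 nm is minimized at 600 nm, not 660, and the package does not
manufacture agreement where the model cannot produce it.

## 4. Wireless-power link

The tuned implant coil is modelled as a series R–L–C branch against a
real 50 Ω reference — the simplest circuit with the observed single-dip
$|S_{11}|$ response. $f_0 = 1/(2\pi\sqrt{LC})$; `required_capacitance()`
is its exact algebraic inverse, and for $L = 15\,\mu$H and
$f_0 = 1.35$ MHz it returns 926.6 pF. A nominal ~100 pF capacitor would
resonate near 4.11 MHz instead; `wpt_design()` computes the consistent
value and flags the nominal one. The coil's effective series resistance
defaults to 53.31 Ω, a documented calibration: at resonance
$|S_{11}| = (53.31-50)/(53.31+50) = 0.032$, i.e. a −29.87 dB return-loss
dip with $1-|S_{11}|^2 = 99.9\%$ of incident power delivered. A
parallel-tank alternative is available (`topology = "parallel"`); note
that against a 50 Ω reference its $|S_{11}|$ minimum is not at the tank's
natural frequency (the tank presents kΩ there), so its resonance is
diagnosed from the impedance-magnitude peak. Sweeps default to
0.5–3 MHz, 2001 linear points; spectra export as Touchstone `.s1p`
(MA, 50 Ω) and columnar text.

## 5. Quasi-static SAR dosimetry

### Field model

A full-wave finite-element solve is replaced by magneto-quasistatics,
valid at 1.35 MHz where tissue dimensions are far below a wavelength: the
coil's magnetic vector potential is computed by exact finite-segment
Biot–Savart over a helical polyline (64 segments/turn by default; the
loop-center field is within 0.1% of $\mu_0 I/2a$ at that
discretization), and the induced field is $|E| = \omega |A|$, neglecting
the conservative charge-redistribution term. Pointwise SAR is
$\sigma |E|^2/\rho$ with RMS field magnitude; air is zero by definition.
Because the absolute drive is not a stated design input, the default coil
current is set so the power dissipated in the coil branch equals the
3 mW optical budget at a 10% end-to-end link efficiency
(23.7 mA RMS; `coil_drive_current()`); SAR scales as $I^2$, so any other
drive assumption rescales the result analytically. Absolute
finite-element SAR magnitudes are consequently out of reach by design;
the pipeline reproduces bounds and structure, not those magnitudes.

### Phantom and averaging

`make_phantom_3d()` voxelizes a hemispherical brain (radius 7 cm, dome
toward the implant) under a 0.7 cm head shell, with a 1 cm³ device box on
the shell apex and the coil at the device center, axis into the head;
2 mm voxels give ≈ 1.2 × 10⁵ tissue voxels — the desk-scale problem size
used throughout, chosen so the full dosimetry stage completes in well
under a minute.

A 10 g averaging mass at 1007 kg/m³ corresponds to a 9.93 × 10⁻⁶ m³
volume — a 1.33 cm sphere or a 1.68 cm hemisphere
(`averaging_radius()`). `mass_averaged_sar()` supports three kernels:

* fixed sphere and fixed hemisphere (flat face through the evaluated
  voxel, dome along the device axis into tissue — the orientation that
  keeps the domain intracranial for an implant on the brain surface);
* the default adaptive air-excluding mode, which visits neighbour voxels
  in increasing physical distance (ties broken by the z, then y, then x
  offset — a documented ordering contract mirrored exactly by the
  brute-force test oracle) and accumulates whole voxels, skipping air and
  the device package, until the 10 g target is reached. Realized mass
  therefore lies within one voxel mass above the target everywhere.

The adaptive search bound defaults to five nominal radii: voxels at the
phantom's flat base, where the hemispherical half-space points into air,
can then still gather 10 g from the in-plane disc; with tighter bounds
the kernel correctly refuses to evaluate ("insufficient tissue mass").
The compliance report gives, per region (brain; head = shell + brain),
the volume-average of pointwise SAR and the maximum of the mass-averaged
map against the 2 W/kg limit. With all defaults the peak 10 g-averaged
SAR is of order 10⁻⁷ W/kg — orders of magnitude inside the limit, as
expected for a milliwatt-budget magneto-quasistatic source.

## 6. What the synthetic data do and do not emulate

The generators reproduce the *study conditions*: layer stack and
thicknesses, embedded vessel, normalized hemoglobin table, cardiac drive,
coil and phantom geometry. They do not emulate real anatomy (no
convoluted cortical surface, no heterogeneous vasculature), physiological
hemoglobin magnitudes, coherent/polarization optics (the transport is
radiative, not wave), tissue heating (thermal properties are stored but
consumed by nothing), or the transmit side of the power link (no coupling
coefficient, rectifier or alignment study). Passing tests therefore
demonstrate internal consistency of the models and exact agreement with
their independent oracles — not clinical validity on real tissue.

## 7. Reproducibility and problem sizes

Every stochastic component draws from R's RNG under an explicit seed;
`run_pipeline()` fans a master seed out to fixed per-stage offsets so
removing stages never reshuffles the others. Monte Carlo checks use
10⁵ packets (binomial standard errors ≈ 1.5 × 10⁻³); the dosimetry stage
uses the 2 mm phantom above; brute-force oracle comparisons run on 8³ and
16³ grids where exhaustive recomputation is exact. The acceptance script
(`scripts/acceptance.R`) recomputes the headline wavelength and the peak
10 g SAR from scratch at these sizes.
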