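---
title: "Single-shot dosimetry for laser-accelerated proton beamlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot dosimetry for laser-accelerated proton beamlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Target-normal sheath acceleration (TNSA) converts a single high-energy
laser pulse into a nanosecond proton bunch with an exponential
("thermal") energy spectrum and a high-energy cutoff.  Transported
through a permanent-magnet quadrupole doublet and a thin scattering
filter, such a bunch can deposit tens of Gy on a centimeter-scale
biological sample in under 10 ns — an ultra-high dose-rate (FLASH-type)
irradiation.  The catch is that the source fluctuates from shot to shot
and nothing can be monitored before the dose has already been
delivered, so the irradiation conditions of every shot must be
reconstructed *after the fact* from the only available measurement:
two or three radiochromic films (RCF) sandwiching the sample.

`lapdose` implements the full chain needed for that reconstruction:

1. **physics kernels** — relativistic Bethe stopping power with Bragg
   additivity, CSDA ranges, slab traversal, LET, and Highland multiple
   scattering;
2. **source model** — the truncated exponential spectrum
   $Q^*(E)\,\mathrm{d}E = (Q_0^*/E_0)\,e^{-E/E_0}\,\mathrm{d}E$ on
   $[E_{low}, E_{high}]$, its sampler, and stacked-film source
   characterization;
3. **beamline Monte Carlo** — hard-edge quadrupole transport with
   chromatic focusing and aperture rejection, filter/window scattering,
   and per-pixel dose scoring in layered targets;
4. **film response** — LET quenching ($\eta$, QCF) and dose-to-water
   equivalence (DWE) corrections;
5. **shot reconstruction** — per-temperature charge extrapolation
   $\overline{Q^*_{E_0}} = \tfrac1N \sum_i D_i^{(rcf)}/d_{i,E_0}^{(sim)}$
   with dispersion
   $\sigma_{E_0} = \tfrac1N \sqrt{\sum_i (Q_i - \overline{Q})^2}$, the
   variance-minimizing temperature fit, the single-film weighted
   protocol, and a linear-quadratic survival utility.

# Model assumptions

**Source.** The spectrum is purely exponential between a 1 MeV lower
cutoff and a 19.5 MeV upper cutoff, emitted isotropically within a
100 mrad cone (the acceptance of the first quadrupole, whose bore
subtends about 6 degrees at 48 mm).  Shot-to-shot variation is carried
entirely by the two free parameters $(Q_0^*, E_0)$; the cutoff is held
fixed during reconstruction because the highest-energy decade of the
spectrum contributes little to the deposited dose.  Shots whose implied
spectrum cannot penetrate the film stack are flagged rejected rather
than fitted.

**Optics.** Quadrupoles are hard-edge: per-energy transfer matrices
from the relativistic rigidity, with aperture rejection at entrance,
midplane and exit of each magnet.  This captures the chromatic
focusing that drives the spectral selection of the line, but not the
fringe fields of the real magnets (which were characterized by
measured field maps we do not have).  That fidelity difference is the
main known source of bias in the fitted temperature.

**Foils and air.** The scattering filter and vacuum window apply CSDA
energy loss followed by a single Gaussian angular kick with the
projected Highland width per transverse axis.  The 55 mm air path
applies energy loss only; its scattering contribution to a 10 mm ROI
is negligible at these energies.

**Targets.** Layered stacks mirror the two irradiation assemblies: the
in-vitro holder (two front EBT-XD films, a 50 µm silicone membrane, a
20 µm water cell layer, an air gap, a 127 µm paraffin seal, one back
film) and the thick-sample holder (one film, a thin polyester window,
600 µm of water sliced into 20 µm scoring layers).  The EBT-XD film is
modeled as 125/28/125 µm polyester/active/polyester with the
manufacturer-style active-layer composition; the stacked-film
spectrometer uses 6.5 µm active layers on 97 µm polyester substrates.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `E_low`, `E_high` | 1, 19.5 MeV | spectral support; `E_high` fixed in fits |
| `theta_max` | 0.100 rad | source acceptance half-angle |
| `gradient_tpm` (Q1, Q2) | 332, 322 T/m | quadrupole field gradients |
| `bore_radius_mm` | 5 mm | aperture radius of both magnets |
| `filter_dz_mm` | 275 (DE), 250 (ZF) mm | filter distance past Q2; the dose-escalation knob |
| `filter_thickness_um` | 70 (DE), 50 (ZF) µm | aluminum scattering filter |
| `roi_diameter_mm` | 10 (DE), 5 (ZF) mm | scoring region of interest |
| `pixel_um` | 250 µm | dose-map pixel pitch |
| `n_primaries` | 2e5 | primaries per library temperature |
| temperature grid | 1–5 MeV, 1 MeV steps | reconstruction grid (ties break low) |
| `calibration_factor` | 0.935 | film calibration correction, $1 - 0.065$ |
| `noise_sigma` | 0.03 / 0.30 | fixture reading noise (film error / shot-to-shot) |

# Numerical choices

* **Low-energy floor.** The Bethe formula is evaluated down to
  0.5 MeV per nucleon; below that the model deposits the remaining
  energy locally.  The CSDA range integral starts at the floor plus a
  constant residual range $E_{floor}/S(E_{floor})$ (about 12 µm of
  water for protons).  Only end-of-range behavior is affected and
  energy is conserved exactly.
* **Mean excitation energies.** Derived from per-element I-values by
  Bragg additivity (this reproduces the standard composite values for
  polyester, 78.7 eV, and polyimide, 79.6 eV); water and air carry
  explicit condensed-phase overrides (78 eV, 85.7 eV).
* **Straggling.** Energy-loss straggling is not simulated: the
  protocol consumes ROI-averaged doses of broad spectra, which are
  insensitive to microdosimetric smearing.
* **Quenching efficiency.** $\eta = -0.0251\,\mathrm{LET} + 1.02$ is
  clamped at 0.05 where the linear law would go non-positive (LET
  above ~38.6 keV/µm); this avoids division blow-up in the QCF sum.
* **Correction tally.** The per-plane spectra that feed QCF and DWE
  count protons that *traverse* the sensitive layer.  The linear
  quenching law is a through-going-film calibration; applying it to
  protons that stop inside the 28 µm active layer would extrapolate
  the law far outside its measured domain and lets a percent-level
  fluence tail dominate the correction.  Stoppers still contribute to
  the dose maps, so no energy is lost.  This convention reproduces the
  depth ordering of the published per-film QCF values; their absolute
  scale remains sensitive to exactly this choice, which is why the
  quenching correction is the least transferable number in the chain.
* **DWE.** Implemented exactly as the fluence-weighted ratio of mass
  stopping powers, water over polyester.  With standard I-values this
  ratio is slightly above unity (water out-stops polyester per unit
  mass).  The alternative linear-stopping reading would push the
  factor far from 1; the mass-stopping convention is retained and the
  factor cancels almost entirely in the temperature fit because it is
  nearly plane-independent.
* **Film water-equivalent thickness.** The mass-stopping-scaled
  thickness of the film model at 10 MeV is ~359 µm (382 µg/cm² areal
  density times a ~0.94 polyester/water stopping ratio).  The nominal
  385 µm often quoted for this film corresponds to density-only
  scaling; we keep the physical formula.
* **Eq. for $\sigma$.** The charge dispersion places $1/N$ outside the
  square root (population-style, matching the printed formula); the
  ratio $\sigma/\overline{Q}$ used for the fit is insensitive to this
  convention.
* **Stack characterization.** The spectrometer fit works in log-dose
  space with equal film weights, excludes saturated films, estimates
  the cutoff bracket from the deepest responsive film, and then fits
  $(Q_0, E_0, E_{cut})$ jointly with the cutoff constrained to its
  bracket (protons above the cutoff cross every film, so a mis-set
  cutoff biases all planes).  Films whose Bragg energy is within 20%
  of the cutoff are used for the cutoff only, as in stacked-film
  spectrometry practice.  A fixed canonical energy grid makes repeated
  forward evaluations bit-identical, and the weakly-determined cutoff
  direction is multi-started.
* **Problem sizes.** Libraries use 2e5 primaries per temperature on a
  {1..5} MeV grid; the parameter-recovery property runs 100 seeded
  trials at 3% reading noise; the Monte Carlo vs deterministic
  comparison uses 1e5 pencil-beam primaries.  All are chosen so the
  Monte Carlo standard error is well below the tolerances they are
  tested against.

# The synthetic-data generators

`make_phantom_shot()` forward-simulates film readings for a known
$(E_0, Q_0^*)$ through a dose library, inverts the correction chain so
that reconstruction round-trips exactly at zero noise, and applies
multiplicative lognormal reading noise (3% models film dosimetry
error; 30% mimics the observed shot-to-shot dose spread).
`make_stack_fixture()` emulates a stacked-film calibration shot close
to the source, including the energy-dependent divergence of the
emission (constant half-angle below a 10 MeV knee, parabolic decrease
above, defaults 20° falling toward ~6° at the cutoff — chosen as
typical TNSA behavior since only the shape, not the values, is
reported).  `make_dose_map_fixture()` produces Gaussian or flat dose
maps on the standard 250 µm grid.

What the generators deliberately do *not* emulate: scanner artifacts,
film lateral non-uniformity, beam pointing jitter, heavier-ion
contamination (only the carbon-ion range-rejection check is
supported), and any non-exponential spectral shape.  Passing the
recovery tests therefore demonstrates the internal consistency of the
protocol under its own assumptions, not its robustness to real-film
systematics.

# Known limitations

* Hard-edge optics vs measured field maps: the chromatic transmission
  curve of the real doublet differs in detail, which propagates into
  the per-plane dose ratios and can shift the fitted temperature by
  about one grid step on real shots.
* No nuclear interactions, secondary particles, or δ-ray transport;
  doses at depth are slightly overestimated for the highest energies.
* The quenching correction magnitude depends on how end-of-range
  protons are treated (see above); per-film *ratios* and the
  temperature fit are much less sensitive than the absolute QCF.
* The single-film protocol inherits whatever bias is present in the
  empirical temperature-occurrence weights supplied by the user; the
  default is uniform over the grid.
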