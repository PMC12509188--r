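# thermopsf

Imaging-response theory for mid-infrared optical photothermal (O-PTIR)
microscopy and confocal light microscopy, as an R package.

O-PTIR is a pump–probe technique: a modulated mid-IR laser heats an
absorbing particle, the surrounding medium forms a "thermal lens"
(refractive-index gradient), and a focused visible probe beam senses the
resulting change in transmitted power.  While the radial imaging response
of such an instrument is close to that of an ordinary confocal
microscope, the *axial* response is not: it is a signed, two-lobed
dispersion curve whose shape depends on the axial offset Δz between the
pump and probe foci.  This package is for microscopists and instrument
builders who want to predict, analyse or fit that response.

It provides:

* **Vectorial confocal PSFs** — the focal-field integrals
  (e₀, e₁, e₂ with Bessel kernels J₀, J₁, J₂ over the aperture angle) for
  high-NA objectives, including annular (Schwarzschild) apertures, and
  FWHM resolution figures extracted from radial/axial profiles.
* **The photothermal nanolens model** — the steady-state thermal-lens
  contrast
  Δn(z, Δz) = σ_abs I₀,h /(4πκR) · (dn/dT) · (1 + (z−Δz)²/z_R,h²)⁻¹,
  the closed-form far-field relative signal
  Φ(θ, z) = e^(−k²tan²θ·Re(ζ⁻¹)/2) ·
  ( e^(2RΔn k₀ arg ζ) |Γ(1 + iRΔn k₀) ₁F₁(−iRΔn k₀; 1; k²tan²θ/(4ζ))|² − 1 )
  with the beam-curvature term ζ(z) = 1/ω²(z) + ik/(2R_c(z)), and its
  integral Φ_tot over the collection cone [θ_min, θ_max].
* **An independent numerical diffraction oracle** — the Fresnel/Hankel
  integral of the probe field with the logarithmic thermal-lens phase,
  used to validate the closed form (agreement ~1e-8 in the tests).
* **Scan-image processing** — tilt-rotation search, central-line
  averaging, Gaussian FWHM fits, beam ellipticity.
* **Parameter recovery** — least-squares fitting of (Δz, σ_abs) to axial
  profiles, plus a synthetic scan-image generator for end-to-end testing.

## Worked example

```r
library(thermopsf)

# theoretical resolution of the two modelled instruments at 633 nm
res_raman <- confocal_resolution(objective(0.55), objective(0.55), 0.633)
res_optir <- confocal_resolution(objective(0.5),  objective(0.5),  0.633)

# the bundled reference scene: 0.25 um PS bead in air, 6.895 um pump
# (6.6 mW avg, 2.5% duty cycle, 50 kHz), 633 nm probe, 21-30 deg annulus
sc  <- table1_scene()
det <- table1_detection()
sig <- axial_scan(sc, det, seq(-10, 10, by = 0.1))
lobe_analysis(sig)

# recover focus offset and cross section from a noisy synthetic scan
set.seed(42)
z <- seq(-8, 8, by = 0.25)
y <- abs(phi_total(table1_scene(0.065, 2), det, z)) * (1 + rnorm(length(z), 0, 0.05))
fit_axial_profile(line_profile(z, y), table1_scene(0.03, 0), det, normalize = FALSE)
```

This prints:

```
Raman:  radial 425 nm, axial 2.45 um
O-PTIR: radial 467 nm, axial 3.02 um
Lobe report: 2 lobe(s); positions (um): 2.10, -2.10; secondary/primary = 0.980
Nanolens fit: dz = 1.999 +/- 0.294 um, sigma_abs = 0.0641 +/- 0.00073 um^2 (6.41e-14 m^2)
```

Reading: the confocal Raman arm (one 0.55 NA objective) resolves ~425 nm
radially and ~2.45 um axially; the O-PTIR optics (two 0.5 NA objectives)
~467 nm and ~3.0 um.  At perfect focus overlap the photothermal z-scan
has two nearly symmetric lobes ±2.1 um from the bead, and a 5%-noise
synthetic scan returns the true focus offset (2 um) and absorption cross
section (0.065 um²) to within a few percent.

A command-line interface over the same functions lives at
`inst/cli/thermopsf.R` (subcommands `psf`, `signal`, `lobes`, `fit`,
`simulate`); every subcommand writes a `.settings.json` snapshot beside
its output.

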