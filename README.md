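# metafcs

Design and evaluation toolkit for **dual-wavelength on-chip metalenses**
used for epi-fluorescence single-molecule sensing, with a full **Monte
Carlo diffusion-FCS** simulation chain.

A metalens on a photonic chip is an array of sub-wavelength silicon
nitride cylinders on a planar waveguide that scatters the guided wave into
a free-space focus. Because the guided mode's propagation constant
β(λ) is strongly dispersive, a single-wavelength design focuses the
fluorophore's red-shifted emission micrometres away from the excitation
focus — which breaks epi-fluorescence detection. The package implements
the segmented remedy: the aperture is split into alternating stripes, and
each stripe's meta-atoms are placed where the accumulated waveguide phase
matches the hyperbolic lens phase at one of the two design wavelengths,

```
φ_wg(x, y)  = β(λ_i) x + φ_input(y, λ_i)
φ_lens(x,y) = (2π n / λ_i) (F − √(F² + x² + y²)),   NA = n sin(arctan(D/2F))
atoms at      φ_wg ≡ φ_lens (mod 2π)
```

and then evaluates the design end to end, for people who want numbers an
instrument builder cares about:

* **Waveguide physics** — dispersion tables (SiN / SOG / water), TE0/TM0
  slab effective indices, single-mode V parameter, grating outcoupling
  relation, taper profile.
* **Design** — stripe segmentation, phase-matched meta-atom placement by
  bracketed root finding (validated against a dense-scan oracle), layout
  CSV export.
* **Scalar PSFs** — band-limited angular-spectrum propagation through the
  SOG/water stack; FWHM, focal position, encircled energy, and
  excitation/collection overlap metrics.
* **Photophysics** — spectrum-weighted collection efficiency, molecule
  detection efficiency MDE = I_exc · CEF, effective volume
  V_eff = π^{3/2} w_xy² w_z, photon budget N_F = MDE·ψ·S̄₁·k_fl.
* **FCS** — lattice Brownian dynamics (300 molecules, 2.4 µm box, 50 nm
  cells, 30 s), Poisson photon traces, a multi-tau correlator with
  block-averaged errors, and weighted 3D-diffusion fits
  G(τ) = G_∞ + (1/N)(1+τ/τ_D)⁻¹(1+τ/(s²τ_D))^{−1/2}.

## Worked example

Design the Alexa 555 lens (520/570 nm), check its focal quality, and
run an FCS experiment through a 0.17 fl detection volume:

```r
library(metafcs)

design <- metalens_design(520, 570)
design
#> metalens_design: D = 20 um, F = 6.796 um, NA = 1.100
#>   lambda = 520 / 570 nm, 5 stripe pairs, 3199 meta-atoms

psf1 <- propagate_stack(synthesize_aperture_field(design, 520))
psf2 <- propagate_stack(synthesize_aperture_field(design, 570))
psf_metrics(psf1)$fwhm_x_nm        # lateral FWHM at the excitation focus
#> [1] 245.7
focal_overlap(psf1, psf2)$delta_z_nm   # axial chromatic mismatch
#> [1] 2.0

cfg   <- diffusion_sim_config(seed = 1)      # 300 molecules, 36 nM, 30 s
mde   <- gaussian_mde(w_xy_um = 0.18, w_z_um = 0.942)  # 0.17 fl volume
trace <- fcs_experiment(cfg, mde, peak_rate = 5400)    # counts/s per molecule
fit   <- fit_3d_diffusion(autocorrelate(trace),
                          init = list(s_ratio = 0.942 / 0.18), fix_s = TRUE)
fit
#> 3D-diffusion FCS fit: N = 3.402, tau_D = 6.84e-05 s, s = 5.23, G_inf = -6.27e-04
```

Reading the numbers: the 246 nm focal width is the diffraction-limited
performance of an NA 1.1 water-immersion focus at 520 nm; the 2 nm axial
mismatch between the 520 and 570 nm foci is what the stripe segmentation
buys (an unsegmented control design, `segmented = FALSE`, shows a
~2.5 µm walk-off instead). The fitted occupancy N ≈ 3.4 matches
36 nM × 0.17 fl × N_A = 3.69 molecules within the seed scatter, and
τ_D ≈ 68 µs tracks w_xy²/4D = 81 µs up to the finite-box bias discussed
in the vignette.

The whole chain — design, PSFs, MDE, photon budget, FCS, summary JSON —
can also be driven from a YAML config via `run_pipeline()`, or from the
shell through the thin CLI at `inst/cli/metafcs.R`
(subcommands `design`, `propagate`, `mde`, `fcs`, `run`, `fixtures`).

## Package layout

```
R/materials.R      dispersion, slab modes, V parameter, grating, taper
R/metalens.R       lens phase, segmentation, meta-atom placement, export
R/propagation.R    angular-spectrum propagation, PSF volumes and metrics
R/photophysics.R   CEF, MDE, effective volume, photon budget
R/fcs.R            diffusion simulation, correlator, model fits
R/fixtures.R       synthetic fluorophore spectra (ATTO 490LS, Alexa 555,
                   APC-Cy7) with packaged ψ and τ_fl
R/pipeline.R       YAML config + end-to-end orchestration
src/fcs.cpp        fused diffusion/photon loop and multi-tau correlator
vignettes/         the methods vignette (model, assumptions, limitations)
```
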