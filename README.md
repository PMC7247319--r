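# membind

Quantitative analysis of cationic peptide binding to anionic lipid
bilayers, and of what that binding does to membrane surface
electrostatics and interfacial ion distributions.

Mitochondria-targeted Szeto–Schiller peptides (net charge +3) bind the
anionic lipids of the mitochondrial inner membrane — cardiolipin in
particular — and attenuate its surface potential. membind implements the
full analysis chain needed to characterize such systems from titration
data:

* **Binding isotherms** — the exact single-site Langmuir quadratic
  (free-ligand depletion included): `PB = 2PS / (P + S + K_D + √((P + S +
  K_D)² − 4PS))`, with `S = L_eff/n` saturable sites; nonlinear fits for
  peptide-into-lipid and lipid-into-peptide titrations, global salt-series
  fits with a shared saturation point, Scatchard transforms (slope
  `−1/K_D`, x-intercept `1/n`) and molar partition coefficients.
* **Gouy–Chapman–Stern electrostatics** — the mixed-valence Grahame
  relation `σ = sign(ψ₀)√(2ε_rε₀RT Σ C_i[e^(−z_iFψ₀/RT) − 1])` with
  Langmuir-type Stern charge regulation, Debye screening, zeta-potential
  conversions (Helmholtz–Smoluchowski; shear plane at 2 Å), and
  potential/ion-distribution profiles of the diffuse double layer.
* **ITC** — a one-site lipid-into-peptide forward model with perfusion
  dilution, Wiseman-plot fitting, and the decomposition
  `ΔG = −RT ln K_A = ΔH − TΔS`.
* **Fluorescence statistics** — generalized polarization (laurdan and
  three-wavelength prodan forms), G-factor-corrected steady-state
  anisotropy, Stern–Volmer quenching, hyperbolic/Hill saturation fits.
* **Interfacial calcium competition** — a coupled equilibrium of Ca²⁺
  among bulk, a 1:1 indicator, and the charged membrane interface
  (diffuse-layer excess + Stern binding), showing how bound peptide
  releases sequestered Ca²⁺.
* **Synthetic data** — seeded generators for all of the above, used by the
  parameter-recovery test suites.

## Worked example

A membrane with 20 mol% tetraoleoyl-cardiolipin in POPC, in 20 mM 1:1
salt:

```r
library(membind)

mem  <- membrane_spec(c(TOCL = 0.2, POPC = 0.8))
salt <- electrolyte(c("K", "Cl"), c(1, -1), c(0.02, 0.02))

mean_lipid_area(mem)                      # 82        (A^2, ideal mixing)
intrinsic_surface_charge_density(mem)     # -0.07815  (C/m^2, fully ionized)
binding_site_area(6.9, mem)               # 565.8     (A^2 for n = 6.9)
anionic_lipids_per_peptide(6.9, mem)      # 1.38      (dianionic lipids/peptide)

bare <- solve_surface_potential(intrinsic_surface_charge_density(mem), salt)
bare
#> <electrostatic_state> sigma=-0.0781 C/m^2 (max -0.0781), psi0=-115.8 mV,
#> zeta=-97.2 mV, 1/kappa=2.15 nm
```

The surface potential of the bare membrane is −116 mV. Saturating the
membrane with a +3 peptide attenuates the charge; zeta measurements of
this system saturate near −30 mV (no charge reversal), so the bound state
is pinned there and the divalent-cation enhancement at the surface
collapses:

```r
bound <- solve_surface_potential(grahame_sigma(-0.030, salt), salt)
divalent_accumulation_ratio(bare, bound)  # 794.7 -- nearly three orders
                                          # of magnitude less surface Ca2+
```

Fitting a synthetic peptide titration generated at the published design
(effective lipid 25–125 uM, 1% multiplicative noise) recovers the
generating stoichiometry:

```r
truth <- binding_params(6.9, 2.0e-6 / 6.9, "peptide_into_lipid")
series <- lapply(c(25, 50, 75, 100, 125) * 1e-6, function(L)
  gen_fluorescence_titration(truth, titration_design("peptide_into_lipid", L),
                             synth_config(seed = 1, noise_scale = 0.01)))
fit_peptide_titration(series)
#> <binding_parameters> (peptide_into_lipid) n=6.91 K_D=2.82e-07 M
#> nK_D=1.95e-06 M rss=0.0104
```

`n` is the number of lipids per bound peptide and `nK_D` the per-lipid
dissociation constant (2 uM here — micromolar affinity, as expected for a
peptide on a fluid anionic bilayer).

## Command-line pipeline

Every stage is also available through a JSON-configured entry point
(`run_pipeline()` in R, or the installed `inst/cli/membind` script):

```sh
Rscript inst/cli/membind --config run.json
```

with e.g. `{"task": "gcs", "membrane": {"fractions": {"TOCL": 0.2, "POPC":
0.8}}, "electrolyte": {"name": ["K","Cl"], "z": [1,-1], "conc":
[0.02,0.02]}, "output_dir": "out"}`. Reports echo the full config so runs
are reproducible bit-for-bit.

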