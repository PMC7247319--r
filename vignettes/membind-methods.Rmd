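---
title: "Models and methods in membind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in membind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membind)
```

membind models the equilibrium interaction of short polycationic peptides
(formal charge +3) with anionic phospholipid vesicles, and the electrostatic
consequences of that binding for the membrane surface and for interfacial
ion distributions. This vignette records the models, their assumptions, the
tunable parameters, and the design decisions taken where the published
methodology left the choice open.

## Membranes

A bilayer is an ideal mixture of lipid species, each carrying a formal
headgroup charge (0, −1 or −2 elementary charges, assuming full ionization
at pH 7.5 — cardiolipins are treated as dianionic throughout) and an
approximate cross-sectional area. The shipped species table uses 70 Å² for
POPC and POPG, 130 Å² for TOCL and 110 Å² for MLCL; these are data, not
constants, and every field can be overridden per species because such areas
are literature approximations with real spread. The intrinsic (fully
ionized) surface charge density is

σ_max = (Σᵢ fᵢ qᵢ e) / (Σᵢ fᵢ Aᵢ),

e.g. −0.078 C/m² for 20 mol% TOCL in POPC. Only the outer leaflet of a
unilamellar vesicle is peptide-accessible, so every "effective" lipid
concentration is half the total.

## Binding isotherms

Binding is single-site Langmuir: the membrane presents L_eff/n saturable
sites (n lipids per bound peptide), with per-site dissociation constant K_D.
The bound concentration is the exact quadratic root of the mass-action
equation — free-peptide depletion is **not** approximated away, because
fluorescence titrations in this system run near stoichiometric conditions
where the free ≈ total shortcut fails badly. Peptide titrations report the
per-site K_D and the per-lipid constant nK_D; lipid titrations are
parameterized directly in the per-lipid constant.

The published fits use equations from supporting material that is not
available verbatim; the exact single-site quadratic, the standard
Scatchard transform (slope −1/K_D, x-intercept 1/n), and both common
partition-coefficient conventions are implemented instead, and every output
records which convention produced it. The `water_normalized` convention
(f_b = K_P·L_eff/(55.3 M + K_P·L_eff)) is the default because the printed
partition coefficients (~5×10⁴, dimensionless) are on that scale.

Fitting uses a compact damped (Levenberg–Marquardt) least-squares engine
written for this package: the environment provides no Levenberg–Marquardt
library and `stats::nls` refuses zero-residual problems, which the
self-consistency tests require. Positive parameters are fitted on the log
scale; the linear signal amplitudes are profiled out by variable projection,
which leaves a two-parameter nonlinear problem that converges from a small
log-spaced multistart grid even for ill-conditioned near-stoichiometric
isotherms. Parameter errors come from the Jacobian at the optimum. Flat
signals (zwitterionic-only membranes, or a saturation ratio r ≈ 1) are
flagged as unidentifiable rather than reported.

Global salt-series fits share the saturation point r across series — the
published isotherms at high salt do not reach saturation, so r is only
identified jointly — while n and K_D remain per-series.

## Gouy–Chapman–Stern electrostatics

The diffuse double layer is described by the mixed-valence Grahame relation

σ(ψ₀) = sign(ψ₀) √(2 ε_r ε₀ R T Σᵢ C_i∞ [exp(−z_i F ψ₀ / RT) − 1]),

and Stern adsorption regulates the intrinsic charge through a Langmuir
denominator, σ = σ_max / (1 + Σⱼ K_j C_j(0)), with surface concentrations
C_j(0) = C_j∞ exp(−z_j F ψ₀/RT). The two are solved simultaneously by a
bracketed root-finder on ψ₀ ∈ [−0.5, 0.5] V to 10⁻⁹ V; robustness was
preferred over speed at these scales. Default intrinsic constants are
0.6 M⁻¹ for Na⁺/K⁺ and 12 M⁻¹ for Ca²⁺ — the standard values of the
charged-bilayer literature — and both are configuration-exposed, because
the exact constants behind the published model figures are not recoverable.

Zeta potentials convert from electrophoretic mobility by
Helmholtz–Smoluchowski (ζ = μη/ε_rε₀, η = 0.89 mPa·s, ε_r = 78.5 by
default) and relate to ψ₀ through the analytic Gouy decay with the shear
plane at x = 2 Å (overridable). The inversion uses the closed tanh form, so
the forward–inverse round trip is exact to the 10⁻¹² V level checked in the
tests. Potential profiles use the analytic Gouy solution for symmetric
electrolytes and a fixed-step RK4 integration of the Poisson–Boltzmann
first integral for mixed valences; the two agree to better than 10⁻⁶ V for
1:1 electrolytes.

Bound peptide enters as surface-charge neutralization, not as a Stern
species: σ_eff = σ_lipid + θ·(+3e)/(n·Ā). At full occupancy this would
overcompensate the lipid charge, but zeta measurements of this system
saturate near −30 mV without reversal; since the published account offers
two nonexclusive mechanisms without choosing, the non-reversal is
implemented as a modeling switch — a ψ₀ floor, default −30 mV and on,
logged whenever it engages — rather than as a mechanism. Disabling the
floor permits and reports sign reversal. The floor lives on
`solve_surface_potential()` because it is defined on the downstream
potential, which the pure σ arithmetic cannot evaluate.

## Isothermal titration calorimetry

Lipid-into-peptide ITC is forward-modeled per injection with the standard
perfusion (overflow) correction: each injection of volume v multiplies
prior cell contents by (1 − v/V₀) before delivering syringe lipid (8 mM
total, half effective). Heat of injection j is Q_j = ΔH·V₀·(B_j −
B_{j−1}(1 − v_j/V₀)) with B the bound concentration from the same binding
quadratic as the fluorescence module. The peptide cell concentration
defaults to 131.25 μM, the midpoint of the published 87.5–175 μM working
range. Fits run over (K_A, n, ΔH) with K_A, n log-scaled; ΔG = −RT ln(K_A·c°)
at c° = 1 M (recorded explicitly, since standard-state ambiguity is the
usual source of confusion), ΔS follows from ΔG = ΔH − TΔS. A first-injection
discard is available as a flag but off by default — common practice, but not
stated in the published protocol. c-values outside ~1–1000 trigger a
featureless-curve warning.

## Interfacial calcium competition

The calcium model couples three sinks for total Ca²⁺: free solution, a 1:1
fluorescent indicator, and the membrane interface. The interfacial term
combines the diffuse-layer Boltzmann excess (integrated over the double
layer via the Poisson–Boltzmann first integral) and Stern-bound Ca²⁺ (the
calcium share of the Langmuir-regulated intrinsic charge, one cation per
anionic site); the two mechanisms can be disabled independently to probe
either. Free calcium is root-found to satisfy mass balance to ~10⁻¹²
absolute, with the GCS state recomputed self-consistently at each candidate
(added CaCl₂ keeps the electrolyte electroneutral). The indicator
dissociation constant is not published for this system; the default 14 μM is
vendor-typical for low-affinity indicators and is mandatory-visible in the
configuration, and the package's acceptance surface deliberately uses only
ratios and monotonicity, never the absolute K_d. Peptide acts purely through
surface-charge modification — the electrostatic interpretation — not through
competitive site binding.

## Synthetic data

The generators state a world and stay there: peptide titrations default to
4-nmol increments (2 μM steps in a 2-mL cuvette, a standard fluorimeter
geometry chosen once here since the cuvette volume is not printed) at
effective lipid 25–125 μM; lipid titrations to 30-nmol total-lipid
increments into ~10 μM peptide; ITC to the printed 170 μL cell / 20 × 2.5 μL
schedule. Fluorescence noise is 1% multiplicative Gaussian, ITC noise 2% of
the largest heat, additive — plausible instrument scales used by the
parameter-recovery criteria. All generators are pure functions of
(parameters, design, seed); replicate k reuses seed + k − 1. What a green
recovery test establishes is that the estimators are unbiased *under the
stated noise model and design*; real titrations add baseline drift,
photobleaching and dilution artifacts that are deliberately not modeled.

## Numerical choices and limitations

* Root-finding is bracketed (Brent) everywhere; no derivatives required.
* The binding quadratic is guarded against catastrophic cancellation by
  clamping to [0, min(P, S)]; agreement with an independent scalar
  root-finder is tested at 10⁻¹⁰ relative over 10⁴ random draws.
* The RK4 profile integrator subdivides steps to ≥ 50 per Debye length;
  accuracy ~10⁻⁹ V in practice against the analytic solution.
* No multi-site or cooperative binding beyond the Hill option for
  saturation curves; no kinetics; no curvature, image-charge or
  dielectric-saturation corrections to the planar double layer; vesicles
  are treated as planes (radius ≫ Debye length).
* Scatchard fits inherit the transform's known noise distortion; they are
  provided for comparability, and the nonlinear fits are authoritative.
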