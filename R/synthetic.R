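# Seeded generators emulating every experimental input the fitters consume:
# fluorescence binding titrations (both directions), one-site ITC
# thermograms, zeta/ANS charge-attenuation series, and calcium-indicator
# titrations with membrane sequestration. All generators are pure functions
# of (parameters, design, seed); noise-free outputs equal the forward models
# bit-for-bit.

#' Synthetic-data configuration
#'
#' @param seed Integer seed; replicate k of a multi-replicate call uses
#'   `seed + k - 1`.
#' @param noise_model `"multiplicative_gaussian"` (scale is relative) or
#'   `"additive_gaussian"` (scale is absolute, or relative to the signal
#'   range for the ITC generator).
#' @param noise_scale Non-negative noise scale (default 0.01 = 1%).
#' @param replicates Number of replicates (default 1).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         noise_model = c("multiplicative_gaussian",
                                         "additive_gaussian"),
                         noise_scale = 0.01, replicates = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale, replicates = as.integer(replicates)),
            class = "synth_config")
}

#' Construct binding parameters for forward simulation
#'
#' @param n Lipids per bound peptide.
#' @param K_D Dissociation constant (M): per-site for
#'   `peptide_into_lipid`, per-lipid-monomer for `lipid_into_peptide`.
#' @param mode Titration direction the parameters describe.
#' @param c_f,c_b Free/bound signal coefficients (peptide titrations).
#' @param r Saturation fluorescence ratio F_inf/F_0 (lipid titrations).
#' @return A `binding_parameters` object usable as a generator input.
#' @export
binding_params <- function(n, K_D,
                           mode = c("peptide_into_lipid", "lipid_into_peptide"),
                           c_f = 1e4, c_b = 1e5, r = 3) {
  mode <- match.arg(mode)
  if (n <= 0 || K_D <= 0) stop("n and K_D must be positive")
  structure(list(n = n, K_D = K_D,
                 nK_D = if (mode == "peptide_into_lipid") n * K_D else K_D,
                 K_P = NA_real_, c_f = c_f, c_b = c_b, r = r, se = NULL,
                 rss = NA_real_, identifiable = TRUE, converged = TRUE,
                 mode = mode),
            class = "binding_parameters")
}

#' Titration sampling design
#'
#' Defaults mirror a standard cuvette protocol: peptide titrations add 4-nmol
#' increments to a 2-mL cuvette (2 uM steps, 20 additions) at effective
#' lipid 25-125 uM; lipid titrations add 30-nmol total-lipid increments
#' (15 uM total = 7.5 uM effective steps) to ~10 uM peptide.
#'
#' @param mode Titration direction.
#' @param fixed_species_total Fixed species (M): effective lipid for peptide
#'   titrations, total peptide for lipid titrations.
#' @param titrant_totals Titrant axis (M); effective lipid when the titrant
#'   is lipid.
#' @return List of class `titration_design`.
#' @export
titration_design <- function(mode = c("peptide_into_lipid", "lipid_into_peptide"),
                             fixed_species_total = NULL,
                             titrant_totals = NULL) {
  mode <- match.arg(mode)
  if (is.null(fixed_species_total))
    fixed_species_total <- if (mode == "peptide_into_lipid") 125e-6 else 10e-6
  if (is.null(titrant_totals))
    titrant_totals <- if (mode == "peptide_into_lipid")
      seq(2e-6, 40e-6, by = 2e-6) else seq(7.5e-6, 150e-6, by = 7.5e-6)
  structure(list(mode = mode, fixed_species_total = fixed_species_total,
                 titrant_totals = titrant_totals),
            class = "titration_design")
}

# internal: apply the configured noise to a clean signal using replicate seed
.apply_noise <- function(y, config, replicate = 1L, absolute_scale = NULL) {
  if (config$noise_scale == 0) return(y)
  withr::with_seed(config$seed + replicate - 1L, {
    if (config$noise_model == "multiplicative_gaussian")
      y * (1 + config$noise_scale * stats::rnorm(length(y)))
    else {
      s <- if (is.null(absolute_scale)) config$noise_scale
           else config$noise_scale * absolute_scale
      y + s * stats::rnorm(length(y))
    }
  })
}

#' Generate a synthetic fluorescence binding titration
#'
#' Forward-models the configured titration direction with the exact
#' single-site quadratic and applies the configured noise. Deterministic for
#' a fixed seed.
#'
#' @param params [binding_params()] (mode must match the design).
#' @param design A [titration_design()].
#' @param config A [synth_config()].
#' @return A [titration_series] (or a list of them when
#'   `config$replicates > 1`).
#' @export
gen_fluorescence_titration <- function(params, design = titration_design(),
                                       config = synth_config()) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(design, "titration_design"))
  if (params$mode != design$mode)
    stop("params mode (", params$mode, ") does not match design mode (",
         design$mode, ")")
  clean <- if (design$mode == "peptide_into_lipid") {
    P <- design$titrant_totals
    PB <- bound_peptide(P, design$fixed_species_total, params$n, params$K_D)
    params$c_f * (P - PB) + params$c_b * PB
  } else {
    P <- design$fixed_species_total
    PB <- bound_peptide(P, design$titrant_totals, params$n,
                        params$K_D / params$n)
    1 + (params$r - 1) * PB / P
  }
  mk <- function(k) titration_series(design$mode, design$fixed_species_total,
                                     design$titrant_totals,
                                     .apply_noise(clean, config, k))
  if (config$replicates == 1L) mk(1L) else lapply(seq_len(config$replicates), mk)
}

#' Generate a synthetic ITC thermogram
#'
#' [simulate_heats()] plus additive Gaussian noise scaled to the largest
#' heat magnitude.
#'
#' @param params An [itc_params()] object.
#' @param experiment An [itc_experiment()].
#' @param config A [synth_config()]; additive noise is used regardless of
#'   `noise_model`, with scale relative to `max(|Q|)`.
#' @return The experiment with its `heats` field filled (list of experiments
#'   when `config$replicates > 1`).
#' @export
gen_itc <- function(params, experiment = itc_experiment(),
                    config = synth_config()) {
  clean <- simulate_heats(experiment, params)
  qmax <- max(abs(clean))
  mk <- function(k) {
    e <- experiment
    h <- as.numeric(clean)
    if (config$noise_scale > 0)
      h <- withr::with_seed(config$seed + k - 1L,
                            h + config$noise_scale * qmax *
                              stats::rnorm(length(h)))
    e$heats <- h
    e
  }
  if (config$replicates == 1L) mk(1L) else lapply(seq_len(config$replicates), mk)
}

#' Generate a synthetic charge-attenuation dose series (zeta or ANS)
#'
#' Maps a peptide dose axis (peptide per effective lipid) to a binding-site
#' occupancy through a hyperbolic or Hill law, pushes each occupancy through
#' the GCS chain (peptide-attenuated sigma -> charge-regulated psi0, with the
#' non-reversal floor) and reads out either the shear-plane zeta potential
#' (mV) or a saturating ANS-fluorescence proxy that increases as the surface
#' potential magnitude falls.
#'
#' @param membrane A [membrane_spec].
#' @param elec An [electrolyte].
#' @param doses Peptide/effective-lipid molar ratios (strictly increasing).
#' @param readout `"zeta"` (mV) or `"ans"` (relative fluorescence).
#' @param config A [synth_config()].
#' @param occupancy_shape `"hyperbolic"` or `"hill"` dose-to-occupancy law.
#' @param half_dose Dose at half occupancy (default 0.05 = 1:20 P/L_eff).
#' @param hill Hill coefficient for the sigmoidal option (default 2).
#' @param n Lipids per bound peptide (default 6.9).
#' @param peptide_valence Default +3.
#' @param psi_floor Non-reversal floor (V; default -0.030).
#' @param ans_amplitude Saturating amplitude of the ANS proxy (default 2).
#' @return data.frame `dose`, `occupancy`, `signal` with attribute
#'   `"readout"`.
#' @export
gen_charge_attenuation_series <- function(membrane, elec,
                                          doses = seq(0, 0.25, by = 0.0125),
                                          readout = c("zeta", "ans"),
                                          config = synth_config(),
                                          occupancy_shape = c("hyperbolic", "hill"),
                                          half_dose = 0.05, hill = 2,
                                          n = 6.9, peptide_valence = 3,
                                          psi_floor = -0.030,
                                          ans_amplitude = 2) {
  readout <- match.arg(readout)
  occupancy_shape <- match.arg(occupancy_shape)
  stopifnot(inherits(membrane, "membrane_spec"), inherits(elec, "electrolyte"))
  h <- if (occupancy_shape == "hyperbolic") 1 else hill
  occ <- doses^h / (half_dose^h + doses^h)
  occ[doses == 0] <- 0
  area <- mean_lipid_area(membrane)
  sigma0 <- intrinsic_surface_charge_density(membrane)
  states <- lapply(occ, function(o) {
    s_eff <- peptide_modified_sigma(sigma0, o, n, area, peptide_valence)
    suppressMessages(solve_surface_potential(
      s_eff, elec, temperature = membrane$temperature, psi_floor = psi_floor))
  })
  psi <- vapply(states, `[[`, numeric(1), "psi0")
  signal <- if (readout == "zeta") {
    vapply(states, `[[`, numeric(1), "zeta") * 1e3
  } else {
    1 + ans_amplitude * (1 - psi / psi[1])
  }
  signal <- .apply_noise(signal, config)
  out <- data.frame(dose = doses, occupancy = occ, signal = signal)
  attr(out, "readout") <- readout
  out
}

#' Generate a synthetic calcium-indicator titration
#'
#' Solves the coupled probe/membrane equilibrium at each total-calcium level
#' and applies the configured noise to the normalized indicator signal.
#'
#' @param base A [calcium_assay()] state (its `Ca_total` is swept).
#' @param Ca_totals Total calcium grid (M).
#' @param config A [synth_config()].
#' @return data.frame `titrant_conc` (total Ca, M), `signal` (normalized
#'   indicator response).
#' @export
gen_calcium_titration <- function(base, Ca_totals = seq(0, 100e-6, by = 5e-6),
                                  config = synth_config()) {
  stopifnot(inherits(base, "calcium_assay_state"))
  clean <- vapply(Ca_totals, function(ca) {
    st <- base
    st$Ca_total <- ca
    solve_assay(st)$predicted_signal
  }, numeric(1))
  data.frame(titrant_conc = Ca_totals,
             signal = .apply_noise(clean, config))
}
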