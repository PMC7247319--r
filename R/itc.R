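# Isothermal titration calorimetry, lipid-into-peptide direction: forward
# model of per-injection heats with perfusion (overflow) dilution, Wiseman
# representation, one-site nonlinear fitting and the thermodynamic
# decomposition dG = -RT ln K_A = dH - T dS.

#' Describe an ITC experiment
#'
#' Lipid-into-peptide geometry: vesicles in the syringe are injected into a
#' fixed-volume cell containing peptide. Only the outer leaflet of the
#' injected vesicles is peptide-accessible, so the effective syringe lipid is
#' half the total.
#'
#' @param peptide_cell_conc Initial peptide in the cell (M). Default
#'   131.25e-6, the midpoint of a typical 87.5-175 uM working range.
#' @param cell_volume Cell volume (L, default 170e-6).
#' @param syringe_lipid_total Total lipid in the syringe (M, default 8e-3);
#'   the effective concentration used by the model is half this.
#' @param injection_volumes Injection volumes (L); default 20 x 2.5 uL.
#' @param temperature K (default 298.15).
#' @param heats Optional observed integrated heats (J), one per injection.
#' @return Object of class `itc_experiment`.
#' @export
itc_experiment <- function(peptide_cell_conc = 131.25e-6,
                           cell_volume = 170e-6,
                           syringe_lipid_total = 8e-3,
                           injection_volumes = rep(2.5e-6, 20L),
                           temperature = 298.15,
                           heats = NULL) {
  if (cell_volume <= 0 || any(injection_volumes <= 0))
    stop("volumes must be positive")
  if (peptide_cell_conc < 0 || syringe_lipid_total < 0)
    stop("concentrations must be >= 0")
  if (!is.null(heats) && length(heats) != length(injection_volumes))
    stop("heats must have one value per injection")
  if (sum(injection_volumes) > cell_volume)
    warning("cumulative injected volume exceeds the cell volume; ",
            "the perfusion dilution model is unreliable here")
  structure(list(peptide_cell_conc = peptide_cell_conc,
                 cell_volume = cell_volume,
                 syringe_lipid_total = syringe_lipid_total,
                 syringe_lipid_eff = syringe_lipid_total / 2,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature, heats = heats),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("<itc_experiment> %d injections, cell %.3g uL, [P]=%.3g uM, syringe lipid %.3g mM%s\n",
              length(x$injection_volumes), x$cell_volume * 1e6,
              x$peptide_cell_conc * 1e6, x$syringe_lipid_total * 1e3,
              if (is.null(x$heats)) "" else " (+heats)"))
  invisible(x)
}

#' One-site thermodynamic parameter set
#'
#' @param K_A Association constant (M^-1, per lipid site of n lipids).
#' @param n Lipids per bound peptide.
#' @param dH Binding enthalpy (J/mol of peptide).
#' @param temperature K.
#' @param se Optional named standard errors.
#' @return Object of class `itc_thermodynamics` carrying `K_A`, `K_D`, `n`,
#'   `dH`, `dG`, `dS`, `minus_TdS` (all J-based SI units).
#' @export
itc_params <- function(K_A, n, dH, temperature = 298.15, se = NULL) {
  if (K_A <= 0) stop("K_A must be positive")
  if (n <= 0) stop("n must be positive")
  td <- thermodynamic_decomposition(K_A, dH, temperature)
  structure(list(K_A = K_A, K_D = 1 / K_A, n = n, dH = dH,
                 dG = td$dG, dS = td$dS, minus_TdS = td$minus_TdS,
                 temperature = temperature, se = se),
            class = "itc_thermodynamics")
}

#' @export
print.itc_thermodynamics <- function(x, ...) {
  cat(sprintf(paste0("<itc_thermodynamics> K_A=%.3g /M (K_D=%.3g M), n=%.3g, ",
                     "dH=%.3g kJ/mol, dG=%.3g kJ/mol, -TdS=%.3g kJ/mol\n"),
              x$K_A, x$K_D, x$n, x$dH / 1e3, x$dG / 1e3, x$minus_TdS / 1e3))
  invisible(x)
}

#' Simulate per-injection ITC heats
#'
#' Forward model. Each injection of volume v displaces cell contents
#' (multiplying prior concentrations by `1 - v/V0`) and delivers syringe
#' lipid; bound peptide is the exact single-site quadratic shared with the
#' binding module, and the heat of injection j is
#' `Q_j = dH * V0 * (B_j - B_{j-1} (1 - v_j/V0))`.
#'
#' @param experiment An [itc_experiment].
#' @param params An [itc_params] object (`K_A` per site of `n` lipids, `dH`
#'   in J/mol).
#' @return Numeric vector of heats (J), one per injection, with attribute
#'   `"molar_ratio"` (cumulative effective lipid / peptide in the cell) and
#'   `"bound"` (bound peptide, M, after each injection).
#' @export
simulate_heats <- function(experiment, params) {
  stopifnot(inherits(experiment, "itc_experiment"),
            inherits(params, "itc_thermodynamics"))
  V0 <- experiment$cell_volume
  P <- experiment$peptide_cell_conc
  L <- 0
  B_prev <- bound_peptide(P, L, params$n, params$K_D)
  Q <- ratio <- Bout <- numeric(length(experiment$injection_volumes))
  for (j in seq_along(Q)) {
    v <- experiment$injection_volumes[j]
    d <- 1 - v / V0
    P <- P * d
    L <- L * d + experiment$syringe_lipid_eff * v / V0
    B <- bound_peptide(P, L, params$n, params$K_D)
    Q[j] <- params$dH * V0 * (B - B_prev * d)
    ratio[j] <- L / P
    Bout[j] <- B
    B_prev <- B
  }
  attr(Q, "molar_ratio") <- ratio
  attr(Q, "bound") <- Bout
  Q
}

#' Wiseman representation of an ITC data set
#'
#' Converts per-injection heats to heat per mole of injected effective lipid
#' against the cumulative molar ratio `[L]_eff/[P]` in the cell.
#'
#' @param experiment An [itc_experiment] with `heats`, or heats passed
#'   explicitly.
#' @param heats Optional heats (J) overriding `experiment$heats`.
#' @return data.frame with `molar_ratio`, `ndh` (J per mole of injectant).
#' @export
wiseman_plot <- function(experiment, heats = NULL) {
  stopifnot(inherits(experiment, "itc_experiment"))
  if (is.null(heats)) heats <- experiment$heats
  if (is.null(heats)) stop("no heats available")
  V0 <- experiment$cell_volume
  P <- experiment$peptide_cell_conc
  L <- 0
  ratio <- numeric(length(heats))
  mol_inj <- experiment$injection_volumes * experiment$syringe_lipid_eff
  for (j in seq_along(heats)) {
    v <- experiment$injection_volumes[j]
    d <- 1 - v / V0
    P <- P * d
    L <- L * d + experiment$syringe_lipid_eff * v / V0
    ratio[j] <- L / P
  }
  data.frame(molar_ratio = ratio, ndh = heats / mol_inj)
}

#' Fit a one-site model to ITC heats (Wiseman fitting)
#'
#' Least-squares fit of [simulate_heats()] to observed integrated heats over
#' `(K_A, n, dH)`, with `K_A` and `n` on the log scale and multistart on
#' `K_A`. Derives `dG = -RT ln(K_A c0)` (standard state c0 = 1 M) and
#' `dS = (dH - dG)/T`.
#'
#' @param experiment An [itc_experiment] carrying observed `heats` (J).
#' @param discard_first Drop the first injection before fitting (common ITC
#'   practice for syringe diffusion artefacts; default FALSE).
#' @return An [itc_params()]-style `itc_thermodynamics` object with standard
#'   errors and `rss`.
#' @export
fit_wiseman <- function(experiment, discard_first = FALSE) {
  stopifnot(inherits(experiment, "itc_experiment"))
  heats <- experiment$heats
  if (is.null(heats)) stop("experiment carries no observed heats")
  keep <- seq_along(heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 8L) stop("need at least 8 informative injections")

  resid_fn <- function(par) {
    p <- itc_params(exp(par[1]), exp(par[2]), par[3],
                    experiment$temperature)
    (heats - simulate_heats(experiment, p))[keep]
  }
  # starts: total heat ~ dH * moles peptide bound; n from schedule midpoint
  Vtot <- sum(experiment$injection_volumes)
  dH0 <- sum(heats) / (experiment$cell_volume * experiment$peptide_cell_conc)
  Lend <- experiment$syringe_lipid_eff * Vtot / experiment$cell_volume
  n0 <- max(Lend / (2 * experiment$peptide_cell_conc), 0.5)
  starts <- lapply(c(1e3, 1e4, 1e5, 1e6), function(K)
    c(log(K), log(n0), if (abs(dH0) > 0) dH0 else -1e3))
  fit <- .lm_multistart(starts, resid_fn)
  if (!fit$converged) warning("ITC fit did not converge")
  K_A <- exp(fit$par[1]); n <- exp(fit$par[2]); dH <- fit$par[3]
  RT <- .const$R * experiment$temperature
  c_value <- experiment$peptide_cell_conc * K_A
  if (is.finite(c_value) && (c_value < 1 || c_value > 1e4))
    warning("c-value ", signif(c_value, 3),
            " outside the informative range ~1-1000; curve may be featureless")
  out <- itc_params(K_A, n, dH, experiment$temperature,
                    se = c(K_A = fit$se[1] * K_A, n = fit$se[2] * n,
                           dH = fit$se[3]))
  out$rss <- fit$rss
  out$converged <- fit$converged
  out
}

#' Thermodynamic decomposition of a binding constant and enthalpy
#'
#' `dG = -RT ln(K_A c0)` with standard state `c0 = 1 M`;
#' `dS = (dH - dG)/T`; `-T dS` reported alongside.
#'
#' @param K_A Association constant (M^-1, > 0).
#' @param dH Binding enthalpy (J/mol).
#' @param temperature K.
#' @return List with `dG`, `dS`, `minus_TdS` (J/mol, J/mol/K, J/mol).
#' @export
#' @examples
#' # dH = -4.2 kJ/mol with -TdS = -22.7 kJ/mol implies dG = -26.9 kJ/mol
#' thermodynamic_decomposition(5.2e4, -4200)
thermodynamic_decomposition <- function(K_A, dH, temperature = 298.15) {
  if (K_A <= 0) stop("K_A must be positive")
  dG <- -.const$R * temperature * log(K_A)  # c0 = 1 M
  dS <- (dH - dG) / temperature
  list(dG = dG, dS = dS, minus_TdS = -temperature * dS)
}
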