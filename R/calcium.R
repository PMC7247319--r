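# Coupled-equilibrium model of Ca2+ partitioning among bulk solution, a
# fluorescent indicator (1:1 binding), and the interfacial region of an
# anionic membrane (diffuse-layer Boltzmann excess + Stern-bound Ca2+),
# with the membrane charge optionally attenuated by bound cationic peptide.

#' Volume-equivalent surface excess of a cation
#'
#' Integrates the diffuse-layer excess of an ion over the double layer,
#' `Gamma = integral C_inf (exp(-z F psi(x)/RT) - 1) dx`, adds the
#' Stern-bound amount (Langmuir share of the regulated intrinsic charge), and
#' converts moles-per-area to a solution-equivalent molarity through the
#' total accessible membrane area `L_eff * N_A * mean_area`.
#'
#' @param state A solved [solve_surface_potential()] state whose electrolyte
#'   contains the ion.
#' @param L_eff Effective (outer-leaflet) lipid concentration (M).
#' @param mean_area Mean lipid cross-sectional area (Angstrom^2).
#' @param ion Name of the ion in the state's electrolyte (default `"Ca"`).
#' @param include_diffuse,include_stern Enable the two sequestration
#'   mechanisms independently (both default TRUE).
#' @return Excess concentration (M) sequestered at the interface.
#' @export
surface_calcium_excess <- function(state, L_eff, mean_area, ion = "Ca",
                                   include_diffuse = TRUE,
                                   include_stern = TRUE) {
  stopifnot(inherits(state, "electrostatic_state"))
  elec <- state$electrolyte
  i <- match(ion, elec$name)
  if (is.na(i)) stop("ion '", ion, "' not present in the electrolyte")
  if (L_eff < 0 || mean_area <= 0) stop("invalid L_eff or mean_area")
  if (L_eff == 0) return(0)
  RT <- .const$R * state$temperature
  eps <- state$eps_r * .const$eps0
  psi0 <- state$psi0

  gamma_diffuse <- 0
  if (include_diffuse && psi0 != 0 && elec$conc[i] > 0) {
    # change of variable x -> psi using the PB first integral
    dpsidx <- function(p) {
      s <- vapply(p, function(pp)
        sum(elec$conc * .M_TO_MOL_M3 *
              (exp(-elec$z * .const$F * pp / RT) - 1)), numeric(1))
      -sign(psi0) * sqrt(pmax(2 * RT / eps * s, 0))
    }
    integrand <- function(p) {
      num <- elec$conc[i] * .M_TO_MOL_M3 *
        (exp(-elec$z[i] * .const$F * p / RT) - 1)
      num / abs(dpsidx(p))
    }
    gamma_diffuse <- stats::integrate(integrand, min(psi0, 0), max(psi0, 0),
                                      rel.tol = 1e-9)$value  # mol/m^2
  }

  gamma_stern <- 0
  if (include_stern && elec$K[i] > 0 && state$sigma_max != 0) {
    C0 <- elec$conc * exp(-elec$z * .const$F * psi0 / RT)
    denom <- 1 + sum(elec$K[elec$K > 0] * C0[elec$K > 0])
    f_i <- elec$K[i] * C0[i] / denom
    gamma_stern <- f_i * abs(state$sigma_max) / .const$F  # mol of sites/m^2
  }

  area_per_litre <- L_eff * .const$Na * mean_area * .A2_TO_M2  # m^2 / L
  (gamma_diffuse + gamma_stern) * area_per_litre
}

#' Configure a calcium-indicator assay state
#'
#' Describes a cuvette containing a Ca2+ indicator (1:1 binding, low
#' affinity), vesicles of a given composition, a salt background, and
#' optionally membrane-bound cationic peptide at a given site occupancy.
#'
#' @param probe_total Total indicator concentration (M).
#' @param Ca_total Total calcium (M).
#' @param membrane A [membrane_spec].
#' @param L_eff Effective lipid concentration (M); 0 for probe-only.
#' @param electrolyte Background [electrolyte] *without* calcium; CaCl2 is
#'   added internally at the free-calcium level being solved.
#' @param probe_Kd Indicator dissociation constant (M, default 14e-6 - a
#'   vendor-typical low-affinity value; configurable).
#' @param peptide_occupancy Fraction of peptide binding sites occupied.
#' @param n Lipids per bound peptide (default 6.9).
#' @param peptide_valence Peptide formal charge (default +3).
#' @param K_Ca Stern association constant of Ca2+ (M^-1, default 12).
#' @param psi_floor Non-reversal floor passed to
#'   [solve_surface_potential()] (V; default -0.030, `NULL` to disable).
#' @param include_diffuse,include_stern Sequestration mechanism switches.
#' @return Object of class `calcium_assay_state` (unsolved).
#' @export
calcium_assay <- function(probe_total, Ca_total, membrane, L_eff, electrolyte,
                          probe_Kd = 14e-6, peptide_occupancy = 0, n = 6.9,
                          peptide_valence = 3, K_Ca = 12,
                          psi_floor = -0.030,
                          include_diffuse = TRUE, include_stern = TRUE) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(electrolyte, "electrolyte"))
  if ("Ca" %in% electrolyte$name)
    stop("background electrolyte must not contain Ca; it is added internally")
  if (probe_total < 0 || Ca_total < 0 || L_eff < 0 || probe_Kd <= 0)
    stop("invalid concentrations")
  if (peptide_occupancy < 0 || peptide_occupancy > 1)
    stop("occupancy must be in [0, 1]")
  structure(list(probe_total = probe_total, probe_Kd = probe_Kd,
                 Ca_total = Ca_total, membrane = membrane, L_eff = L_eff,
                 electrolyte = electrolyte,
                 peptide_occupancy = peptide_occupancy, n = n,
                 peptide_valence = peptide_valence, K_Ca = K_Ca,
                 psi_floor = psi_floor, include_diffuse = include_diffuse,
                 include_stern = include_stern, solved = FALSE),
            class = "calcium_assay_state")
}

# internal: electrolyte with CaCl2 at the candidate free level
.with_calcium <- function(background, Ca_free, K_Ca) {
  electrolyte(c(background$name, "Ca", "Cl_ca"),
              c(background$z, 2L, -1L),
              c(background$conc, Ca_free, 2 * Ca_free),
              c(background$K, K_Ca, 0))
}

#' Solve the coupled calcium-partitioning equilibrium
#'
#' Root-finds the free bulk Ca2+ satisfying the mass balance
#' `Ca_total = Ca_free + Ca_probe_bound + Ca_surface`, with probe binding
#' 1:1 and the surface excess recomputed self-consistently from the GCS
#' state (membrane charge attenuated by the configured peptide occupancy).
#'
#' @param state A [calcium_assay()] state.
#' @return The state with `solved = TRUE` and fields `Ca_free`,
#'   `Ca_probe_bound`, `Ca_surface` (M), `predicted_signal`
#'   (`Ca_probe_bound / probe_total`), `psi0` and `gcs_state`.
#' @export
solve_assay <- function(state) {
  stopifnot(inherits(state, "calcium_assay_state"))
  mean_area <- mean_lipid_area(state$membrane)
  sigma_lipid <- intrinsic_surface_charge_density(state$membrane)
  sigma_eff <- peptide_modified_sigma(sigma_lipid, state$peptide_occupancy,
                                      state$n, mean_area,
                                      state$peptide_valence)
  psi_floor <- state$psi_floor

  gcs_at <- function(Ca_free) {
    elec <- .with_calcium(state$electrolyte, Ca_free, state$K_Ca)
    suppressMessages(
      solve_surface_potential(sigma_eff, elec,
                              temperature = state$membrane$temperature,
                              psi_floor = psi_floor))
  }
  excess_at <- function(Ca_free) {
    if (state$L_eff == 0 || (sigma_eff == 0 && is.null(psi_floor)))
      return(list(ex = 0, st = NULL))
    st <- gcs_at(Ca_free)
    list(ex = surface_calcium_excess(st, state$L_eff, mean_area, ion = "Ca",
                                     include_diffuse = state$include_diffuse,
                                     include_stern = state$include_stern),
         st = st)
  }
  probe_bound <- function(Ca_free)
    state$probe_total * Ca_free / (state$probe_Kd + Ca_free)
  residual <- function(Ca_free)
    state$Ca_total - Ca_free - probe_bound(Ca_free) - excess_at(Ca_free)$ex

  if (state$Ca_total == 0) {
    Ca_free <- 0
  } else {
    root <- stats::uniroot(residual, c(0, state$Ca_total),
                           tol = 1e-15 * max(state$Ca_total, 1e-6),
                           maxiter = 2000L)
    Ca_free <- root$root
    # secant polish so the mass balance holds to ~1e-12 absolute
    for (k in 1:5) {
      r <- residual(Ca_free)
      if (abs(r) < 1e-13) break
      h <- max(1e-9 * Ca_free, 1e-15)
      dr <- (residual(Ca_free + h) - r) / h
      if (!is.finite(dr) || dr == 0) break
      Ca_free <- min(max(Ca_free - r / dr, 0), state$Ca_total)
    }
  }
  ex <- excess_at(Ca_free)
  state$Ca_free <- Ca_free
  state$Ca_probe_bound <- probe_bound(Ca_free)
  state$Ca_surface <- ex$ex
  state$predicted_signal <- if (state$probe_total > 0)
    state$Ca_probe_bound / state$probe_total else 0
  state$gcs_state <- ex$st
  state$psi0 <- if (is.null(ex$st)) 0 else ex$st$psi0
  state$solved <- TRUE
  state
}

#' @export
print.calcium_assay_state <- function(x, ...) {
  cat(sprintf("<calcium_assay_state> Ca_total=%.3g M, L_eff=%.3g M, occupancy=%.2f%s\n",
              x$Ca_total, x$L_eff, x$peptide_occupancy,
              if (isTRUE(x$solved))
                sprintf("; free=%.3g, probe=%.3g, surface=%.3g, signal=%.3f",
                        x$Ca_free, x$Ca_probe_bound, x$Ca_surface,
                        x$predicted_signal)
              else " (unsolved)"))
  invisible(x)
}

#' Peptide displacement of interfacial calcium
#'
#' Sweeps the peptide occupancy at otherwise fixed conditions and returns the
#' predicted indicator signal, which rises monotonically as bound peptide
#' attenuates the surface charge and releases sequestered Ca2+.
#'
#' @param base A [calcium_assay()] state (its occupancy field is ignored).
#' @param occupancies Occupancy grid in `[0, 1]`.
#' @return data.frame `occupancy`, `predicted_signal`, `Ca_surface`, `psi0`;
#'   attribute `"occupancy_95"` holds the (interpolated) occupancy at 95% of
#'   the signal rise to the asymptote.
#' @export
peptide_displacement_curve <- function(base, occupancies = seq(0, 1, 0.1)) {
  stopifnot(inherits(base, "calcium_assay_state"))
  rows <- lapply(occupancies, function(occ) {
    st <- base
    st$peptide_occupancy <- occ
    st <- solve_assay(st)
    data.frame(occupancy = occ, predicted_signal = st$predicted_signal,
               Ca_surface = st$Ca_surface, psi0 = st$psi0)
  })
  out <- do.call(rbind, rows)
  s <- out$predicted_signal
  s95 <- s[1] + 0.95 * (s[length(s)] - s[1])
  occ95 <- if (s[length(s)] > s[1])
    stats::approx(s, out$occupancy, xout = s95, ties = "ordered")$y
  else NA_real_
  attr(out, "occupancy_95") <- occ95
  out
}
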