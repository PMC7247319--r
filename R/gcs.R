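# Gouy-Chapman-Stern electrostatics of charged bilayers: Debye screening,
# the mixed-valence Grahame relation, charge regulation by Stern-adsorbing
# cations, surface-potential/zeta conversions through the Gouy decay, and
# potential / ion-distribution profiles.
#
# All potentials in volts, charge densities in C/m^2, distances in metres,
# bulk concentrations in mol/L (converted to mol/m^3 internally).

#' Define an electrolyte composition
#'
#' @param name Character vector of ion names.
#' @param z Integer valences (signed).
#' @param conc Bulk concentrations (M, >= 0).
#' @param K Intrinsic Stern association constants (M^-1); 0 = non-adsorbing.
#'   Conventional defaults for the charged-bilayer literature are ~0.6 M^-1
#'   for Na+/K+ and ~12 M^-1 for Ca2+ (see [stern_default_K()]).
#' @return Object of class `electrolyte` (a data frame), validated for bulk
#'   electroneutrality.
#' @export
#' @examples
#' electrolyte(c("K", "Cl"), c(1, -1), c(0.02, 0.02))
electrolyte <- function(name, z, conc, K = 0) {
  stopifnot(length(name) == length(z), length(z) == length(conc))
  K <- rep_len(K, length(name))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (any(K < 0)) stop("Stern constants must be >= 0")
  if (any(z != round(z))) stop("valences must be integers")
  if (abs(sum(z * conc)) > 1e-12 * max(sum(abs(z) * conc), 1e-300))
    stop("bulk electroneutrality violated: sum(z*C) = ", sum(z * conc))
  structure(data.frame(name = name, z = as.integer(z), conc = conc, K = K,
                       stringsAsFactors = FALSE),
            class = c("electrolyte", "data.frame"))
}

#' Conventional Stern association constants
#'
#' @return Named vector of intrinsic 1:1 association constants (M^-1) for
#'   common cations at anionic phospholipid surfaces.
#' @export
stern_default_K <- function() c(Na = 0.6, K = 0.6, Ca = 12)

#' Debye constant
#'
#' `kappa^2 = F^2 sum(z_i^2 C_i) / (eps_r eps_0 R T)` with C in mol/m^3 - the
#' general ionic-strength form, reducing to the symmetric Z:Z textbook
#' expression for a binary electrolyte.
#'
#' @param elec An [electrolyte].
#' @param temperature K (default 298.15).
#' @param eps_r Relative permittivity of the solvent (default 78.5).
#' @return kappa in m^-1 (its inverse is the Debye length).
#' @export
#' @examples
#' 1 / debye_constant(electrolyte(c("K", "Cl"), c(1, -1), c(0.1, 0.1)))  # ~0.96 nm
debye_constant <- function(elec, temperature = 298.15, eps_r = 78.5) {
  stopifnot(inherits(elec, "electrolyte"))
  s <- sum(elec$z^2 * elec$conc) * .M_TO_MOL_M3
  if (s <= 0) stop("zero ionic strength")
  sqrt(.const$F^2 * s / (eps_r * .const$eps0 * .const$R * temperature))
}

#' Grahame relation: surface charge from surface potential
#'
#' The mixed-valence Grahame equation of diffuse double-layer theory:
#' `sigma = sign(psi0) * sqrt(2 eps_r eps_0 R T * sum(C_i (exp(-z_i F psi0 / RT) - 1)))`.
#'
#' @param psi0 Surface potential (V), vectorized.
#' @param elec An [electrolyte].
#' @param temperature K.
#' @param eps_r Relative permittivity.
#' @return Surface charge density sigma (C/m^2).
#' @export
grahame_sigma <- function(psi0, elec, temperature = 298.15, eps_r = 78.5) {
  stopifnot(inherits(elec, "electrolyte"), all(is.finite(psi0)))
  RT <- .const$R * temperature
  vapply(psi0, function(p) {
    s <- sum(elec$conc * .M_TO_MOL_M3 * (exp(-elec$z * .const$F * p / RT) - 1))
    stopifnot(s >= -1e-9 * max(sum(elec$conc) * .M_TO_MOL_M3, 1))
    sign(p) * sqrt(2 * eps_r * .const$eps0 * RT * max(s, 0))
  }, numeric(1))
}

#' Solve the charge-regulated surface potential
#'
#' Finds the surface potential psi0 satisfying simultaneously the Grahame
#' relation and Langmuir-type Stern regulation of the intrinsic charge:
#' `sigma(psi0) = sigma_max / (1 + sum_j K_j C_j(0))` with surface
#' concentrations `C_j(0) = C_j_inf exp(-z_j F psi0 / RT)` for every
#' adsorbing ion (K_j > 0). Bracketing root-finder on psi0 in
#' `[-0.5, 0.5] V`, tolerance 1e-9 V.
#'
#' An optional non-reversal floor clamps psi0 at a configured minimum
#' magnitude (e.g. -30 mV): when the regulated solution would be less
#' negative than the floor, psi0 is held at the floor, the prevailing sigma
#' is recomputed from the Grahame relation, and the engagement is logged.
#'
#' @param sigma_max Intrinsic surface charge density (C/m^2).
#' @param elec An [electrolyte].
#' @param temperature K.
#' @param eps_r Relative permittivity.
#' @param psi_floor Optional floor on psi0 (V, same sign as sigma_max), e.g.
#'   `-0.030`; `NULL` (default) disables it.
#' @param shear_plane_x Shear-plane distance stored in the state (m,
#'   default 2 Angstrom).
#' @param viscosity Solution viscosity stored for mobility conversions
#'   (Pa s, default 0.89e-3).
#' @param tol Root tolerance on psi0 (V).
#' @return Object of class `electrostatic_state`: `sigma`, `sigma_max`,
#'   `psi0`, `kappa`, `zeta` (potential at the shear plane), `temperature`,
#'   `eps_r`, `viscosity`, `shear_plane_x`, `electrolyte`, `floor_engaged`.
#' @export
#' @examples
#' kcl <- electrolyte(c("K", "Cl"), c(1, -1), c(0.02, 0.02))
#' solve_surface_potential(-0.0781, kcl)  # psi0 ~ -116 mV
solve_surface_potential <- function(sigma_max, elec, temperature = 298.15,
                                    eps_r = 78.5, psi_floor = NULL,
                                    shear_plane_x = 2e-10,
                                    viscosity = 0.89e-3, tol = 1e-9) {
  stopifnot(inherits(elec, "electrolyte"), is.finite(sigma_max))
  RT <- .const$R * temperature
  kappa <- debye_constant(elec, temperature, eps_r)
  regulated_sigma <- function(psi) {
    ads <- elec$K > 0
    denom <- 1 + sum(elec$K[ads] * elec$conc[ads] *
                       exp(-elec$z[ads] * .const$F * psi / RT))
    sigma_max / denom
  }
  floor_engaged <- FALSE
  if (sigma_max == 0) {
    psi0 <- 0
    sigma <- 0
  } else {
    g <- function(psi) grahame_sigma(psi, elec, temperature, eps_r) -
      regulated_sigma(psi)
    lo <- -0.5; hi <- 0.5
    if (sign(g(lo)) == sign(g(hi)))
      stop("no sign change of the regulation residual in [-0.5, 0.5] V; ",
           "g(-0.5) = ", format(g(lo)), ", g(0.5) = ", format(g(hi)))
    psi0 <- stats::uniroot(g, c(lo, hi), tol = tol)$root
    sigma <- regulated_sigma(psi0)
  }
  # non-reversal floor: clamp whenever the solution would pass the floor
  # toward zero or beyond (including sign reversal)
  if (!is.null(psi_floor) &&
      ((psi_floor < 0 && psi0 > psi_floor) ||
       (psi_floor > 0 && psi0 < psi_floor))) {
    message("non-reversal floor engaged: psi0 clamped from ",
            signif(psi0 * 1e3, 4), " mV to ", psi_floor * 1e3, " mV")
    psi0 <- psi_floor
    sigma <- grahame_sigma(psi0, elec, temperature, eps_r)
    floor_engaged <- TRUE
  }
  Zmag <- max(abs(elec$z))
  zeta <- if (psi0 == 0) 0 else
    .gouy_psi_x(psi0, kappa, shear_plane_x, Z = 1, temperature = temperature)
  structure(list(sigma = sigma, sigma_max = sigma_max, psi0 = psi0,
                 kappa = kappa, zeta = zeta, temperature = temperature,
                 eps_r = eps_r, viscosity = viscosity,
                 shear_plane_x = shear_plane_x, electrolyte = elec,
                 floor_engaged = floor_engaged, Z = Zmag),
            class = "electrostatic_state")
}

#' @export
print.electrostatic_state <- function(x, ...) {
  cat(sprintf(paste0("<electrostatic_state> sigma=%.4g C/m^2 (max %.4g), ",
                     "psi0=%.4g mV, zeta=%.4g mV, 1/kappa=%.3g nm%s\n"),
              x$sigma, x$sigma_max, x$psi0 * 1e3, x$zeta * 1e3,
              1e9 / x$kappa, if (x$floor_engaged) " [floor engaged]" else ""))
  invisible(x)
}

#' Peptide-modified surface charge density
#'
#' The bound cationic peptide partially neutralizes the lipid charge:
#' `sigma_eff = sigma_lipid + occupancy * valence * e / (n * mean_area)`,
#' occupancy being the fraction of saturable sites bound. Pure arithmetic;
#' pair with the `psi_floor` argument of [solve_surface_potential()] to
#' impose the observed ~-30 mV non-reversal of zeta at saturation.
#'
#' @param sigma_lipid Bare-lipid surface charge density (C/m^2).
#' @param peptide_occupancy Fraction of saturable sites occupied, in `[0, 1]`.
#' @param n Lipids per bound peptide (> 0).
#' @param mean_area Mean lipid cross-sectional area (Angstrom^2, > 0).
#' @param peptide_valence Formal peptide charge (default +3).
#' @return sigma_eff in C/m^2.
#' @export
#' @examples
#' peptide_modified_sigma(-0.0781, 1, 6.9, 82)
peptide_modified_sigma <- function(sigma_lipid, peptide_occupancy, n,
                                   mean_area, peptide_valence = 3) {
  if (any(peptide_occupancy < 0 | peptide_occupancy > 1))
    stop("occupancy must be in [0, 1]")
  if (n <= 0 || mean_area <= 0) stop("n and mean_area must be positive")
  sigma_lipid + peptide_occupancy * peptide_valence * .const$e /
    (n * mean_area * .A2_TO_M2)
}

#' Zeta potential from electrophoretic mobility
#'
#' Helmholtz-Smoluchowski relation `zeta = mu * eta / (eps_r eps_0)`.
#'
#' @param mu Electrophoretic mobility (m^2 V^-1 s^-1).
#' @param eta Viscosity (Pa s, default 0.89e-3).
#' @param eps_r Relative permittivity (default 78.5).
#' @return zeta in V.
#' @export
#' @examples
#' zeta_from_mobility(-2e-8)  # ~ -25.6 mV
zeta_from_mobility <- function(mu, eta = 0.89e-3, eps_r = 78.5) {
  if (eta <= 0) stop("viscosity must be positive")
  mu * eta / (eps_r * .const$eps0)
}

# analytic Gouy decay of the potential from a charged plane in a symmetric
# Z:Z electrolyte: psi(x) = (2RT/ZF) ln((1 + G e^-kx)/(1 - G e^-kx)),
# G = tanh(ZF psi0 / 4RT)
.gouy_psi_x <- function(psi0, kappa, x, Z = 1, temperature = 298.15) {
  RT <- .const$R * temperature
  G <- tanh(Z * .const$F * psi0 / (4 * RT))
  gx <- G * exp(-kappa * x)
  (2 * RT / (Z * .const$F)) * log((1 + gx) / (1 - gx))
}

#' Evaluate the Gouy potential decay at a distance
#'
#' @param psi0 Surface potential (V).
#' @param kappa Debye constant (m^-1).
#' @param x Distance from the surface (m), vectorized.
#' @param Z Electrolyte valence (symmetric Z:Z, default 1).
#' @param temperature K.
#' @return psi(x) in V.
#' @export
potential_at_distance <- function(psi0, kappa, x, Z = 1, temperature = 298.15) {
  .gouy_psi_x(psi0, kappa, x, Z, temperature)
}

#' Surface potential from zeta potential
#'
#' Inverts the distance-dependent Gouy decay: given the potential zeta
#' measured at the shear plane `x` (default 2 Angstrom), recovers the surface
#' potential psi0 using the analytic tanh form; `|psi0| >= |zeta|`.
#'
#' @param zeta Shear-plane potential (V); `|zeta| < 0.3` required.
#' @param kappa Debye constant (m^-1).
#' @param x Shear-plane distance (m, default 2e-10).
#' @param Z Symmetric electrolyte valence (default 1).
#' @param temperature K.
#' @return psi0 in V.
#' @export
#' @examples
#' k <- debye_constant(electrolyte(c("K", "Cl"), c(1, -1), c(0.1, 0.1)))
#' surface_potential_from_zeta(-0.030, k)
surface_potential_from_zeta <- function(zeta, kappa, x = 2e-10, Z = 1,
                                        temperature = 298.15) {
  if (abs(zeta) >= 0.3) stop("|zeta| >= 300 mV outside the model's sanity bound")
  if (zeta == 0) return(0)
  RT <- .const$R * temperature
  G0 <- tanh(Z * .const$F * zeta / (4 * RT)) * exp(kappa * x)
  if (abs(G0) >= 1)
    stop("decay inversion has no solution (|tanh| argument >= 1); ",
         "zeta too large for this kappa*x")
  (4 * RT / (Z * .const$F)) * atanh(G0)
}

#' Potential and ion-distribution profile of the diffuse layer
#'
#' For a symmetric binary electrolyte the analytic Gouy solution is used;
#' for mixed valences the Poisson-Boltzmann first integral
#' `dpsi/dx = -sign(psi0) sqrt((2RT/eps) sum C_i (exp(-z_i F psi/RT) - 1))`
#' is integrated with a fixed-step RK4 scheme. Ion profiles follow Boltzmann:
#' `C_i(x) = C_i_inf exp(-z_i F psi(x) / RT)`.
#'
#' @param state A solved [solve_surface_potential()] state.
#' @param x_max Profile extent (m); default 10 Debye lengths.
#' @param points Number of grid points (default 201).
#' @param method `"auto"` (analytic when symmetric), `"analytic"`, or
#'   `"numeric"`.
#' @return Object of class `surface_ion_profile`: data.frame with `x` (m),
#'   `psi` (V) and one concentration column per ion (M).
#' @export
potential_profile <- function(state, x_max = NULL, points = 201L,
                              method = c("auto", "analytic", "numeric")) {
  stopifnot(inherits(state, "electrostatic_state"))
  method <- match.arg(method)
  elec <- state$electrolyte
  RT <- .const$R * state$temperature
  if (is.null(x_max)) x_max <- 10 / state$kappa
  x <- seq(0, x_max, length.out = points)

  zs <- sort(unique(elec$z))
  symmetric <- length(zs) == 2L && sum(zs) == 0L &&
    abs(diff(elec$conc[order(elec$z)])) < 1e-15
  if (method == "analytic" && !symmetric)
    stop("analytic profile requires a symmetric binary electrolyte")
  use_analytic <- method == "analytic" || (method == "auto" && symmetric)

  if (state$psi0 == 0) {
    psi <- rep(0, points)
  } else if (use_analytic) {
    psi <- .gouy_psi_x(state$psi0, state$kappa, x, Z = max(abs(elec$z)),
                       temperature = state$temperature)
  } else {
    eps <- state$eps_r * .const$eps0
    dpsidx <- function(p) {
      s <- sum(elec$conc * .M_TO_MOL_M3 *
                 (exp(-elec$z * .const$F * p / RT) - 1))
      -sign(state$psi0) * sqrt(pmax(2 * RT / eps * s, 0))
    }
    # RK4 with substeps fine relative to the Debye length
    psi <- numeric(points)
    psi[1] <- state$psi0
    h_grid <- diff(x)
    nsub <- max(1L, ceiling(max(h_grid) * state$kappa * 50))
    for (i in seq_len(points - 1L)) {
      p <- psi[i]
      h <- h_grid[i] / nsub
      for (s in seq_len(nsub)) {
        k1 <- dpsidx(p)
        k2 <- dpsidx(p + h / 2 * k1)
        k3 <- dpsidx(p + h / 2 * k2)
        k4 <- dpsidx(p + h * k3)
        p_new <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        # the decay may not cross zero
        if (sign(p_new) != sign(state$psi0)) p_new <- 0
        p <- p_new
      }
      psi[i + 1L] <- p
    }
  }
  prof <- data.frame(x = x, psi = psi)
  for (i in seq_len(nrow(elec)))
    prof[[elec$name[i]]] <- elec$conc[i] *
      exp(-elec$z[i] * .const$F * psi / RT)
  structure(prof, class = c("surface_ion_profile", "data.frame"))
}

#' Ratio of divalent-cation surface accumulation between two states
#'
#' Boltzmann enhancement of a divalent cation at the surface is
#' `exp(-2 F psi0 / RT)`; the ratio between a bare and a peptide-bound
#' membrane quantifies how strongly peptide binding depletes interfacial
#' divalents.
#'
#' @param state_bare,state_bound Solved [solve_surface_potential()] states
#'   sharing temperature.
#' @return Dimensionless ratio (> 1 when the bound state is less negative).
#' @export
divalent_accumulation_ratio <- function(state_bare, state_bound) {
  stopifnot(inherits(state_bare, "electrostatic_state"),
            inherits(state_bound, "electrostatic_state"))
  RT <- .const$R * state_bare$temperature
  exp(-2 * .const$F * state_bare$psi0 / RT) /
    exp(-2 * .const$F * state_bound$psi0 / RT)
}
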