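bg_salt <- function(K_cation = 0.6) kcl(0.02, K_cation = K_cation)

base_assay <- function(...) {
  calcium_assay(probe_total = 1e-6, Ca_total = 50e-6, membrane = tocl20(),
                L_eff = 100e-6, electrolyte = bg_salt(), ...)
}

test_that("surface excess: trivial zero, monotonicity, quadrature oracle", {
  ca_elec <- function(kca = 12) electrolyte(
    c("K", "Cl", "Ca", "Cl_ca"), c(1, -1, 2, -1),
    c(0.02, 0.02, 1e-5, 2e-5), c(0, 0, kca, 0))
  # psi0 = 0 and K_Ca = 0 -> no excess
  st0 <- solve_surface_potential(0, ca_elec(0))
  expect_equal(surface_calcium_excess(st0, 100e-6, 82), 0)
  # excess grows with |psi0|
  exs <- vapply(c(-0.02, -0.05, -0.08, -0.116), function(psi) {
    st <- solve_surface_potential(grahame_sigma(psi, ca_elec()), ca_elec())
    st$sigma_max <- st$sigma  # treat as intrinsic for the Stern share
    surface_calcium_excess(st, 100e-6, 82)
  }, numeric(1))
  expect_true(all(diff(exs) > 0))
  # diffuse-layer integral vs brute-force trapezoid quadrature of the ion
  # profile (dense grid: the near-surface enhancement decays steeply)
  st <- solve_surface_potential(grahame_sigma(-0.06, ca_elec()), ca_elec())
  ex_diff <- surface_calcium_excess(st, 100e-6, 82, include_stern = FALSE)
  prof <- potential_profile(st, x_max = 50e-9, points = 20001L,
                            method = "numeric")
  dx <- diff(prof$x)
  f <- (prof$Ca - 1e-5) * 1000  # mol/m^3 excess
  gamma_bf <- sum((f[-1] + f[-length(f)]) / 2 * dx)  # mol/m^2
  area_per_litre <- 100e-6 * physical_constants()$Na * 82e-20
  expect_rel_equal(ex_diff, gamma_bf * area_per_litre, 1e-3)
})

test_that("probe-only limit reproduces the closed-form 1:1 quadratic", {
  a <- calcium_assay(1e-6, 50e-6, tocl20(), 0, bg_salt())
  s <- solve_assay(a)
  Kd <- 14e-6; P <- 1e-6; C <- 50e-6
  b <- P + C + Kd
  cb <- (b - sqrt(b^2 - 4 * P * C)) / 2
  expect_equal(s$Ca_probe_bound, cb, tolerance = 1e-12)
  expect_equal(s$predicted_signal, cb / P, tolerance = 1e-12)
  expect_equal(s$Ca_surface, 0)
})

test_that("mass balance holds at solver tolerance in solved states", {
  for (occ in c(0, 0.5, 1)) {
    s <- suppressMessages(solve_assay(base_assay(peptide_occupancy = occ)))
    resid <- s$Ca_total - s$Ca_free - s$Ca_probe_bound - s$Ca_surface
    expect_lt(abs(resid), 1e-12)
    expect_true(all(c(s$Ca_free, s$Ca_probe_bound) >= 0))
  }
})

test_that("anionic membrane reduces the indicator signal; peptide restores it", {
  s_free <- solve_assay(calcium_assay(1e-6, 50e-6, tocl20(), 0, bg_salt()))
  s_mem <- solve_assay(base_assay())
  expect_lt(s_mem$predicted_signal, s_free$predicted_signal)
  # increasing occupancy strictly increases the signal
  sigs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(occ)
    suppressMessages(
      solve_assay(base_assay(peptide_occupancy = occ)))$predicted_signal,
    numeric(1))
  expect_true(all(diff(sigs) > 0))
  # with the floor at -30 mV, full occupancy stays below the membrane-free
  # level: residual sequestration persists
  expect_lt(sigs[5], s_free$predicted_signal)
})

test_that("valence ordering: divalent sequestration exceeds monovalent", {
  # same bulk concentration, Ca2+ vs a hypothetical monovalent analogue
  mk <- function(z) {
    nm <- c("K", "Cl", "Ca", "Cl_ca")
    electrolyte(nm, c(1, -1, z, -1), c(0.02, 0.02, 1e-5, z * 1e-5),
                c(0, 0, 12, 0))
  }
  st2 <- solve_surface_potential(-0.0781, mk(2))
  st1 <- solve_surface_potential(-0.0781, mk(1))
  ex2 <- surface_calcium_excess(st2, 100e-6, 82)
  ex1 <- surface_calcium_excess(st1, 100e-6, 82)
  expect_gt(ex2, ex1)
})

test_that("peptide displacement curve is monotone and reports 95% point", {
  curve <- suppressMessages(
    peptide_displacement_curve(base_assay(), seq(0, 1, 0.2)))
  expect_equal(curve$occupancy, seq(0, 1, 0.2))
  expect_true(all(diff(curve$predicted_signal) >= 0))
  o95 <- attr(curve, "occupancy_95")
  expect_true(is.finite(o95) && o95 > 0 && o95 <= 1)
  # occupancy 0 reproduces the base state
  s0 <- solve_assay(base_assay())
  expect_equal(curve$predicted_signal[1], s0$predicted_signal,
               tolerance = 1e-10)
})

test_that("assay configuration is validated", {
  expect_error(calcium_assay(1e-6, 50e-6, tocl20(), 100e-6,
                             electrolyte(c("Ca", "Cl"), c(2, -1),
                                         c(1e-3, 2e-3))),
               "must not contain Ca")
  expect_error(base_assay(peptide_occupancy = 2), "occupancy")
  expect_error(calcium_assay(-1, 1e-6, tocl20(), 0, bg_salt()),
               "concentrations")
})
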