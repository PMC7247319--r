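test_that("electrolyte constructor enforces electroneutrality", {
  expect_error(electrolyte(c("K", "Cl"), c(1, -1), c(0.1, 0.05)),
               "electroneutrality")
  expect_error(electrolyte("K", 1, -0.1), ">= 0")
  e <- electrolyte(c("K", "Cl", "Ca", "Cl2"), c(1, -1, 2, -1),
                   c(0.02, 0.02, 1e-3, 2e-3), c(0.6, 0, 12, 0))
  expect_s3_class(e, "electrolyte")
})

test_that("Debye constant matches independent arithmetic", {
  cst <- physical_constants()
  k100 <- debye_constant(kcl(0.1))
  # independent evaluation of kappa^2 = F^2 sum z^2 C / (eps RT)
  k_ref <- sqrt(cst$F^2 * 2 * 0.1 * 1000 /
                  (78.5 * cst$eps0 * cst$R * 298.15))
  expect_equal(k100, k_ref, tolerance = 1e-12)
  expect_equal(1e9 / k100, 0.96, tolerance = 0.01)
  expect_equal(1e9 / debye_constant(kcl(0.02)), 2.15, tolerance = 0.01)
  # kappa ~ sqrt(C): quadrupling the salt halves the Debye length
  expect_equal(debye_constant(kcl(0.4)) / k100, 2, tolerance = 1e-12)
  expect_error(debye_constant(electrolyte("X", 0, 0.1)), "ionic strength")
})

test_that("Grahame relation: limits, antisymmetry, Debye-Huckel agreement", {
  e <- kcl(0.1)
  expect_equal(grahame_sigma(0, e), 0)
  expect_equal(grahame_sigma(-0.05, e), -grahame_sigma(0.05, e),
               tolerance = 1e-12)
  # linearized (Debye-Huckel) limit sigma = eps kappa psi within 2% at 10 mV
  cst <- physical_constants()
  for (conc in c(0.02, 0.1, 0.5)) {
    el <- kcl(conc)
    kap <- debye_constant(el)
    for (psi in c(-0.01, -0.005, 0.005, 0.01)) {
      lin <- 78.5 * cst$eps0 * kap * psi
      expect_rel_equal(grahame_sigma(psi, el), lin, 0.02)
    }
  }
  # mixed-valence electrolyte also approaches the linearized limit; the
  # asymmetric cubic term does not cancel, so the potential must be smaller
  # for the same 2% agreement
  mix <- electrolyte(c("K", "Cl", "Ca", "Cl2"), c(1, -1, 2, -1),
                     c(0.02, 0.02, 0.005, 0.01))
  kap <- debye_constant(mix)
  expect_rel_equal(grahame_sigma(-0.004, mix),
                   78.5 * cst$eps0 * kap * -0.004, 0.02)
})

test_that("charge-regulated surface potential solves the fixed point", {
  e <- kcl(0.02)
  st <- solve_surface_potential(-0.0781, e)
  # independent numeric root of the bare Grahame equation
  psi_ref <- uniroot(function(p) grahame_sigma(p, e) + 0.0781,
                     c(-0.3, 0), tol = 1e-12)$root
  expect_equal(st$psi0, psi_ref, tolerance = 1e-7)
  expect_equal(st$psi0, -0.116, tolerance = 0.005)
  expect_equal(solve_surface_potential(0, e)$psi0, 0)
  # round-trip: grahame_sigma(psi0*) equals the regulated sigma to 1e-9
  es <- kcl(0.1, K_cation = 0.6)
  sts <- solve_surface_potential(-0.0781, es)
  expect_lt(abs(grahame_sigma(sts$psi0, es) - sts$sigma), 1e-9)
  expect_lt(abs(sts$sigma), abs(sts$sigma_max))  # Stern adsorption attenuates
  # screening monotonicity: added salt strictly reduces |psi0|
  psis <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5), function(conc)
    solve_surface_potential(-0.0781, kcl(conc, K_cation = 0.6))$psi0,
    numeric(1))
  expect_true(all(diff(abs(psis)) < 0))
})

test_that("peptide-modified sigma and the non-reversal floor", {
  expect_equal(peptide_modified_sigma(-0.0781, 0, 6.9, 82), -0.0781)
  cst <- physical_constants()
  dsig <- 3 * cst$e / (6.9 * 82 * 1e-20)
  expect_equal(peptide_modified_sigma(-0.0781, 1, 6.9, 82),
               -0.0781 + dsig, tolerance = 1e-12)
  expect_equal(dsig, 0.0849, tolerance = 1e-3)
  expect_error(peptide_modified_sigma(-0.1, 1.5, 6.9, 82), "occupancy")

  e <- kcl(0.02)
  s_eff <- peptide_modified_sigma(intrinsic_surface_charge_density(tocl20()),
                                  1, 6.9, 82)
  expect_gt(s_eff, 0)  # full occupancy overcompensates the lipid charge
  # floor on: psi0 clamped at -30 mV, engagement logged
  expect_message(st <- solve_surface_potential(s_eff, e, psi_floor = -0.030),
                 "floor engaged")
  expect_equal(st$psi0, -0.030)
  expect_true(st$floor_engaged)
  # floor off: sign reversal permitted and reported
  st2 <- solve_surface_potential(s_eff, e)
  expect_gt(st2$psi0, 0)
  expect_false(st2$floor_engaged)
})

test_that("zeta from mobility (Helmholtz-Smoluchowski)", {
  expect_equal(zeta_from_mobility(0), 0)
  expect_equal(zeta_from_mobility(-4e-8), 2 * zeta_from_mobility(-2e-8))
  expect_equal(zeta_from_mobility(-2e-8, 0.89e-3, 78.5), -0.0256,
               tolerance = 1e-3)
  expect_error(zeta_from_mobility(1e-8, eta = 0), "positive")
})

test_that("surface potential <-> zeta decay inversion round-trips", {
  kap <- debye_constant(kcl(0.1))
  # x = 0: identity
  expect_equal(surface_potential_from_zeta(-0.03, kap, x = 0), -0.03,
               tolerance = 1e-12)
  expect_equal(surface_potential_from_zeta(0, kap), 0)
  # forward decay residual of the inverted value < 1e-12 (round-trip)
  cst <- physical_constants()
  RT <- cst$R * 298.15
  for (zeta in c(-0.03, -0.08, 0.02)) {
    psi0 <- surface_potential_from_zeta(zeta, kap, x = 2e-10)
    expect_gte(abs(psi0), abs(zeta))
    # evaluate the implicit decay equation kappa*x = ln(...) directly
    ez <- exp(cst$F * zeta / (2 * RT)); ep <- exp(cst$F * psi0 / (2 * RT))
    lhs <- kap * 2e-10
    rhs <- log(((ez + 1) * (ep - 1)) / ((ez - 1) * (ep + 1)))
    expect_lt(abs(lhs - rhs), 1e-12)
    # and the forward analytic evaluation returns zeta
    expect_equal(potential_at_distance(psi0, kap, 2e-10), zeta,
                 tolerance = 1e-12)
  }
  # small-potential limit: psi0 ~ zeta * exp(kappa x) within 2% at 10 mV
  for (zeta in c(-0.01, -0.005, 0.005)) {
    psi0 <- surface_potential_from_zeta(zeta, kap, x = 2e-10)
    expect_rel_equal(psi0, zeta * exp(kap * 2e-10), 0.02)
  }
  expect_error(surface_potential_from_zeta(-0.31, kap), "sanity")
})

test_that("potential profile: boundaries, oracle equivalence, Boltzmann ions", {
  st <- solve_surface_potential(-0.0781, kcl(0.02))
  prof <- potential_profile(st, x_max = 15 / st$kappa, points = 101L)
  expect_equal(prof$psi[1], st$psi0, tolerance = 1e-12)
  expect_lt(abs(prof$psi[101]), 1e-6)
  expect_true(all(diff(prof$psi) > 0))  # monotone decay toward zero
  # analytic symmetric solution vs numeric first-integral to 1e-6 V
  pa <- potential_profile(st, x_max = 15 / st$kappa, points = 101L,
                          method = "analytic")
  pn <- potential_profile(st, x_max = 15 / st$kappa, points = 101L,
                          method = "numeric")
  expect_lt(max(abs(pa$psi - pn$psi)), 1e-6)
  # ion profiles: Boltzmann at the surface, bulk far away
  cst <- physical_constants()
  expect_equal(prof$K[1], 0.02 * exp(-cst$F * st$psi0 / (cst$R * 298.15)),
               tolerance = 1e-9)
  expect_equal(prof$K[101], 0.02, tolerance = 1e-4)
  expect_true(all(prof$K >= 0 & prof$Cl >= 0))
  # divalent enhancement at psi0 = -25.7 mV is e^2
  st2 <- solve_surface_potential(
    grahame_sigma(-0.0257, kcl(0.02)), kcl(0.02))
  rat <- exp(-2 * cst$F * st2$psi0 / (cst$R * 298.15))
  expect_equal(rat, exp(2), tolerance = 1e-2)
})

test_that("divalent accumulation ratio", {
  e <- kcl(0.02)
  st <- solve_surface_potential(-0.0781, e)
  expect_equal(divalent_accumulation_ratio(st, st), 1)
  bound <- solve_surface_potential(grahame_sigma(-0.030, e), e)
  ratio <- divalent_accumulation_ratio(st, bound)
  expect_equal(ratio, 8.1e2, tolerance = 0.05)
  expect_gt(ratio, 10)
  # monotone in |psi0_bare|
  rats <- vapply(c(-0.05, -0.08, -0.116), function(p)
    divalent_accumulation_ratio(
      solve_surface_potential(grahame_sigma(p, e), e), bound), numeric(1))
  expect_true(all(diff(rats) > 0))
})
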