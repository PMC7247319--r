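test_that("bound_peptide agrees with the scalar-root oracle", {
  # the quadratic and an independent root-finder must agree to 1e-10 relative
  set.seed(11)
  for (i in 1:200) {  # acceptance suite runs the full 1e4-draw sweep
    P <- 10^runif(1, -7, -4)
    L <- 10^runif(1, -6, -3)
    n <- 10^runif(1, 0, 1.5)
    K <- 10^runif(1, -8, -4)
    PB <- bound_peptide(P, L, n, K)
    expect_rel_equal(PB, bound_peptide_oracle(P, L, n, K), 1e-10)
  }
})

test_that("bound_peptide limits and monotonicity", {
  expect_equal(bound_peptide(0, 100e-6, 5, 1e-6), 0)
  # stoichiometric limit K_D -> 0
  expect_equal(bound_peptide(10e-6, 100e-6, 5, 1e-15), 10e-6,
               tolerance = 1e-6)
  expect_equal(bound_peptide(50e-6, 100e-6, 5, 1e-15), 20e-6,
               tolerance = 1e-6)
  # worked point vs oracle
  expect_rel_equal(bound_peptide(10e-6, 125e-6, 6.9, 0.29e-6),
                   bound_peptide_oracle(10e-6, 125e-6, 6.9, 0.29e-6), 1e-10)
  # monotone in P_total and L_eff, antitone in K_D
  P <- seq(1e-6, 50e-6, length.out = 30)
  expect_true(all(diff(bound_peptide(P, 100e-6, 6.9, 1e-6)) > 0))
  L <- seq(1e-6, 500e-6, length.out = 30)
  expect_true(all(diff(bound_peptide(10e-6, L, 6.9, 1e-6)) > 0))
  K <- 10^seq(-8, -4, length.out = 30)
  pb <- vapply(K, function(k) bound_peptide(10e-6, 100e-6, 6.9, k), numeric(1))
  expect_true(all(diff(pb) < 0))
})

test_that("peptide-titration fit recovers generating parameters exactly", {
  p <- binding_params(6.9, 2.0e-6 / 6.9, "peptide_into_lipid")
  serset <- lapply(c(25, 50, 75, 100, 125) * 1e-6, function(L)
    gen_fluorescence_titration(p, titration_design("peptide_into_lipid", L),
                               synth_config(noise_scale = 0)))
  f <- fit_peptide_titration(serset)
  expect_equal(f$n, 6.9, tolerance = 1e-6)
  expect_equal(f$nK_D, 2.0e-6, tolerance = 1e-6)
  expect_equal(f$c_f, p$c_f, tolerance = 1e-6)
  expect_equal(f$c_b, p$c_b, tolerance = 1e-6)
  expect_true(f$identifiable)
})

test_that("no-binding (zwitterionic-only) series is flagged unidentifiable", {
  P <- seq(2e-6, 40e-6, by = 2e-6)
  ser <- titration_series("peptide_into_lipid", 125e-6, P, 1e4 * P)
  expect_warning(f <- fit_peptide_titration(ser), "unidentifiable|amplitude")
  expect_false(f$identifiable)
})

test_that("lipid-titration fit recovers parameters; saturation asymptote", {
  p <- binding_params(6.9, 2.9e-6, "lipid_into_peptide", r = 3)
  s <- gen_fluorescence_titration(p, titration_design("lipid_into_peptide"),
                                  synth_config(noise_scale = 0))
  f <- fit_lipid_titration(s)
  expect_equal(f$n, 6.9, tolerance = 1e-5)
  expect_equal(f$K_D, 2.9e-6, tolerance = 1e-5)
  expect_equal(f$r, 3, tolerance = 1e-6)
  # saturating lipid drives F/F0 toward r
  big <- gen_fluorescence_titration(
    p, titration_design("lipid_into_peptide",
                        titrant_totals = c(0.01, 0.02, 0.05, 0.1, 0.5, 1)),
    synth_config(noise_scale = 0))
  expect_equal(big$signal[6], 3, tolerance = 1e-3)
  # r = 1 (no spectral change) flagged
  flat <- gen_fluorescence_titration(
    binding_params(6.9, 2.9e-6, "lipid_into_peptide", r = 1),
    titration_design("lipid_into_peptide"), synth_config(noise_scale = 0))
  expect_warning(ff <- fit_lipid_titration(flat), "unidentifiable")
  expect_false(ff$identifiable)
})

test_that("global salt-series fit shares the saturation point", {
  d <- titration_design("lipid_into_peptide")
  s1 <- gen_fluorescence_titration(
    binding_params(6.9, 2.0e-6, "lipid_into_peptide", r = 3), d,
    synth_config(noise_scale = 0))
  s2 <- gen_fluorescence_titration(
    binding_params(6.9, 12e-6, "lipid_into_peptide", r = 3), d,
    synth_config(noise_scale = 0))
  fits <- fit_global_salt_series(list(s1, s2))
  expect_equal(fits[[1]]$K_D, 2.0e-6, tolerance = 1e-4)
  expect_equal(fits[[2]]$K_D, 12e-6, tolerance = 1e-4)
  expect_equal(fits[[1]]$r, fits[[2]]$r)
  expect_equal(fits[[1]]$r, 3, tolerance = 1e-5)
  # single series degenerates to the per-series fit
  f1 <- fit_global_salt_series(list(s1))[[1]]
  expect_equal(f1$K_D, fit_lipid_titration(s1)$K_D, tolerance = 1e-8)
  # incompatible saturation points leave a larger joint residual
  s3 <- gen_fluorescence_titration(
    binding_params(6.9, 2.0e-6, "lipid_into_peptide", r = 5), d,
    synth_config(noise_scale = 0))
  joint <- fit_global_salt_series(list(s1, s3))[[1]]$rss
  indep <- fit_global_salt_series(list(s1, s3), shared_saturation = FALSE)
  expect_gt(joint, indep[[1]]$rss + 1e-8)
})

test_that("Scatchard transform of exact data recovers n and K_D", {
  p <- binding_params(6.9, 0.29e-6, "peptide_into_lipid")
  ser <- gen_fluorescence_titration(
    p, titration_design("peptide_into_lipid", 125e-6),
    synth_config(noise_scale = 0))
  sc <- scatchard_transform(ser, p)
  expect_equal(sc$n, 6.9, tolerance = 1e-8)
  expect_equal(sc$K_D, 0.29e-6, tolerance = 1e-8)
  expect_equal(sc$x_intercept, 1 / 6.9, tolerance = 1e-8)
  expect_false(sc$nonlinear)
  # heterogeneous two-site data produce a curved Scatchard plot
  P <- seq(2e-6, 40e-6, by = 2e-6)
  PB <- bound_peptide(P, 125e-6, 4, 0.05e-6) * 0.5 +
    bound_peptide(P, 125e-6, 25, 5e-6) * 0.5
  y <- p$c_f * (P - PB) + p$c_b * PB
  ser2 <- titration_series("peptide_into_lipid", 125e-6, P, y)
  expect_warning(sc2 <- scatchard_transform(ser2, p), "nonlinear")
  expect_true(sc2$nonlinear)
})

test_that("partition coefficient: both conventions, exact recovery", {
  L <- seq(5e-6, 400e-6, by = 12e-6)
  fb <- 5.07e4 * L / (55.3 + 5.07e4 * L)
  ser <- titration_series("lipid_into_peptide", 10e-6, L, 1 + 2.2 * fb)
  pw <- partition_coefficient(ser, "water_normalized")
  expect_equal(pw$K_P, 5.07e4, tolerance = 1e-6)
  expect_equal(pw$r, 3.2, tolerance = 1e-6)
  # site_free convention on the same data: K_x = K_P / [W]
  ps <- partition_coefficient(ser, "site_free")
  expect_equal(ps$K_P, 5.07e4 / 55.3, tolerance = 1e-6)
  expect_equal(ps$rss, pw$rss, tolerance = 1e-10)  # same curve, reparameterized
  expect_error(partition_coefficient(
    titration_series("peptide_into_lipid", 1e-6, c(1e-6, 2e-6), c(1, 2))),
    "lipid_into_peptide")
})

test_that("fractional saturation limits", {
  p <- binding_params(6.9, 0.29e-6, "peptide_into_lipid")
  expect_equal(fractional_saturation(0, p, 125e-6), 0)
  expect_equal(fractional_saturation(1, p, 125e-6), 1, tolerance = 1e-4)
  # stoichiometric half-point: P = S/2 with K_D << S
  tight <- binding_params(6.9, 1e-12, "peptide_into_lipid")
  S <- 125e-6 / 6.9
  expect_equal(fractional_saturation(S / 2, tight, 125e-6), 0.5,
               tolerance = 1e-4)
  # lipid-mode parameters use the per-lipid constant internally
  pl <- binding_params(6.9, 2.0e-6, "lipid_into_peptide")
  th <- fractional_saturation(10e-6, pl, 125e-6)
  expect_equal(th, bound_peptide(10e-6, 125e-6, 6.9, 2.0e-6 / 6.9) / S,
               tolerance = 1e-10)
})

test_that("noisy parameter recovery is unbiased at the design scale", {
  # reduced-n version of the 200-seed study run by the acceptance suite
  p <- binding_params(6.9, 2.0e-6 / 6.9, "peptide_into_lipid")
  ns <- vapply(1:25, function(k) {
    serset <- lapply(c(25, 75, 125) * 1e-6, function(L)
      gen_fluorescence_titration(p, titration_design("peptide_into_lipid", L),
                                 synth_config(seed = k, noise_scale = 0.01)))
    suppressWarnings(fit_peptide_titration(serset)$n)
  }, numeric(1))
  expect_rel_equal(stats::median(ns), 6.9, 0.05)
})
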