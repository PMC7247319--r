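# Shared fixtures and independent oracles.

tocl20 <- function() membrane_spec(c(TOCL = 0.2, POPC = 0.8))
mlcl20 <- function() membrane_spec(c(MLCL = 0.2, POPC = 0.8))
popg20 <- function() membrane_spec(c(POPG = 0.2, POPC = 0.8))
popc_only <- function() membrane_spec(c(POPC = 1))

kcl <- function(conc, K_cation = 0)
  electrolyte(c("K", "Cl"), c(1, -1), c(conc, conc), c(K_cation, 0))

# independent scalar-root oracle for the single-site mass-action equilibrium:
# (P - PB)(S - PB) = K_D * PB, PB in [0, min(P, S)]
bound_peptide_oracle <- function(P, L_eff, n, K_D) {
  S <- L_eff / n
  if (P == 0 || S == 0) return(0)
  f <- function(PB) (P - PB) * (S - PB) - K_D * PB
  r <- stats::uniroot(f, c(0, min(P, S)), tol = 1e-18)$root
  # uniroot's tolerance is absolute; Newton-polish to full relative precision
  for (k in 1:8) {
    fp <- -(S - r) - (P - r) - K_D
    step <- f(r) / fp
    r <- r - step
    if (abs(step) <= 1e-16 * abs(r)) break
  }
  r
}

# brute-force mole-tracking ITC oracle: explicit moles, overflow expelled at
# the pre-injection cell composition
itc_heats_oracle <- function(experiment, params) {
  V0 <- experiment$cell_volume
  molP <- experiment$peptide_cell_conc * V0
  molL <- 0
  B_prev <- bound_peptide(molP / V0, molL / V0, params$n, params$K_D)
  Q <- numeric(length(experiment$injection_volumes))
  for (j in seq_along(Q)) {
    v <- experiment$injection_volumes[j]
    molP <- molP - (molP / V0) * v
    molL <- molL - (molL / V0) * v + experiment$syringe_lipid_eff * v
    B <- bound_peptide(molP / V0, molL / V0, params$n, params$K_D)
    Q[j] <- params$dH * (B * V0 - B_prev * V0 * (1 - v / V0))
    B_prev <- B
  }
  Q
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
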