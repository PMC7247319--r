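# Equilibrium peptide-membrane binding: the exact single-site Langmuir
# quadratic (no free ~ total approximation), nonlinear fits for both
# titration directions, global salt-series fits with a shared saturation
# point, Scatchard transforms and molar partition coefficients.
#
# Conventions: a membrane presents L_eff/n saturable sites (L_eff = outer
# leaflet lipid = total/2); K_D is the per-site dissociation constant in
# peptide titrations and n*K_D the per-lipid-monomer constant reported by
# lipid titrations. Nonlinear fits use damped least squares with the linear
# amplitudes profiled out (variable projection) and log-scale multistart on
# (n, K_D).

#' Construct a titration series
#'
#' Container for a fluorescence binding titration in either direction.
#'
#' @param mode `"peptide_into_lipid"` (peptide titrated into vesicles at
#'   fixed lipid) or `"lipid_into_peptide"` (vesicles titrated into peptide).
#' @param fixed_species_total Concentration (M) of the fixed species: the
#'   effective (outer-leaflet) lipid for peptide titrations, the total
#'   peptide for lipid titrations.
#' @param titrant_totals Strictly increasing titrant axis (M); effective
#'   leaflet concentration when the titrant is lipid.
#' @param signal Signal values (arbitrary units; F/F0 for lipid titrations).
#' @param membrane Optional [membrane_spec].
#' @param electrolyte Optional [electrolyte] describing the salt background.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(mode = c("peptide_into_lipid", "lipid_into_peptide"),
                             fixed_species_total, titrant_totals, signal,
                             membrane = NULL, electrolyte = NULL) {
  mode <- match.arg(mode)
  if (fixed_species_total < 0) stop("fixed_species_total must be >= 0")
  if (any(titrant_totals < 0)) stop("concentrations must be >= 0")
  if (any(diff(titrant_totals) <= 0)) stop("titrant axis must be strictly increasing")
  if (length(signal) != length(titrant_totals))
    stop("signal and titrant_totals must have equal length")
  structure(list(mode = mode, fixed_species_total = fixed_species_total,
                 titrant_totals = as.numeric(titrant_totals),
                 signal = as.numeric(signal), membrane = membrane,
                 electrolyte = electrolyte),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s: fixed %.3g M, %d points, titrant %.3g-%.3g M\n",
              x$mode, x$fixed_species_total, length(x$signal),
              min(x$titrant_totals), max(x$titrant_totals)))
  invisible(x)
}

#' Bound peptide concentration (exact single-site quadratic)
#'
#' Mass-action equilibrium of peptide P binding L_eff/n saturable membrane
#' sites with per-site dissociation constant K_D, solved exactly (free
#' peptide depletion included):
#' `PB = ((P + S + K_D) - sqrt((P + S + K_D)^2 - 4 P S)) / 2`, `S = L_eff/n`.
#'
#' @param P_total Total peptide (M), vectorized.
#' @param L_eff Effective (outer-leaflet) lipid (M), vectorized.
#' @param n Lipids per bound peptide (> 0).
#' @param K_D Per-site dissociation constant (M, > 0).
#' @return Bound peptide concentration (M), bounded by `min(P_total, L_eff/n)`.
#' @export
#' @examples
#' bound_peptide(10e-6, 125e-6, 6.9, 0.29e-6)
bound_peptide <- function(P_total, L_eff, n, K_D) {
  if (any(P_total < 0) || any(L_eff < 0)) stop("concentrations must be >= 0")
  if (n <= 0) stop("n must be positive")
  if (K_D <= 0) stop("K_D must be positive")
  S <- L_eff / n
  b <- P_total + S + K_D
  disc <- b^2 - 4 * P_total * S
  stopifnot(all(disc >= -1e-12 * b^2))  # numerically impossible otherwise
  # conjugate form of the smaller quadratic root: avoids the catastrophic
  # cancellation of (b - sqrt(disc))/2 when 4PS << b^2
  PB <- 2 * P_total * S / (b + sqrt(pmax(disc, 0)))
  pmin(pmax(PB, 0), pmin(P_total, S))
}

# internal: profiled linear amplitudes for a design matrix X and response y
.profile_linear <- function(X, y) {
  qr.coef(qr(X), y)
}

#' Fit peptide-into-lipid titrations
#'
#' Fits `signal(P) = c_f (P - PB) + c_b PB` for the stoichiometry `n`,
#' per-site `K_D` and the free/bound signal coefficients, with `PB` the exact
#' single-site quadratic. Several series at different fixed lipid
#' concentrations may be fit simultaneously with shared `(n, K_D, c_f, c_b)`.
#'
#' @param series A [titration_series] in `peptide_into_lipid` mode, or a list
#'   of them (global fit).
#' @return Object of class `binding_parameters`: `n`, `K_D` (per-site),
#'   `nK_D` (per-lipid-monomer), `c_f`, `c_b`, standard errors, `rss`,
#'   `identifiable` flag.
#' @export
fit_peptide_titration <- function(series) {
  if (inherits(series, "titration_series")) series <- list(series)
  lapply(series, function(s) {
    stopifnot(inherits(s, "titration_series"))
    if (s$mode != "peptide_into_lipid") stop("expected peptide_into_lipid mode")
    if (length(s$signal) < 6L) stop("need at least 6 points per series")
  })
  P <- unlist(lapply(series, `[[`, "titrant_totals"))
  L <- unlist(lapply(series, function(s)
    rep(s$fixed_species_total, length(s$signal))))
  y <- unlist(lapply(series, `[[`, "signal"))

  resid_fn2 <- function(par) {  # par = (log n, log K_D); amplitudes profiled
    PB <- bound_peptide(P, L, exp(par[1]), exp(par[2]))
    X <- cbind(P - PB, PB)
    cf <- .profile_linear(X, y)
    as.numeric(y - X %*% cf)
  }
  Pmed <- stats::median(P[P > 0])
  starts <- expand.grid(ln = log(c(3, 8, 20)),
                        lk = log(Pmed * c(1 / 30, 1 / 3, 1)))
  fit2 <- .lm_multistart(split(as.matrix(starts), seq_len(nrow(starts))),
                         resid_fn2)
  n <- exp(fit2$par[1]); K_D <- exp(fit2$par[2])
  PB <- bound_peptide(P, L, n, K_D)
  cf <- .profile_linear(cbind(P - PB, PB), y)

  # polish all four parameters jointly for the covariance at the optimum
  resid_fn4 <- function(par) {
    PBi <- bound_peptide(P, L, exp(par[1]), exp(par[2]))
    y - (par[3] * (P - PBi) + par[4] * PBi)
  }
  fit4 <- .lm_fit(c(log(n), log(K_D), cf[1], cf[2]), resid_fn4)
  par <- fit4$par
  n <- exp(par[1]); K_D <- exp(par[2])

  # identifiability: compare bound-state signal contribution to signal range
  PB <- bound_peptide(P, L, n, K_D)
  bound_amp <- max(PB) * abs(par[4] - par[3])
  identifiable <- is.finite(bound_amp) &&
    bound_amp > 0.02 * max(diff(range(y)), .Machine$double.eps)
  if (!identifiable)
    warning("binding signal amplitude ~ 0: K_D unidentifiable (no binding?)")
  if (!fit4$converged) warning("peptide-titration fit did not converge")

  structure(list(n = n, K_D = K_D, nK_D = n * K_D,
                 K_P = NA_real_, c_f = par[3], c_b = par[4], r = NA_real_,
                 se = c(n = fit4$se[1] * n, K_D = fit4$se[2] * K_D,
                        nK_D = n * K_D * sqrt(fit4$se[1]^2 + fit4$se[2]^2),
                        c_f = fit4$se[3], c_b = fit4$se[4]),
                 rss = fit4$rss, identifiable = identifiable,
                 converged = fit4$converged, mode = "peptide_into_lipid"),
            class = "binding_parameters")
}

#' Fit a lipid-into-peptide titration
#'
#' Fits `F/F0(L_eff) = 1 + (r - 1) PB / P_total` for `(n, K_D, r)` where `r`
#' is the bound/free fluorescence ratio at saturation. `K_D` here is the
#' per-lipid-monomer dissociation constant (the per-site constant is
#' `K_D / n`).
#'
#' @param series A [titration_series] in `lipid_into_peptide` mode with
#'   signal `F/F0`.
#' @return A `binding_parameters` object; field `K_D` holds the
#'   per-lipid-monomer constant, `nK_D` mirrors it, and `r` the saturation
#'   ratio.
#' @export
fit_lipid_titration <- function(series) {
  fits <- fit_global_salt_series(list(series), shared_saturation = FALSE)
  fits[[1]]
}

#' Globally fit lipid titrations across a salt series
#'
#' Fits several lipid-into-peptide titrations (same membrane, different
#' electrolyte) with a common saturation point `r` and per-series
#' `(n, K_D)`. With a single series this degenerates to
#' [fit_lipid_titration()].
#'
#' @param series_list List of [titration_series] in `lipid_into_peptide`
#'   mode.
#' @param shared_saturation Share `r` across series (default TRUE).
#' @return List of `binding_parameters`, one per series, each carrying the
#'   joint `rss` and the shared `r`.
#' @export
fit_global_salt_series <- function(series_list, shared_saturation = TRUE) {
  stopifnot(length(series_list) >= 1L)
  lapply(series_list, function(s) {
    stopifnot(inherits(s, "titration_series"))
    if (s$mode != "lipid_into_peptide")
      stop("expected lipid_into_peptide mode in every series")
    if (length(s$signal) < 6L) stop("need at least 6 points per series")
  })
  ns <- length(series_list)
  L <- lapply(series_list, `[[`, "titrant_totals")
  P <- vapply(series_list, `[[`, numeric(1), "fixed_species_total")
  y <- lapply(series_list, `[[`, "signal")
  yall <- unlist(y)

  # fraction bound per series given (n, K_D-per-lipid)
  fb <- function(i, n, KDlip) {
    bound_peptide(P[i], L[[i]], n, KDlip / n) / P[i]
  }
  # par: per-series (log n, log K_D); slope (r-1) profiled out
  resid_fn <- function(par) {
    w <- unlist(lapply(seq_len(ns), function(i)
      fb(i, exp(par[2 * i - 1]), exp(par[2 * i]))))
    if (shared_saturation || ns == 1L) {
      b <- sum(w * (yall - 1)) / max(sum(w^2), 1e-300)
      (yall - 1) - b * w
    } else {
      res <- numeric(0)
      idx <- split(seq_along(w), rep(seq_len(ns), lengths(y)))
      for (i in seq_len(ns)) {
        wi <- w[idx[[i]]]; yi <- yall[idx[[i]]] - 1
        b <- sum(wi * yi) / max(sum(wi^2), 1e-300)
        res <- c(res, yi - b * wi)
      }
      res
    }
  }
  Lmed <- stats::median(unlist(L))
  starts <- lapply(c(0.3, 1, 3), function(f)
    rep(c(log(7), log(Lmed * f / 10)), ns))
  fit <- .lm_multistart(starts, resid_fn)

  out <- vector("list", ns)
  w <- unlist(lapply(seq_len(ns), function(i)
    fb(i, exp(fit$par[2 * i - 1]), exp(fit$par[2 * i]))))
  slope <- sum(w * (yall - 1)) / max(sum(w^2), 1e-300)
  for (i in seq_len(ns)) {
    n <- exp(fit$par[2 * i - 1]); KDlip <- exp(fit$par[2 * i])
    wi <- fb(i, n, KDlip)
    r <- 1 + slope
    identifiable <- abs(r - 1) > 1e-6 * max(abs(yall), 1)
    if (!identifiable)
      warning("saturation ratio r ~ 1: no spectral change, fit unidentifiable")
    out[[i]] <- structure(list(
      n = n, K_D = KDlip, nK_D = KDlip, K_P = NA_real_,
      c_f = NA_real_, c_b = NA_real_, r = r,
      se = c(n = fit$se[2 * i - 1] * n, K_D = fit$se[2 * i] * KDlip),
      rss = fit$rss, identifiable = identifiable, converged = fit$converged,
      mode = "lipid_into_peptide"), class = "binding_parameters")
  }
  out
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("<binding_parameters> (%s) n=%.3g K_D=%.3g M nK_D=%.3g M rss=%.3g%s\n",
              x$mode, x$n, x$K_D, x$nK_D, x$rss,
              if (!isTRUE(x$identifiable)) " [UNIDENTIFIABLE]" else ""))
  invisible(x)
}

#' Scatchard transform and linear fit
#'
#' Converts a titration to Scatchard coordinates: `nu` (bound peptide per
#' effective lipid) against `nu / [P_free]`. For exact single-site data the
#' plot is linear with slope `-1/K_D` (per-site) and x-intercept `1/n`.
#'
#' @param series A [titration_series].
#' @param params `binding_parameters` providing the fitted amplitudes used to
#'   convert signal to bound concentration (`c_f`/`c_b` for peptide
#'   titrations, `r` for lipid titrations).
#' @return List with `data` (data.frame `nu`, `nu_over_Pfree`), `K_D`
#'   (per-site, from the slope), `n` (from the x-intercept), `r_squared`, and
#'   `nonlinear` flag raised when a straight line is a poor description
#'   (heterogeneous sites).
#' @export
scatchard_transform <- function(series, params) {
  stopifnot(inherits(series, "titration_series"),
            inherits(params, "binding_parameters"))
  if (series$mode == "peptide_into_lipid") {
    P <- series$titrant_totals
    L <- rep(series$fixed_species_total, length(P))
    PB <- (series$signal - params$c_f * P) / (params$c_b - params$c_f)
  } else {
    P <- rep(series$fixed_species_total, length(series$signal))
    L <- series$titrant_totals
    PB <- P * (series$signal - 1) / (params$r - 1)
  }
  keep <- is.finite(PB) & PB > 0 & PB < P & L > 0
  if (!any(keep)) stop("no usable points (nonpositive free or bound)")
  nu <- PB[keep] / L[keep]
  Pfree <- P[keep] - PB[keep]
  if (any(Pfree <= 0)) stop("nonpositive free peptide concentration")
  yy <- nu / Pfree
  lf <- stats::lm(yy ~ nu)
  slope <- stats::coef(lf)[[2]]
  inter <- stats::coef(lf)[[1]]
  if (slope >= 0) stop("non-negative Scatchard slope: not saturable binding")
  r2 <- summary(lf)$r.squared
  nonlinear <- is.finite(r2) && r2 < 0.99
  if (nonlinear)
    warning("Scatchard plot is nonlinear (R^2 = ", signif(r2, 3),
            "); single-site model questionable")
  list(data = data.frame(nu = nu, nu_over_Pfree = yy),
       K_D = -1 / slope, n = -slope / inter, x_intercept = -inter / slope,
       r_squared = r2, nonlinear = nonlinear)
}

#' Molar partition coefficient from a lipid titration
#'
#' Fits the bound fraction `f_b` of peptide against effective lipid:
#' `site_free` convention `f_b = K_x L / (1 + K_x L)` (K_x in M^-1) or
#' `water_normalized` convention `f_b = K_P L / (W + K_P L)` with
#' `W = 55.3 M` (dimensionless molar partition coefficient). The saturation
#' ratio `r` converting `F/F0` to `f_b` is fitted jointly.
#'
#' @param series A [titration_series] in `lipid_into_peptide` mode.
#' @param convention `"water_normalized"` (default) or `"site_free"`.
#' @param water_molarity Molar concentration of water (default 55.3 M).
#' @return List with `K_P`, `se`, `convention`, `r`, `rss`.
#' @export
partition_coefficient <- function(series,
                                  convention = c("water_normalized", "site_free"),
                                  water_molarity = 55.3) {
  convention <- match.arg(convention)
  stopifnot(inherits(series, "titration_series"))
  if (series$mode != "lipid_into_peptide") stop("expected lipid_into_peptide mode")
  L <- series$titrant_totals
  y <- series$signal
  fbfun <- function(K) {
    if (convention == "site_free") K * L / (1 + K * L)
    else K * L / (water_molarity + K * L)
  }
  resid_fn <- function(par) {  # par = log K; slope (r-1) profiled
    w <- fbfun(exp(par[1]))
    b <- sum(w * (y - 1)) / max(sum(w^2), 1e-300)
    (y - 1) - b * w
  }
  K0 <- if (convention == "site_free") 1 / stats::median(L[L > 0])
        else water_molarity / stats::median(L[L > 0])
  fit <- .lm_multistart(as.list(log(K0 * c(0.1, 1, 10))), resid_fn)
  K <- exp(fit$par[1])
  w <- fbfun(K)
  r <- 1 + sum(w * (y - 1)) / max(sum(w^2), 1e-300)
  if (!fit$converged) warning("partition-coefficient fit did not converge")
  list(K_P = K, se = fit$se[1] * K, convention = convention, r = r,
       rss = fit$rss, converged = fit$converged)
}

#' Fractional saturation of membrane binding sites
#'
#' `theta = PB / (L_eff / n)`, the occupied fraction of saturable sites at a
#' given total peptide.
#'
#' @param P_total Total peptide (M), vectorized.
#' @param params A `binding_parameters` object (per-site `K_D` and `n`).
#' @param L_eff Effective lipid concentration (M).
#' @return Fractional saturation in `[0, 1]`.
#' @export
fractional_saturation <- function(P_total, params, L_eff) {
  stopifnot(inherits(params, "binding_parameters"))
  K_site <- if (params$mode == "lipid_into_peptide") params$K_D / params$n
            else params$K_D
  S <- L_eff / params$n
  if (S <= 0) stop("L_eff must be positive")
  pmin(bound_peptide(P_total, L_eff, params$n, K_site) / S, 1)
}
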