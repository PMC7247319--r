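# Reduction of raw fluorescence readings to the derived statistics used
# throughout: blank subtraction, generalized polarization (laurdan two-band
# and prodan three-wavelength forms), steady-state anisotropy with G-factor
# correction, Stern-Volmer quenching constants, and saturation-curve fits
# (hyperbolic / Hill).

#' Background-subtract a signal series
#'
#' Elementwise `raw - blank`. Negative results are retained (clipping would
#' bias downstream fits) but flagged via the `"negative"` attribute and a
#' warning.
#'
#' @param raw Numeric vector of raw intensities.
#' @param blank Numeric vector of blank intensities, same length.
#' @return Numeric vector `raw - blank` with logical attribute `"negative"`.
#' @export
#' @examples
#' background_subtract(c(100, 200), c(10, 10))
background_subtract <- function(raw, blank) {
  if (length(raw) != length(blank))
    stop("raw and blank must have equal length")
  out <- raw - blank
  neg <- out < 0
  if (any(neg))
    warning(sum(neg), " background-subtracted value(s) are negative ",
            "(noise floor); retained, not clipped")
  attr(out, "negative") <- neg
  out
}

#' Laurdan generalized polarization
#'
#' `GP = (I_440 - I_490) / (I_440 + I_490)`, the two-band emission statistic
#' reporting interfacial hydration / lipid packing (I_440 and I_490 are the
#' gel- and fluid-phase emission maxima).
#'
#' @param I_440,I_490 Emission intensities (counts), non-negative.
#' @return GP in `[-1, 1]`.
#' @export
#' @examples
#' generalized_polarization_laurdan(300, 100)  # 0.5
generalized_polarization_laurdan <- function(I_440, I_490) {
  denom <- I_440 + I_490
  if (any(denom <= 0)) stop("I_440 + I_490 must be positive")
  (I_440 - I_490) / denom
}

#' Prodan three-wavelength generalized polarization
#'
#' The 3wGP statistic `GP = (R_12 - 1)/(R_12 + 1)` with
#' `R_12 = I_420 * k / (I_480 * k - I_530)`. The instrument constant `k`
#' defaults to 2.8.
#'
#' @param I_420,I_480,I_530 Emission intensities (counts).
#' @param k Instrument constant (default 2.8).
#' @return GP value.
#' @export
#' @examples
#' generalized_polarization_prodan(200, 100, 0)  # R_12 = 2 -> 1/3
generalized_polarization_prodan <- function(I_420, I_480, I_530, k = 2.8) {
  denom <- I_480 * k - I_530
  if (any(abs(denom) < .Machine$double.eps * 100))
    stop("singular denominator in R_12 (I_480*k == I_530)")
  R12 <- I_420 * k / denom
  (R12 - 1) / (R12 + 1)
}

#' Steady-state fluorescence anisotropy
#'
#' Computes the G-factor `G = I_HV / I_HH` first, then
#' `r = (I_VV - G I_VH) / (I_VV + 2 G I_VH)`. Values outside the physically
#' meaningful range `[-0.2, 0.4]` are returned with a warning.
#'
#' @param I_VV,I_VH,I_HV,I_HH Polarized emission intensities (counts).
#' @return Anisotropy (dimensionless).
#' @export
#' @examples
#' steady_state_anisotropy(3, 1, 1, 1)  # 0.4
steady_state_anisotropy <- function(I_VV, I_VH, I_HV, I_HH) {
  if (any(I_HH <= 0)) stop("I_HH must be positive (G-factor undefined)")
  G <- I_HV / I_HH
  denom <- I_VV + 2 * G * I_VH
  if (any(denom <= 0)) stop("anisotropy denominator must be positive")
  r <- (I_VV - G * I_VH) / denom
  if (any(r < -0.2 | r > 0.4))
    warning("anisotropy outside the physically meaningful range [-0.2, 0.4]")
  r
}

#' Stern-Volmer quenching fit
#'
#' Fits `(F_0/F) - 1 = K_SV [Q]` by least squares through the origin.
#'
#' @param quencher_concs Quencher concentrations (M), length >= 2.
#' @param F_values Quenched fluorescence at each concentration (> 0).
#' @param F_0 Unquenched fluorescence (scalar or vector).
#' @return List with `K_SV` (M^-1), `se` (standard error of the slope) and
#'   `residuals`.
#' @export
#' @examples
#' stern_volmer_fit(c(0.5, 1), c(100/1.5, 50), 100)
stern_volmer_fit <- function(quencher_concs, F_values, F_0) {
  if (length(quencher_concs) < 2L) stop("need at least 2 points")
  if (length(F_values) != length(quencher_concs))
    stop("quencher_concs and F_values must have equal length")
  if (any(F_values <= 0)) stop("F values must be positive")
  if (all(quencher_concs == 0)) stop("all-zero quencher axis")
  y <- F_0 / F_values - 1
  x <- quencher_concs
  K <- sum(x * y) / sum(x^2)        # closed-form through-origin slope
  res <- y - K * x
  dof <- length(x) - 1L
  se <- if (dof > 0) sqrt(sum(res^2) / dof / sum(x^2)) else NA_real_
  list(K_SV = K, se = se, residuals = res)
}

#' Fit a saturation (dose-response) curve
#'
#' Nonlinear least-squares fit of
#' `y = baseline + amplitude * x^h / (K^h + x^h)`; the hyperbolic model
#' fixes the Hill coefficient `h = 1`. Uses damped least squares with
#' automatic initialization (amplitude from the y-range, half-saturation at
#' the median x).
#'
#' @param x Concentration axis (>= 4 points).
#' @param y Signal values.
#' @param model `"hyperbolic"` (h fixed at 1) or `"hill"`.
#' @return Object of class `saturation_fit`: list with `model`, `amplitude`,
#'   `half_saturation`, `hill_coefficient`, `baseline`, `se` (named vector),
#'   `rss`, `converged`, and `degenerate` flag (TRUE when the signal is flat
#'   and the half-saturation is unidentifiable).
#' @export
#' @examples
#' x <- c(1, 2, 5, 10, 20, 50) * 1e-6
#' y <- x / (10e-6 + x)
#' fit_saturation_curve(x, y, "hyperbolic")
fit_saturation_curve <- function(x, y, model = c("hyperbolic", "hill")) {
  model <- match.arg(model)
  if (length(x) < 4L) stop("need at least 4 points")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0)) stop("concentrations must be non-negative")

  yr <- diff(range(y))
  degenerate <- yr <= max(1e-12, 1e-10 * max(abs(y), 1))
  if (degenerate) {
    warning("flat signal: amplitude ~ 0, half-saturation unidentifiable")
    return(structure(list(model = model, amplitude = 0,
                          half_saturation = NA_real_,
                          hill_coefficient = if (model == "hyperbolic") 1 else NA_real_,
                          baseline = mean(y), se = NULL, rss = sum((y - mean(y))^2),
                          converged = TRUE, degenerate = TRUE),
                     class = "saturation_fit"))
  }

  amp0 <- y[which.max(x)] - y[which.min(x)]
  K0 <- stats::median(x[x > 0])
  b0 <- y[which.min(x)]
  fitted_fn <- function(par) {
    amp <- par[1]; K <- exp(par[2]); b <- par[3]
    h <- if (model == "hill") exp(par[4]) else 1
    b + amp * ifelse(x == 0 & K == 0, 0.5, x^h / (K^h + x^h))
  }
  resid_fn <- function(par) y - fitted_fn(par)
  starts <- lapply(c(0.5, 1, 2), function(f) {
    p <- c(amp0, log(K0 * f), b0)
    if (model == "hill") p <- c(p, log(1.5))
    p
  })
  fit <- .lm_multistart(starts, resid_fn)
  if (!fit$converged)
    warning("saturation fit did not converge; rss = ", format(fit$rss))
  par <- fit$par
  se <- fit$se
  K <- exp(par[2])
  h <- if (model == "hill") exp(par[4]) else 1
  # delta-method SEs for log-scale parameters
  se_named <- c(amplitude = se[1], half_saturation = se[2] * K,
                baseline = se[3],
                hill_coefficient = if (model == "hill") se[4] * h else 0)
  structure(list(model = model, amplitude = par[1], half_saturation = K,
                 hill_coefficient = h, baseline = par[3], se = se_named,
                 rss = fit$rss, converged = fit$converged, degenerate = FALSE),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> model=%s amp=%.4g K=%.4g h=%.3g base=%.4g rss=%.3g%s\n",
              x$model, x$amplitude, x$half_saturation, x$hill_coefficient,
              x$baseline, x$rss, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}
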