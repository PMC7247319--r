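# Internal damped (Levenberg-Marquardt) least-squares engine shared by the
# isotherm, saturation and calorimetry fitters. minpack-style: numeric
# Jacobian, multiplicative damping, parameter covariance from the Jacobian at
# the optimum. Kept internal; user-facing fitters wrap it with model-specific
# parameterisations (positive parameters are fitted on the log scale by the
# callers).

# resid_fn(par) must return the residual vector (observed - fitted).
.lm_fit <- function(par, resid_fn, max_iter = 200L, ftol = 1e-12,
                    ptol = 1e-10, lambda0 = 1e-3) {
  par <- as.numeric(par)
  p <- length(par)
  r <- resid_fn(par)
  if (any(!is.finite(r))) stop("non-finite residuals at starting values")
  rss <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE

  jac <- function(par) {
    m <- length(resid_fn(par))
    J <- matrix(0, m, p)
    for (j in seq_len(p)) {
      h <- max(1e-7, 1e-7 * abs(par[j]))
      pp <- par; pp[j] <- par[j] + h
      pm <- par; pm[j] <- par[j] - h
      J[, j] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h)
    }
    J
  }

  for (iter in seq_len(max_iter)) {
    J <- jac(par)
    if (any(!is.finite(J))) break
    g <- crossprod(J, r)          # gradient of 0.5*rss is -g
    A <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:30) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), p)
      delta <- tryCatch(-solve(Ad, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- par + as.numeric(delta)
        rc <- tryCatch(resid_fn(cand), error = function(e) NULL)
        if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) < rss) {
          step_rel <- max(abs(delta) / pmax(abs(par), 1e-12))
          par <- cand
          drop_rel <- (rss - sum(rc^2)) / max(rss, 1e-300)
          r <- rc; rss <- sum(rc^2)
          lambda <- max(lambda / 4, 1e-12)
          step_ok <- TRUE
          if (drop_rel < ftol || step_rel < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!step_ok) { converged <- TRUE; break }  # no improving step: at optimum
    if (converged) break
  }

  J <- jac(par)
  m <- length(r)
  covmat <- matrix(NA_real_, p, p)
  se <- rep(NA_real_, p)
  if (m > p) {
    s2 <- rss / (m - p)
    A <- crossprod(J)
    ci <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(ci)) {
      covmat <- s2 * ci
      se <- sqrt(pmax(diag(covmat), 0))
    }
  }
  list(par = par, rss = rss, residuals = r, se = se, cov = covmat,
       converged = converged, iterations = iter)
}

# Multistart wrapper: tries each start, keeps the best converged fit.
.lm_multistart <- function(starts, resid_fn, ...) {
  best <- NULL
  errors <- character(0)
  for (s in starts) {
    fit <- tryCatch(.lm_fit(s, resid_fn, ...),
                    error = function(e) { e })
    if (inherits(fit, "error")) { errors <- c(errors, conditionMessage(fit)); next }
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (is.null(best))
    stop("least-squares fit failed from every start: ",
         paste(unique(errors), collapse = "; "))
  best
}
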