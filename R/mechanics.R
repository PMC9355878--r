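#' Stress-relaxation force trace
#'
#' Bundles a force-over-time recording from a parallel-plate compression
#' experiment. Time is in seconds, force in µN. `strain_onset_t` marks the
#' time at which compression was completed; the relaxation fit only uses
#' samples from that time on.
#'
#' @param t Numeric vector of sample times (s), strictly increasing.
#' @param F Numeric vector of forces (µN), same length as `t`, non-negative.
#' @param strain_onset_t Time (s) at which the target strain was reached.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(t, F, strain_onset_t = 0) {
  t <- as.numeric(t)
  F <- as.numeric(F)
  if (length(t) != length(F) || length(t) < 10)
    stop("t and F must have equal length >= 10")
  if (any(!is.finite(t)) || any(!is.finite(F)))
    stop("non-finite values in trace")
  if (any(diff(t) <= 0))
    stop("t must be strictly increasing")
  if (any(F < 0))
    stop("forces must be non-negative")
  structure(list(t = t, F = F, strain_onset_t = strain_onset_t),
            class = "force_trace")
}

#' Plate-compression geometry
#'
#' Geometrical parameters measured manually on 2D side-view images of the
#' compressed lymph node: heights before compression and at equilibrium,
#' length, and the three radii (R3 is the plate-contact radius, R1 and R2
#' the curvature radii of the free surface). All lengths in mm.
#'
#' @param h0,h_eq Height before compression and at equilibrium (mm),
#'   `h_eq <= h0`.
#' @param L Length before compression (mm).
#' @param R1,R2,R3 Measured radii (mm).
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(h0, h_eq, L, R1, R2, R3) {
  vals <- c(h0 = h0, h_eq = h_eq, L = L, R1 = R1, R2 = R2, R3 = R3)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be positive and finite")
  if (h_eq > h0)
    stop("invalid geometry: h_eq must not exceed h0")
  structure(as.list(vals), class = "plate_geometry")
}

#' Fit a double-exponential (generalized Kelvin) relaxation curve
#'
#' Fits `F(t) = F_eq + A1 exp(-t/tau1) + A2 exp(-t/tau2)` to the part of
#' the trace after strain onset (times measured from `strain_onset_t`).
#' Because double exponentials are ill-conditioned, the fit is seeded from
#' a grid of log-spaced timescale pairs: for each candidate `(tau1, tau2)`
#' the amplitudes and asymptote are solved by linear least squares
#' (variable projection), and the best candidates are refined with
#' Levenberg-Marquardt trust-region iterations. Timescales are
#' canonicalised to `tau1 < tau2`.
#'
#' Fits whose slow timescale exceeds half the recording span are flagged
#' `viscosity_undetermined`: the trace is then too short to pin down the
#' slow branch and the derived viscosity should not be used.
#'
#' @param trace A [force_trace()].
#' @param n_starts Number of log-spaced timescale grid values per branch.
#' @param tau_range Range (s) over which starting timescales are log-spaced.
#' @return An object of class `kelvin_fit` with fields `F_eq`, `A1`, `A2`,
#'   `tau1`, `tau2`, `rss`, `converged`, `viscosity_undetermined`.
#' @export
fit_relaxation <- function(trace, n_starts = 8, tau_range = c(1, 1000)) {
  stopifnot(inherits(trace, "force_trace"))
  keep <- trace$t >= trace$strain_onset_t
  t <- trace$t[keep] - trace$strain_onset_t
  y <- trace$F[keep]
  if (length(t) < 10) stop("fewer than 10 samples after strain onset")
  span <- max(t) - min(t)

  new_fit <- function(F_eq, A1, tau1, A2, tau2, rss, converged) {
    if (tau1 > tau2) {            # canonical order: fast branch first
      tmp <- c(A1, tau1); A1 <- A2; tau1 <- tau2; A2 <- tmp[1]; tau2 <- tmp[2]
    }
    structure(list(F_eq = F_eq, A1 = A1, A2 = A2, tau1 = tau1, tau2 = tau2,
                   rss = rss, converged = converged,
                   viscosity_undetermined = tau2 > span / 2),
              class = "kelvin_fit")
  }

  if (diff(range(y)) == 0)        # degenerate single-level curve
    return(new_fit(y[1], 0, 1, 0, 2, 0, TRUE))

  # variable projection on a log-spaced timescale grid
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_starts))
  grid <- expand.grid(tau1 = taus, tau2 = taus)
  grid <- grid[grid$tau1 < grid$tau2, ]
  proj <- function(tau1, tau2) {
    X <- cbind(1, exp(-t / tau1), exp(-t / tau2))
    fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(coef = unname(fit$coefficients), rss = sum(fit$residuals^2))
  }
  cand <- lapply(seq_len(nrow(grid)),
                 function(i) c(grid$tau1[i], grid$tau2[i],
                               {p <- proj(grid$tau1[i], grid$tau2[i])
                                if (is.null(p)) Inf else p$rss}))
  cand <- do.call(rbind, cand)
  ord <- order(cand[, 3])

  best <- NULL
  for (i in head(ord, 3)) {
    tau1 <- cand[i, 1]; tau2 <- cand[i, 2]
    p <- proj(tau1, tau2)
    st <- list(F_eq = p$coef[1], A1 = p$coef[2], tau1 = tau1,
               A2 = p$coef[3], tau2 = tau2)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ F_eq + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
        start = st,
        lower = c(F_eq = 0, A1 = -Inf, tau1 = 1e-6, A2 = -Inf, tau2 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(F_eq = cf[["F_eq"]], A1 = cf[["A1"]], tau1 = cf[["tau1"]],
                   A2 = cf[["A2"]], tau2 = cf[["tau2"]], rss = rss)
    }
  }

  if (is.null(best)) {
    # all refinements failed: report the best grid candidate with a warning
    i <- ord[1]
    if (!is.finite(cand[i, 3]))
      stop("fit-failure: no double-exponential candidate converged")
    warning("Levenberg-Marquardt refinement failed; returning grid solution")
    p <- proj(cand[i, 1], cand[i, 2])
    return(new_fit(p$coef[1], p$coef[2], cand[i, 1], p$coef[3], cand[i, 2],
                   p$rss, FALSE))
  }
  new_fit(best$F_eq, best$A1, best$tau1, best$A2, best$tau2, best$rss, TRUE)
}

#' @export
print.kelvin_fit <- function(x, ...) {
  cat(sprintf("Generalized Kelvin relaxation fit\n  F_eq = %.4g uN\n", x$F_eq))
  cat(sprintf("  fast branch: A1 = %.4g uN, tau1 = %.4g s\n", x$A1, x$tau1))
  cat(sprintf("  slow branch: A2 = %.4g uN, tau2 = %.4g s\n", x$A2, x$tau2))
  cat(sprintf("  rss = %.4g uN^2%s\n", x$rss,
              if (isTRUE(x$viscosity_undetermined)) "  [viscosity undetermined]" else ""))
  invisible(x)
}

#' Compressive strain from heights
#'
#' `eps = 1 - h_eq/h0`; compression to 75% of the original height gives a
#' strain of 0.25.
#'
#' @param h0 Height before compression (mm).
#' @param h_eq Height at equilibrium (mm).
#' @return Dimensionless strain in `[0, 1)`.
#' @export
strain <- function(h0, h_eq) {
  if (any(h0 <= 0) || any(h_eq <= 0)) stop("heights must be positive")
  if (any(h_eq > h0)) stop("invalid geometry: h_eq exceeds h0")
  1 - h_eq / h0
}

#' Effective resistance of the organ
#'
#' At force equilibrium the plate force balances the collective resistance
#' of the node to expansion. The effective resistance (a surface-tension
#' like quantity, N/m) is the equilibrium stress divided by the total
#' surface curvature: `sigma = (F_eq / (pi R3^2)) / (1/R1 + 1/R2)`.
#' Inputs are in bench units (µN, mm); the result is converted to SI.
#'
#' @param F_eq Equilibrium force (µN).
#' @param geom A [plate_geometry()].
#' @return Effective resistance in N/m.
#' @export
effective_resistance <- function(F_eq, geom) {
  stopifnot(inherits(geom, "plate_geometry"))
  if (F_eq < 0) stop("F_eq must be non-negative")
  F_N <- F_eq * 1e-6
  R1 <- geom$R1 * 1e-3; R2 <- geom$R2 * 1e-3; R3 <- geom$R3 * 1e-3
  (F_N / (pi * R3^2)) / (1 / R1 + 1 / R2)
}

#' Equilibrium stress under the plate
#'
#' `s = F_eq / (pi R3^2)` with `F_eq` in µN and `R3` in mm; because
#' µN/mm² equals Pa, the value is returned in Pa.
#'
#' @param F_eq Equilibrium force (µN).
#' @param R3 Plate-contact radius (mm).
#' @return Stress in Pa.
#' @export
equilibrium_stress <- function(F_eq, R3) {
  if (R3 <= 0) stop("invalid geometry: R3 must be positive")
  if (F_eq < 0) stop("F_eq must be non-negative")
  F_eq / (pi * R3^2)
}

#' Young's modulus from equilibrium stress and strain
#'
#' `E = s / eps` with `s = F_eq / (pi R3^2)`.
#'
#' @param F_eq Equilibrium force (µN).
#' @param R3 Plate-contact radius (mm).
#' @param eps Dimensionless strain, > 0.
#' @return Young's modulus in Pa.
#' @export
youngs_modulus <- function(F_eq, R3, eps) {
  if (eps <= 0) stop("invalid strain: eps must be positive")
  equilibrium_stress(F_eq, R3) / eps
}

#' Spring and dashpot constants from the relaxation fit
#'
#' The two relaxation timescales satisfy `tau_i = mu_i / k_i`. The spring
#' constants are taken as the stress amplitude of each decay branch over
#' the applied strain, `k_i = (A_i / (pi R3^2)) / eps`, and the dashpot
#' constants follow as `mu_i = k_i tau_i`. `mu1` belongs to the fast
#' (seconds) branch and `mu2` to the slow (minutes) branch; the slow
#' branch reflects cellular rearrangement and is reported as the tissue
#' viscosity.
#'
#' @param fit A [fit_relaxation()] result.
#' @param geom A [plate_geometry()].
#' @param eps Dimensionless strain, > 0.
#' @return List with `k1`, `k2` (Pa) and `mu1`, `mu2` (Pa s).
#' @export
viscosities <- function(fit, geom, eps) {
  stopifnot(inherits(fit, "kelvin_fit"), inherits(geom, "plate_geometry"))
  if (eps <= 0) stop("invalid strain: eps must be positive")
  if (fit$A1 < 0 || fit$A2 < 0)
    stop("fit-quality error: negative decay amplitude")
  k1 <- equilibrium_stress(fit$A1, geom$R3) / eps
  k2 <- equilibrium_stress(fit$A2, geom$R3) / eps
  list(k1 = k1, k2 = k2, mu1 = k1 * fit$tau1, mu2 = k2 * fit$tau2)
}

#' Lymph-node volume from a side view
#'
#' Approximates the node as an ellipsoid of revolution measured on the
#' pre-compression side view: `V = 4/3 pi R1 (h0/2)^2`.
#'
#' @param R1 Long-axis radius (mm).
#' @param h0 Height before compression (mm).
#' @return Volume in mm³.
#' @export
ln_volume_from_sideview <- function(R1, h0) {
  if (R1 <= 0 || h0 <= 0) stop("R1 and h0 must be positive")
  4 / 3 * pi * R1 * (h0 / 2)^2
}

#' Micropipette aspiration measurement
#'
#' @param delta_P Pressure difference between pipette and atmosphere (Pa).
#' @param d Pipette inner diameter (µm).
#' @param h Aspirated tongue height (µm).
#' @return An object of class `aspiration_measurement`.
#' @export
aspiration_measurement <- function(delta_P, d, h) {
  if (delta_P <= 0) stop("delta_P must be positive")
  if (d <= 0) stop("pipette diameter must be positive")
  if (h < 0) stop("tongue height must be non-negative")
  structure(list(delta_P = delta_P, d = d, h = h),
            class = "aspiration_measurement")
}

#' Capsule Young's modulus from aspiration (Laplace's law)
#'
#' `E = delta_P / (h/d)^2`: the further the capsule tongue is drawn into
#' the pipette at a given suction pressure, the softer the capsule.
#'
#' @param m An [aspiration_measurement()].
#' @return Young's modulus in Pa.
#' @export
aspiration_modulus <- function(m) {
  stopifnot(inherits(m, "aspiration_measurement"))
  if (m$h == 0) stop("no aspiration: tongue height is zero")
  m$delta_P / (m$h / m$d)^2
}

#' Passive capsule tension
#'
#' The product of the capsule Young's modulus and its thickness: the force
#' per unit length needed to stretch the full capsule thickness.
#'
#' @param E_capsule Capsule Young's modulus (Pa).
#' @param thickness Capsule thickness (µm).
#' @return Tension in N/m.
#' @export
passive_tension <- function(E_capsule, thickness) {
  if (E_capsule < 0 || thickness < 0) stop("inputs must be non-negative")
  E_capsule * thickness * 1e-6
}

#' Full mechanical read-out of a compression experiment
#'
#' Convenience wrapper: fits the relaxation curve and derives strain,
#' stress, Young's modulus, effective resistance, spring/dashpot constants
#' and the pre-compression volume from one trace plus its geometry.
#'
#' @param trace A [force_trace()].
#' @param geom A [plate_geometry()].
#' @param ... Passed to [fit_relaxation()].
#' @return An object of class `tissue_mechanics`.
#' @export
analyze_relaxation <- function(trace, geom, ...) {
  fit <- fit_relaxation(trace, ...)
  eps <- strain(geom$h0, geom$h_eq)
  mu <- viscosities(fit, geom, eps)
  structure(list(
    fit = fit,
    strain = eps,
    stress = equilibrium_stress(fit$F_eq, geom$R3),
    E = youngs_modulus(fit$F_eq, geom$R3, eps),
    sigma = effective_resistance(fit$F_eq, geom),
    k1 = mu$k1, k2 = mu$k2, mu1 = mu$mu1, mu2 = mu$mu2,
    volume = ln_volume_from_sideview(geom$R1, geom$h0)
  ), class = "tissue_mechanics")
}

#' @export
print.tissue_mechanics <- function(x, ...) {
  cat("Lymph-node tissue mechanics\n")
  cat(sprintf("  strain eps            = %.3f\n", x$strain))
  cat(sprintf("  stress s              = %.4g Pa\n", x$stress))
  cat(sprintf("  Young's modulus E     = %.4g Pa\n", x$E))
  cat(sprintf("  effective resistance  = %.4g N/m\n", x$sigma))
  cat(sprintf("  viscosity mu2         = %.4g Pa s%s\n", x$mu2,
              if (isTRUE(x$fit$viscosity_undetermined)) "  [undetermined]" else ""))
  cat(sprintf("  volume V              = %.4g mm^3\n", x$volume))
  invisible(x)
}
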