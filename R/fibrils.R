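#' Traced collagen fibril
#'
#' An ordered 3D polyline in nm, as exported from manual filament tracing.
#'
#' @param points n x 3 matrix of coordinates (nm), n >= 2, consecutive
#'   points distinct.
#' @param id Optional label.
#' @return An object of class `fibril_trace`.
#' @export
fibril_trace <- function(points, id = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2)
    stop("a fibril needs >= 2 points with 3 coordinates")
  if (any(!is.finite(points))) stop("non-finite coordinates")
  if (any(rowSums(diff(points)^2) == 0))
    stop("consecutive points must be distinct")
  dimnames(points) <- NULL
  structure(list(points = points, id = id), class = "fibril_trace")
}

#' Smooth a fibril trace
#'
#' Centred moving average over the coordinates to damp manual tracing
#' jitter. The window is truncated symmetrically at the ends, so the
#' point count is preserved.
#'
#' @param trace A [fibril_trace()].
#' @param window Odd window length (points); `window = 1` is the identity.
#' @return The smoothed `fibril_trace`.
#' @export
smooth_trace <- function(trace, window) {
  stopifnot(inherits(trace, "fibril_trace"))
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  n <- nrow(trace$points)
  if (window > 2 * n) stop("invalid parameter: window larger than twice the trace")
  if (window == 1) return(trace)
  half <- (window - 1) / 2
  sm <- t(vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    w <- min(i - lo, hi - i)           # symmetric truncation at the ends
    colMeans(trace$points[(i - w):(i + w), , drop = FALSE])
  }, numeric(3)))
  # collapse accidental duplicate points created by heavy smoothing
  keep <- c(TRUE, rowSums(diff(sm)^2) > 0)
  fibril_trace(sm[keep, , drop = FALSE], trace$id)
}

# natural cubic spline through 4 supports, chord-length parameterised
.make_spline <- function(supports) {
  supports <- as.matrix(supports)
  ch <- c(0, cumsum(sqrt(rowSums(diff(supports)^2))))
  if (any(diff(ch) == 0)) ch <- seq(0, 1, length.out = nrow(supports))
  u <- ch / max(ch)
  fx <- splinefun(u, supports[, 1], method = "natural")
  fy <- splinefun(u, supports[, 2], method = "natural")
  fz <- splinefun(u, supports[, 3], method = "natural")
  list(eval = function(uu, deriv = 0)
         cbind(fx(uu, deriv), fy(uu, deriv), fz(uu, deriv)),
       knots_u = u)
}

.spline_geometry <- function(sp, n_dense = 400) {
  u <- seq(0, 1, length.out = n_dense)
  P <- sp$eval(u)
  d1 <- sp$eval(u, 1)
  d2 <- sp$eval(u, 2)
  speed <- sqrt(rowSums(d1^2))
  ds <- c(0, (speed[-1] + speed[-n_dense]) / 2 * diff(u))
  arc <- cumsum(ds)
  cross <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                 d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                 d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  kappa <- sqrt(rowSums(cross^2)) / pmax(speed, 1e-12)^3
  list(u = u, P = P, speed = speed, arc = arc, kappa = kappa)
}

#' Fit a conduit centerline to a fibril bundle
#'
#' The centerline is a natural cubic spline through four support points.
#' The supports minimise a composite cost with four dimensionless terms:
#' the mean squared distance of the fibril points to the spline (data),
#' the integrated squared curvature (curvature), the squared mismatch
#' between spline arc length and the bundle length (length; the bundle
#' length is estimated as the arc length of a coarse slab-centroid
#' polyline through the point cloud), and the variance of the
#' inter-support arc spacings (spacing). All terms are
#' scale-normalised by the bundle length, so the fit is covariant
#' under uniform scaling with unchanged weights. Optimisation is
#' multi-start Nelder-Mead initialised from centroids of the point cloud
#' split along its principal axis; supplying `supports` skips the
#' optimisation entirely (the manual-override escape hatch).
#'
#' @param fibrils List of [fibril_trace()]s.
#' @param weights Named weights `c(data =, curv =, len =, space =)`.
#' @param n_starts Number of optimisation restarts (first from the
#'   principal-axis init, the rest jittered deterministically).
#' @param supports Optional 4 x 3 matrix of hand-set support points (nm).
#' @return An object of class `centerline_spline` with `support_points`,
#'   an `eval(u, deriv)` function on `u` in `[0, 1]`, `cost_terms` and a
#'   `converged` flag.
#' @export
fit_centerline <- function(fibrils,
                           weights = c(data = 1, curv = 1e-3,
                                       len = 1e-2, space = 1e-2),
                           n_starts = 2, supports = NULL) {
  if (inherits(fibrils, "fibril_trace")) fibrils <- list(fibrils)
  stopifnot(all(vapply(fibrils, inherits, logical(1), "fibril_trace")))
  if (any(weights <= 0)) stop("weights must be positive")

  if (!is.null(supports)) {           # hand-set centerline: no optimisation
    sup <- as.matrix(supports)
    if (!all(dim(sup) == c(4, 3))) stop("supports must be a 4 x 3 matrix")
    sp <- .make_spline(sup)
    return(structure(list(support_points = sup, eval = sp$eval,
                          cost_terms = NULL, converged = NA, manual = TRUE),
                     class = "centerline_spline"))
  }
  if (!length(fibrils)) stop("at least one fibril required")
  pts <- do.call(rbind, lapply(fibrils, `[[`, "points"))
  # bundle length: arc length of a coarse centroid polyline along the
  # principal axis (individual fibrils are much shorter than the conduit)
  ctr0 <- colMeans(pts)
  pc0 <- svd(sweep(pts, 2, ctr0))$v[, 1]
  proj0 <- as.numeric(sweep(pts, 2, ctr0) %*% pc0)
  qs0 <- quantile(proj0, seq(0, 1, length.out = 9))
  cent <- t(vapply(seq_len(8), function(i) {
    sel <- proj0 >= qs0[i] & proj0 <= qs0[i + 1]
    colMeans(pts[sel, , drop = FALSE])
  }, numeric(3)))
  # slab centroids sit mid-slab, so the polyline misses ~half a slab at
  # each end; 8/7 stretches it back to the full bundle length
  Lbar <- sum(sqrt(rowSums(diff(cent)^2))) * 8 / 7

  # subsample the bundle points for the data term (cost evaluations are
  # the optimisation bottleneck; 400 points pin the centerline just as well)
  fit_pts <- if (nrow(pts) > 400)
    pts[seq(1, nrow(pts), length.out = 400), , drop = FALSE] else pts

  cost_terms <- function(sup, n_dense = 150) {
    sp <- .make_spline(matrix(sup, 4, 3))
    g <- .spline_geometry(sp, n_dense)
    # data: nearest dense-sample distance, normalised by Lbar^2
    d2 <- .min_dist2(fit_pts, g$P)
    term_data <- mean(d2) / Lbar^2
    # curvature: integral of kappa^2 ds, made dimensionless with Lbar
    term_curv <- sum(g$kappa^2 * c(0, diff(g$arc))) * Lbar
    # length mismatch
    term_len <- ((max(g$arc) - Lbar) / Lbar)^2
    # even spacing of supports in arc length
    su <- vapply(sp$knots_u, function(k) g$arc[which.min(abs(g$u - k))],
                 numeric(1))
    gaps <- diff(su)
    term_space <- if (mean(gaps) > 0) var(gaps) / mean(gaps)^2 else 0
    c(data = term_data, curv = term_curv, len = term_len, space = term_space)
  }
  cost <- function(sup) sum(weights * cost_terms(sup))

  # principal-axis init: centroids of 4 slabs along PC1
  ctr <- colMeans(pts)
  pc <- svd(sweep(pts, 2, ctr))$v[, 1]
  proj <- as.numeric(sweep(pts, 2, ctr) %*% pc)
  qs <- quantile(proj, c(0, 0.25, 0.5, 0.75, 1))
  init <- t(vapply(seq_len(4), function(i) {
    sel <- proj >= qs[i] & proj <= qs[i + 1]
    colMeans(pts[sel, , drop = FALSE])
  }, numeric(3)))

  best <- NULL
  jit_rng <- 0.05 * Lbar
  for (s in seq_len(n_starts)) {
    x0 <- as.numeric(init)
    if (s > 1) x0 <- x0 + .with_seed(1000L + s, rnorm(12, 0, jit_rng))
    op <- optim(x0, cost, method = "Nelder-Mead",
                control = list(maxit = 1200, reltol = 1e-9))
    if (is.null(best) || op$value < best$value) best <- op
  }
  sup <- matrix(best$par, 4, 3)
  sp <- .make_spline(sup)
  structure(list(support_points = sup, eval = sp$eval,
                 cost_terms = cost_terms(best$par), cost = best$value,
                 converged = best$convergence == 0, manual = FALSE),
            class = "centerline_spline")
}

# squared distance from each query point to the nearest row of ref
.min_dist2 <- function(query, ref) {
  r2 <- rowSums(ref^2)
  out <- numeric(nrow(query))
  step <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1L, nrow(query), by = step)) {
    idx <- s:min(nrow(query), s + step - 1L)
    D <- outer(rowSums(query[idx, , drop = FALSE]^2), r2, `+`) -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx] <- apply(D, 1, min)
  }
  pmax(out, 0)
}

# parameter u of the centerline point nearest to p (dense scan + local
# quadratic refinement)
.nearest_u <- function(p, sp, n_dense = 1000) {
  u <- seq(0, 1, length.out = n_dense)
  P <- sp$eval(u)
  d2 <- rowSums(sweep(P, 2, p)^2)
  i <- which.min(d2)
  if (i == 1 || i == n_dense) return(u[i])
  # parabola through the three bracketing samples
  y <- d2[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom <= 0) return(u[i])
  u[i] + 0.5 * (y[1] - y[3]) / denom * (u[2] - u[1])
}

#' Per-point and per-fibril alignment angles
#'
#' At `n_samples` points along the fibril the local fibril tangent
#' (central differences on the polyline) is compared with the centerline
#' tangent at the nearest centerline point. The angle is
#' `acos(abs(v_fibril . v_centerline / (|v_fibril| |v_centerline|)))`,
#' folding antiparallel directions together so all angles lie in
#' `[0, 90]` degrees; the per-fibril angle is the arithmetic mean.
#'
#' @param fibril A [fibril_trace()].
#' @param centerline A [fit_centerline()] result.
#' @param n_samples Number of sample points; defaults to all polyline
#'   vertices.
#' @return List with `per_point_angles` (deg) and `mean_angle` (deg).
#' @export
segment_angles <- function(fibril, centerline, n_samples = NULL) {
  stopifnot(inherits(fibril, "fibril_trace"),
            inherits(centerline, "centerline_spline"))
  P <- fibril$points
  n <- nrow(P)
  idx <- if (is.null(n_samples)) seq_len(n) else
    unique(round(seq(1, n, length.out = max(1, n_samples))))
  angles <- numeric(0)
  for (i in idx) {
    a <- P[min(i + 1, n), ] - P[max(i - 1, 1), ]   # central difference
    la <- sqrt(sum(a^2))
    if (la == 0) { warning("zero-length tangent skipped"); next }
    u <- .nearest_u(P[i, ], centerline)
    b <- centerline$eval(u, 1)
    lb <- sqrt(sum(b^2))
    if (lb == 0) { warning("zero-length centerline tangent skipped"); next }
    cosang <- abs(sum(a * b) / (la * lb))
    angles <- c(angles, acos(min(1, cosang)) * 180 / pi)
  }
  list(per_point_angles = angles, mean_angle = mean(angles))
}

#' Alignment distribution of a fibril bundle
#'
#' Per-fibril mean alignment angles against the fitted centerline,
#' with the bundle mean and dispersion.
#'
#' @param fibrils List of [fibril_trace()]s.
#' @param centerline A [fit_centerline()] result.
#' @param n_samples Samples per fibril (default: all vertices).
#' @return An object of class `alignment_result` with `per_fibril_angle`,
#'   `mean`, `sd`.
#' @export
alignment_distribution <- function(fibrils, centerline, n_samples = NULL) {
  if (inherits(fibrils, "fibril_trace")) fibrils <- list(fibrils)
  if (!length(fibrils)) stop("at least one fibril required")
  per <- vapply(fibrils, function(f)
    segment_angles(f, centerline, n_samples)$mean_angle, numeric(1))
  structure(list(per_fibril_angle = per, mean = mean(per),
                 sd = if (length(per) > 1) sd(per) else NA_real_),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Fibril alignment: %d fibrils, mean angle %.2f deg (sd %.2f)\n",
              length(x$per_fibril_angle), x$mean, x$sd))
  invisible(x)
}
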