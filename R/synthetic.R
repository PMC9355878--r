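# Seeded generators with known ground truth for every pipeline stage.
# Each generator runs on its own RNG stream (the caller's stream is
# saved and restored), so identical arguments give bit-identical output.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic stress-relaxation trace
#'
#' `F(t) = F_eq + A1 exp(-t/tau1) + A2 exp(-t/tau2)` plus Gaussian noise,
#' with a default plate geometry consistent with a 25% strain
#' compression. The generating parameters are echoed as ground truth,
#' including the effective resistance, Young's modulus and viscosities
#' they imply.
#'
#' @param F_eq,A1,tau1,A2,tau2 Generating parameters (µN, s); `tau1 <
#'   tau2`.
#' @param noise_sd Gaussian noise s.d. (µN).
#' @param duration Recording length (s); at least `3 * tau2` is
#'   recommended.
#' @param dt Sampling interval (s).
#' @param geometry A [plate_geometry()]; default is a 2 mm node
#'   compressed to 1.5 mm.
#' @param seed Integer seed.
#' @return List with `trace`, `geometry` and `truth`.
#' @export
gen_relaxation_trace <- function(F_eq = 40, A1 = 30, tau1 = 5, A2 = 20,
                                 tau2 = 300, noise_sd = 0.01 * F_eq,
                                 duration = 3 * tau2, dt = 1,
                                 geometry = NULL, seed = 1) {
  if (dt <= 0) stop("invalid dt")
  if (tau1 >= tau2) stop("tau1 must be smaller than tau2")
  if (is.null(geometry))
    geometry <- plate_geometry(h0 = 2, h_eq = 1.5, L = 2.4,
                               R1 = 1, R2 = 1, R3 = 0.5)
  .with_seed(seed, {
    t <- seq(0, duration, by = dt)
    f0 <- F_eq + A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    f <- pmax(0, f0 + rnorm(length(t), 0, noise_sd))
    eps <- strain(geometry$h0, geometry$h_eq)
    k1 <- equilibrium_stress(A1, geometry$R3) / eps
    k2 <- equilibrium_stress(A2, geometry$R3) / eps
    list(trace = force_trace(t, f),
         geometry = geometry,
         truth = list(F_eq = F_eq, A1 = A1, tau1 = tau1, A2 = A2,
                      tau2 = tau2, noise_sd = noise_sd, eps = eps,
                      sigma = effective_resistance(F_eq, geometry),
                      E = youngs_modulus(F_eq, geometry$R3, eps),
                      k1 = k1, k2 = k2,
                      mu1 = k1 * tau1, mu2 = k2 * tau2))
  })
}

#' Generate a lattice network mask with known gap size
#'
#' A regular lattice of network strands of width `strand_width` px spaced
#' `lattice_pitch` px apart, in 2D (square gaps) or 3D (cubic cavities).
#' The true inscribed gap diameter is `lattice_pitch - strand_width`.
#' Optional jitter shifts each wall by a random offset.
#'
#' @param mode `"2d"` or `"3d"`.
#' @param size Image side length (px); used for every dimension.
#' @param lattice_pitch Wall spacing (px).
#' @param strand_width Wall thickness (px); 0 gives a single all-gap
#'   image.
#' @param jitter Max absolute wall displacement (px).
#' @param pixel_size µm per px for the returned mask.
#' @param seed Integer seed (used only when `jitter > 0`).
#' @return List with `mask` (a [network_mask()]) and `truth`
#'   (`gap_diameter_px`).
#' @export
gen_network_mask <- function(mode = c("2d", "3d"), size = 64,
                             lattice_pitch = 20, strand_width = 4,
                             jitter = 0, pixel_size = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (lattice_pitch <= strand_width) stop("pitch must exceed strand width")
  nd <- if (mode == "2d") 2L else 3L
  dims <- rep(size, nd)
  .with_seed(seed, {
    wall_1d <- function() {
      on <- rep(FALSE, size)
      starts <- seq(1, size, by = lattice_pitch)
      if (jitter > 0)
        starts <- pmax(1, pmin(size, starts +
                                 round(runif(length(starts), -jitter, jitter))))
      for (s in starts) {
        idx <- s:min(size, s + strand_width - 1)
        if (strand_width > 0) on[idx] <- TRUE
      }
      on
    }
    if (strand_width == 0) {
      vox <- array(FALSE, dims)
    } else {
      walls <- lapply(seq_len(nd), function(i) wall_1d())
      vox <- array(FALSE, dims)
      if (nd == 2L) {
        vox[walls[[1]], ] <- TRUE
        vox[, walls[[2]]] <- TRUE
      } else {
        vox[walls[[1]], , ] <- TRUE
        vox[, walls[[2]], ] <- TRUE
        vox[, , walls[[3]]] <- TRUE
      }
    }
    list(mask = network_mask(vox, pixel_size),
         truth = list(gap_diameter_px = lattice_pitch - strand_width,
                      gap_diameter_um = (lattice_pitch - strand_width) * pixel_size))
  })
}

# uniform unit vector at a fixed polar angle around axis `t`
.cone_dir <- function(tangent, theta_deg, phi) {
  tangent <- tangent / sqrt(sum(tangent^2))
  a <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- a - sum(a * tangent) * tangent
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(tangent[2] * n1[3] - tangent[3] * n1[2],
          tangent[3] * n1[1] - tangent[1] * n1[3],
          tangent[1] * n1[2] - tangent[2] * n1[1])
  th <- theta_deg * pi / 180
  cos(th) * tangent + sin(th) * (cos(phi) * n1 + sin(phi) * n2)
}

#' Generate clonally clustered two-channel cell data
#'
#' Emulates sparse lineage labelling: parent cells are placed uniformly
#' in the analysis region (node interior eroded by the edge margin, minus
#' HEV volumes), each parent spawns Gaussian-dispersed offspring of its
#' lineage, and unclustered singletons are added per lineage. The red
#' channel is rigidly misaligned by `channel_transform` to exercise the
#' registration step. True cluster memberships are recorded.
#'
#' @param masks A [region_masks()].
#' @param n_parents Number of clone parents.
#' @param offspring_per_parent Offspring per parent (the parent itself is
#'   included in the clone, so clone size is `offspring_per_parent`).
#' @param dispersion_sd_um Gaussian dispersion of offspring around the
#'   parent (µm).
#' @param n_singletons Singleton cells added per lineage.
#' @param n_double Double-labelled cells whose spot appears in both
#'   channels (these provide the true correspondences that anchor the
#'   channel registration, and become yellow cells downstream).
#' @param channel_transform `list(rotation = 3x3, translation = 3-vector)`
#'   applied to the red channel, or `NULL` for perfect alignment.
#' @param seed Integer seed.
#' @return List with `green`, `red` ([spot_set()]s), `masks`, and `truth`
#'   (true positions, lineages, clone ids, the transform).
#' @export
gen_madm_cells <- function(masks = region_masks(), n_parents = 15,
                           offspring_per_parent = 10, dispersion_sd_um = 8,
                           n_singletons = 150, n_double = 0,
                           channel_transform = NULL, seed = 1) {
  stopifnot(inherits(masks, "region_masks"))
  .with_seed(seed, {
    parents <- .sample_region(n_parents, masks)
    lineage_p <- rep(c("green", "red"), length.out = max(n_parents, 1))
    pos <- NULL; lin <- character(0); clone <- integer(0)
    if (n_parents > 0) {
      for (i in seq_len(n_parents)) {
        k <- offspring_per_parent
        pts <- sweep(matrix(rnorm(3 * k, 0, dispersion_sd_um), k, 3), 2,
                     parents[i, ], `+`)
        pos <- rbind(pos, pts)
        lin <- c(lin, rep(lineage_p[i], k))
        clone <- c(clone, rep(i, k))
      }
    }
    for (lg in c("green", "red")) {
      if (n_singletons > 0) {
        pts <- .sample_region(n_singletons, masks)
        pos <- rbind(pos, pts)
        lin <- c(lin, rep(lg, n_singletons))
        clone <- c(clone, rep(0L, n_singletons))
      }
    }
    if (n_double > 0) {
      pts <- .sample_region(n_double, masks)
      pos <- rbind(pos, pts)
      lin <- c(lin, rep("yellow", n_double))
      clone <- c(clone, rep(0L, n_double))
    }
    if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
    g <- pos[lin %in% c("green", "yellow"), , drop = FALSE]
    r <- pos[lin %in% c("red", "yellow"), , drop = FALSE]
    if (!is.null(channel_transform))
      r <- sweep(r %*% t(channel_transform$rotation), 2,
                 channel_transform$translation, `+`)
    list(green = spot_set(g, "green"), red = spot_set(r, "red"),
         masks = masks,
         truth = list(positions = pos, lineage = lin, clone = clone,
                      transform = channel_transform,
                      n_parents = n_parents,
                      offspring_per_parent = offspring_per_parent,
                      dispersion_sd_um = dispersion_sd_um))
  })
}

#' Generate a fibril bundle with known angular dispersion
#'
#' Straight fibrils whose directions deviate from the local centerline
#' tangent by exactly `half_angle_deg` (azimuth uniform on the cone),
#' starting within `bundle_radius` of the centerline at uniformly drawn
#' arc positions.
#'
#' @param centerline_supports 4 x 3 matrix of support points (nm); the
#'   true centerline is the natural cubic spline through them.
#' @param n_fibrils Number of fibrils.
#' @param half_angle_deg Cone half-angle (deg), in `[0, 90)`.
#' @param fibril_length Fibril length (nm).
#' @param bundle_radius Max radial offset of fibril start points (nm).
#' @param n_points Polyline vertices per fibril.
#' @param seed Integer seed.
#' @return List with `fibrils` (list of [fibril_trace()]), `centerline`
#'   (the true [fit_centerline()]-style spline, built from the supports)
#'   and `truth`.
#' @export
gen_fibril_bundle <- function(centerline_supports, n_fibrils = 30,
                              half_angle_deg = 20, fibril_length = 400,
                              bundle_radius = 60, n_points = 9, seed = 1) {
  if (half_angle_deg < 0 || half_angle_deg >= 90)
    stop("half_angle_deg must be in [0, 90)")
  sup <- as.matrix(centerline_supports)
  sp <- .make_spline(sup)
  .with_seed(seed, {
    fibs <- vector("list", n_fibrils)
    for (i in seq_len(n_fibrils)) {
      u0 <- runif(1, 0.1, 0.9)
      tang <- sp$eval(u0, 1)
      tang <- tang / sqrt(sum(tang^2))
      # random radial offset perpendicular to the centerline
      off <- .cone_dir(tang, 90, runif(1, 0, 2 * pi)) *
        runif(1, 0, bundle_radius)
      base <- as.numeric(sp$eval(u0)) + as.numeric(off)
      dirv <- .cone_dir(tang, half_angle_deg, runif(1, 0, 2 * pi))
      s <- seq(-fibril_length / 2, fibril_length / 2, length.out = n_points)
      fibs[[i]] <- fibril_trace(sweep(outer(s, as.numeric(dirv)), 2, base, `+`),
                                id = i)
    }
    truthline <- structure(list(support_points = sup, eval = sp$eval,
                                cost_terms = NULL, converged = NA,
                                manual = TRUE),
                           class = "centerline_spline")
    list(fibrils = fibs, centerline = truthline,
         truth = list(supports = sup, half_angle_deg = half_angle_deg,
                      fibril_length = fibril_length))
  })
}

#' Generate a synthetic recoil movie, kymograph and cut geometry
#'
#' A textured band (sum of random plane waves) initially abuts a vertical
#' cut line; from the cut frame on it retracts away from the cut at a
#' constant velocity. Frames are sampled continuously, so sub-pixel
#' displacements are faithful. The kymograph is taken along the recoil
#' axis through the image centre.
#'
#' @param v_um_s True recoil speed (µm/s), >= 0.
#' @param px_size µm per px.
#' @param frame_interval s per frame.
#' @param n_frames Total frames.
#' @param cut_frame First post-cut frame.
#' @param nx,ny Image size (px); x is the recoil axis.
#' @param noise_sd Additive Gaussian noise s.d. (intensity units; the
#'   texture has s.d. about 1).
#' @param seed Integer seed.
#' @return List with `frames` (list of matrices), `kymo`
#'   (a [kymograph()]), `cut` (a [cut_geometry()]) and `truth`.
#' @export
gen_recoil_movie <- function(v_um_s, px_size = 0.2, frame_interval = 0.2,
                             n_frames = 30, cut_frame = 6, nx = 160,
                             ny = 96, noise_sd = 0, seed = 1) {
  if (v_um_s < 0) stop("v must be non-negative")
  .with_seed(seed, {
    nwave <- 80
    wl <- runif(nwave, 3, 20) * px_size            # wavelengths in um
    ang <- runif(nwave, 0, 2 * pi)
    ph <- runif(nwave, 0, 2 * pi)
    amp <- rnorm(nwave, 0, 1) / sqrt(nwave / 2)
    kx <- 2 * pi * cos(ang) / wl; ky <- 2 * pi * sin(ang) / wl
    tex <- function(x, y) {                        # x, y in um (vectors)
      out <- 0
      for (k in seq_len(nwave))
        out <- out + amp[k] * sin(kx[k] * x + ky[k] * y + ph[k])
      out
    }
    x_cut <- (nx / 4) * px_size
    edge_w <- 0.7 * px_size                          # smooth band edge
    xs <- (seq_len(nx) - 1) * px_size
    ys <- (seq_len(ny) - 1) * px_size
    X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
    frames <- vector("list", n_frames)
    for (j in seq_len(n_frames)) {
      t_post <- (j - cut_frame) * frame_interval
      offset <- if (t_post >= 0) v_um_s * t_post else 0
      band <- 1 / (1 + exp(-(X - (x_cut + offset)) / edge_w))
      img <- (1 + 0.35 * tex(X - offset, Y)) * band
      if (noise_sd > 0)
        img <- img + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
      frames[[j]] <- img
    }
    # kymograph averaged over a band of lines, as done at the bench: the
    # y-invariant edge survives, texture along y averages out
    ysel <- round(ny / 2) + (-15:15)
    kym <- vapply(frames, function(f) rowMeans(f[, ysel]), numeric(nx))
    # roi sits on the retracting band, clear of the ablation edge
    roi <- c(x_cut + 0.15 * (nx * px_size - x_cut),
             x_cut + 0.9 * (nx * px_size - x_cut),
             ys[round(ny * 0.1)], ys[round(ny * 0.9)])
    cut <- cut_geometry(rbind(c(x_cut, ys[1]), c(x_cut, ys[ny])), roi)
    list(frames = frames,
         kymo = kymograph(kym, px_size, frame_interval, cut_frame),
         cut = cut,
         truth = list(v_um_s = v_um_s, x_cut = x_cut,
                      cut_frame = cut_frame, px_size = px_size,
                      frame_interval = frame_interval))
  })
}

#' Generate an aspiration measurement for a known modulus
#'
#' Inverts Laplace's law: `h = d sqrt(delta_P / E_true)`, optionally with
#' relative Gaussian measurement noise on the tongue height.
#'
#' @param E_true True Young's modulus (Pa).
#' @param delta_P Suction pressure (Pa), default 750 (the bench operating
#'   point).
#' @param d Pipette inner diameter (µm), default 15.
#' @param noise_rel Relative s.d. of the tongue-height noise.
#' @param seed Integer seed.
#' @return List with `measurement` (an [aspiration_measurement()]) and
#'   `truth`.
#' @export
gen_aspiration <- function(E_true, delta_P = 750, d = 15, noise_rel = 0,
                           seed = 1) {
  if (E_true <= 0 || delta_P <= 0 || d <= 0) stop("inputs must be positive")
  .with_seed(seed, {
    h <- d * sqrt(delta_P / E_true)
    if (noise_rel > 0) h <- h * (1 + rnorm(1, 0, noise_rel))
    list(measurement = aspiration_measurement(delta_P, d, h),
         truth = list(E_true = E_true, h_noiseless = d * sqrt(delta_P / E_true)))
  })
}
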