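#' Detected-spot point cloud for one channel
#'
#' @param coords n x 3 matrix (or data frame) of spot positions in µm.
#' @param channel `"green"` or `"red"`.
#' @return An object of class `spot_set`.
#' @export
spot_set <- function(coords, channel = c("green", "red")) {
  channel <- match.arg(channel)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z in um)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  dimnames(coords) <- NULL
  structure(list(coords = coords, channel = channel), class = "spot_set")
}

.kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  list(R = R, t = as.numeric(cf - R %*% cm))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix of positions (µm).
#' @param tf A `rigid_transform` from [icp_register()].
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(coords, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Rigid registration of two spot clouds (iterative closest point)
#'
#' Corrects the shift and rotation between the spectral channels: each
#' iteration matches every moving point to its nearest fixed point,
#' solves the optimal rigid transform for those correspondences (SVD /
#' Kabsch), and repeats until the RMS nearest-neighbour distance improves
#' by less than `tol` or `max_iter` is reached.
#'
#' @param moving,fixed [spot_set()]s (or n x 3 matrices) with >= 4 points
#'   each.
#' @param max_iter Maximum ICP iterations.
#' @param tol RMS improvement threshold (µm) for convergence.
#' @return An object of class `rigid_transform` with `rotation` (3 x 3,
#'   det = +1), `translation` (µm) and `rms_residual` (µm).
#' @export
icp_register <- function(moving, fixed, max_iter = 50, tol = 1e-6) {
  M <- if (inherits(moving, "spot_set")) moving$coords else as.matrix(moving)
  F_ <- if (inherits(fixed, "spot_set")) fixed$coords else as.matrix(fixed)
  if (nrow(M) < 4 || nrow(F_) < 4) stop("each cloud needs >= 4 points")
  for (X in list(M, F_)) {
    e <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    if (e[2] < 1e-9 * max(e[1], 1))
      stop("rank deficiency: degenerate (collinear) point cloud")
  }
  R <- diag(3); tr <- c(0, 0, 0)
  cur <- M
  rms_prev <- Inf
  rms <- Inf
  for (it in seq_len(max_iter)) {
    nn <- .nearest_idx(cur, F_)
    rms <- sqrt(mean(rowSums((cur - F_[nn, , drop = FALSE])^2)))
    if (rms_prev - rms < tol) break
    rms_prev <- rms
    kb <- .kabsch(M, F_[nn, , drop = FALSE])
    R <- kb$R; tr <- kb$t
    cur <- sweep(M %*% t(R), 2, tr, `+`)
  }
  structure(list(rotation = R, translation = tr, rms_residual = rms,
                 iterations = it),
            class = "rigid_transform")
}

# nearest fixed index for each query row (brute force, chunked)
.nearest_idx <- function(query, ref) {
  n <- nrow(query)
  out <- integer(n)
  step <- max(1L, floor(2e6 / nrow(ref)))
  r2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(n, s + step - 1L)
    G <- query[idx, , drop = FALSE] %*% t(ref)
    D <- outer(rowSums(query[idx, , drop = FALSE]^2), r2, `+`) - 2 * G
    out[idx] <- max.col(-D, ties.method = "first")
  }
  out
}

#' Sort registered spots into lineage colour classes
#'
#' Mutual nearest-neighbour pairs across the two channels closer than the
#' typical cell radius are merged into yellow (double-labelled) cells at
#' the pair midpoint; unpaired spots become green or red cells. Each spot
#' is used at most once; distance ties are broken by lowest index.
#'
#' @param green,red Registered [spot_set()]s.
#' @param cell_radius Pairing distance threshold (µm).
#' @param sphere_diameter Diameter (µm) of the sphere representing each
#'   cell in the cluster analysis (default 12).
#' @return An object of class `cell_set` with `positions` (n x 3, µm),
#'   `color_class` (factor green/red/yellow) and `sphere_diameter`.
#' @export
classify_colors <- function(green, red, cell_radius = 6, sphere_diameter = 12) {
  G <- if (inherits(green, "spot_set")) green$coords else as.matrix(green)
  R <- if (inherits(red, "spot_set")) red$coords else as.matrix(red)
  ng <- nrow(G); nr <- nrow(R)
  pos <- NULL; cls <- character(0)
  if (ng > 0 && nr > 0) {
    D <- outer(rowSums(G^2), rowSums(R^2), `+`) - 2 * G %*% t(R)
    D <- sqrt(pmax(D, 0))
    ng_min <- apply(D, 1, which.min)          # red index nearest each green
    nr_min <- apply(D, 2, which.min)          # green index nearest each red
    used_g <- logical(ng); used_r <- logical(nr)
    for (i in seq_len(ng)) {
      j <- ng_min[i]
      if (!used_g[i] && !used_r[j] && nr_min[j] == i && D[i, j] < cell_radius) {
        pos <- rbind(pos, (G[i, ] + R[j, ]) / 2)
        cls <- c(cls, "yellow")
        used_g[i] <- TRUE; used_r[j] <- TRUE
      }
    }
    if (any(!used_g)) { pos <- rbind(pos, G[!used_g, , drop = FALSE])
                        cls <- c(cls, rep("green", sum(!used_g))) }
    if (any(!used_r)) { pos <- rbind(pos, R[!used_r, , drop = FALSE])
                        cls <- c(cls, rep("red", sum(!used_r))) }
  } else {
    pos <- rbind(G, R)
    cls <- c(rep("green", ng), rep("red", nr))
  }
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  cell_set(pos, cls, sphere_diameter)
}

#' Construct a cell set directly
#'
#' @param positions n x 3 matrix of cell positions (µm).
#' @param color_class Character/factor vector (green, red, yellow).
#' @param sphere_diameter Cell sphere diameter (µm), default 12.
#' @return An object of class `cell_set`.
#' @export
cell_set <- function(positions, color_class, sphere_diameter = 12) {
  positions <- as.matrix(positions)
  if (nrow(positions) && ncol(positions) != 3) stop("positions must be n x 3")
  if (sphere_diameter <= 0) stop("sphere_diameter must be positive")
  cls <- factor(as.character(color_class), levels = c("green", "red", "yellow"))
  if (length(cls) != nrow(positions)) stop("one colour per cell required")
  if (any(is.na(cls))) stop("colour classes must be green/red/yellow")
  dimnames(positions) <- NULL
  structure(list(positions = positions, color_class = cls,
                 sphere_diameter = sphere_diameter),
            class = "cell_set")
}

#' Analytic lymph-node and HEV region description
#'
#' The node interior is an ellipsoid (centre + semi-axes, µm); high
#' endothelial venules are capped cylinders (segment endpoints + radius,
#' µm). The edge margin implements the exclusion of cells within a set
#' distance of the node surface; the margin is realised by shrinking each
#' semi-axis by the margin (exact on-axis, mildly conservative at oblique
#' positions of an elongated ellipsoid).
#'
#' @param ln_center Ellipsoid centre (µm).
#' @param ln_semiaxes Ellipsoid semi-axes (µm).
#' @param hev List of HEV cylinders, each `list(p0 =, p1 =, radius =)` in
#'   µm; may be empty.
#' @param edge_margin Exclusion depth from the node surface (µm),
#'   default 100.
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(ln_center = c(0, 0, 0),
                         ln_semiaxes = c(600, 400, 400),
                         hev = list(), edge_margin = 100) {
  if (any(ln_semiaxes <= 0)) stop("semi-axes must be positive")
  if (edge_margin < 0) stop("edge_margin must be non-negative")
  if (any(ln_semiaxes - edge_margin <= 0))
    stop("edge_margin leaves no interior region")
  structure(list(ln_center = as.numeric(ln_center),
                 ln_semiaxes = as.numeric(ln_semiaxes),
                 hev = hev, edge_margin = edge_margin),
            class = "region_masks")
}

.inside_ellipsoid <- function(p, center, semiaxes) {
  q <- sweep(p, 2, center)
  rowSums(sweep(q, 2, semiaxes, `/`)^2) <= 1
}

# distance from points to a segment p0-p1
.dist_to_segment <- function(p, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  q <- sweep(p, 2, p0)
  tt <- if (L2 == 0) rep(0, nrow(p)) else pmin(1, pmax(0, (q %*% v) / L2))
  sqrt(rowSums((q - outer(as.numeric(tt), v))^2))
}

.in_hev <- function(p, masks) {
  if (!length(masks$hev) || nrow(p) == 0) return(rep(FALSE, nrow(p)))
  hit <- rep(FALSE, nrow(p))
  for (cyl in masks$hev)
    hit <- hit | (.dist_to_segment(p, cyl$p0, cyl$p1) <= cyl$radius)
  hit
}

#' Distance from points to the nearest HEV surface
#'
#' @param p n x 3 matrix of positions (µm).
#' @param masks A [region_masks()] with at least one HEV cylinder.
#' @return Distances (µm); 0 inside a vessel.
#' @export
hev_surface_distance <- function(p, masks) {
  if (!length(masks$hev)) stop("no HEV volumes defined")
  p <- as.matrix(p)
  d <- rep(Inf, nrow(p))
  for (cyl in masks$hev)
    d <- pmin(d, .dist_to_segment(p, cyl$p0, cyl$p1) - cyl$radius)
  pmax(d, 0)
}

# the region cells live in: eroded ellipsoid minus HEV volumes
.in_placement_region <- function(p, masks) {
  inner <- masks$ln_semiaxes - masks$edge_margin
  .inside_ellipsoid(p, masks$ln_center, inner) & !.in_hev(p, masks)
}

#' Exclude cells outside the node or too close to its surface
#'
#' Retains cells that lie inside the node, at least `edge_margin` µm from
#' its surface, and outside the HEV volumes — the same region in which the
#' random null is placed, so observed and simulated data face identical
#' exclusions.
#'
#' @param cells A [cell_set()].
#' @param masks A [region_masks()].
#' @return The filtered `cell_set`.
#' @export
apply_exclusions <- function(cells, masks) {
  stopifnot(inherits(cells, "cell_set"), inherits(masks, "region_masks"))
  keep <- .in_placement_region(cells$positions, masks)
  cell_set(cells$positions[keep, , drop = FALSE], cells$color_class[keep],
           cells$sphere_diameter)
}

# classic DBSCAN on one lineage; minPts counts the point itself
.dbscan <- function(pos, eps, minPts) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(pos))
  nb <- D <= eps
  core <- rowSums(nb) >= minPts
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- which(nb[i, ] & seq_len(n) != i)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (lab[q] == 0L) {
        lab[q] <- cl
        if (core[q]) queue <- c(queue, which(nb[q, ] & lab == 0L))
      }
    }
  }
  lab
}

#' Same-lineage cluster detection (sphere-contact DBSCAN)
#'
#' Cells are represented as spheres of `sphere_diameter` µm; two cells of
#' the same lineage are neighbours when the gap between their sphere
#' surfaces is at most `search_radius`, i.e. their centre distance is at
#' most `search_radius + sphere_diameter` (`radius_mode = "gap"`, the
#' default; `"surface_to_center"` uses `search_radius + sphere_diameter/2`
#' instead). A cluster is a density-connected set of at least `min_cells`
#' cells of one lineage (DBSCAN with minPts = `min_cells`, counting the
#' point itself). Green and red lineages are clustered independently;
#' yellow (double-labelled) cells never join clusters but count in the
#' total-cell denominator by default.
#'
#' @param cells A [cell_set()].
#' @param search_radius Surface-to-surface search radius (µm), default 20.
#' @param min_cells Minimum cells per cluster, default 3.
#' @param radius_mode `"gap"` or `"surface_to_center"`.
#' @param yellow_in_total Count yellow cells in the denominator of the
#'   clustered fraction?
#' @return An object of class `cluster_stats` with the cluster table,
#'   per-cell assignment, sizes and `clustered_fraction`; the Cluster
#'   Factor is added by [cluster_factor()].
#' @export
find_clusters <- function(cells, search_radius = 20, min_cells = 3,
                          radius_mode = c("gap", "surface_to_center"),
                          yellow_in_total = TRUE) {
  stopifnot(inherits(cells, "cell_set"))
  radius_mode <- match.arg(radius_mode)
  if (min_cells < 2) stop("invalid parameter: min_cells must be >= 2")
  eps <- search_radius + switch(radius_mode,
                                gap = cells$sphere_diameter,
                                surface_to_center = cells$sphere_diameter / 2)
  n <- nrow(cells$positions)
  assignment <- rep(NA_integer_, n)
  lineage_of <- character(0)
  cl_offset <- 0L
  for (lin in c("green", "red")) {
    idx <- which(cells$color_class == lin)
    if (!length(idx)) next
    lab <- .dbscan(cells$positions[idx, , drop = FALSE], eps, min_cells)
    ncl <- max(lab, 0L)
    assignment[idx[lab > 0L]] <- lab[lab > 0L] + cl_offset
    if (ncl > 0L) lineage_of <- c(lineage_of, rep(lin, ncl))
    cl_offset <- cl_offset + ncl
  }
  sizes <- if (cl_offset > 0L) tabulate(assignment, nbins = cl_offset) else integer(0)
  total <- if (yellow_in_total) n else sum(cells$color_class != "yellow")
  clustered <- sum(!is.na(assignment))
  structure(list(assignment = assignment, n_clusters = cl_offset,
                 sizes = sizes, lineage = lineage_of,
                 clustered_fraction = if (total > 0) clustered / total else 0,
                 n_cells = n, total_cells = total,
                 eps = eps, search_radius = search_radius,
                 min_cells = min_cells, radius_mode = radius_mode,
                 yellow_in_total = yellow_in_total),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("Cluster statistics: %d clusters among %d cells\n",
              x$n_clusters, x$n_cells))
  cat(sprintf("  clustered fraction = %.4g\n", x$clustered_fraction))
  if (!is.null(x$cf)) cat(sprintf("  cluster factor     = %.4g\n", x$cf))
  invisible(x)
}

#' Random-placement null for the cluster analysis
#'
#' Places the same number of cells per lineage uniformly at random into
#' the region occupied by the real cells (node interior eroded by the
#' edge margin, minus HEV volumes; rejection sampling), runs
#' [find_clusters()] with identical parameters on each replicate, and
#' averages the clustered fraction over replicates.
#'
#' @param n_per_lineage Named counts, e.g. `c(green = 150, red = 150)`;
#'   a `yellow` count may be included and enters only the denominator.
#' @param masks A [region_masks()].
#' @param n_reps Number of replicates, default 10.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param keep_cells Keep the simulated cell sets (needed for distance
#'   profiles)?
#' @param ... Cluster parameters passed to [find_clusters()].
#' @return An object of class `random_null` with per-replicate fractions,
#'   their mean, and (optionally) the simulated cells and their stats.
#' @export
simulate_random <- function(n_per_lineage, masks, n_reps = 10, seed,
                            keep_cells = FALSE, ...) {
  stopifnot(inherits(masks, "region_masks"))
  if (is.null(names(n_per_lineage)))
    names(n_per_lineage) <- c("green", "red")[seq_along(n_per_lineage)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fractions <- numeric(n_reps)
  sims <- if (keep_cells) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    pos <- .sample_region(sum(n_per_lineage), masks)
    cls <- rep(names(n_per_lineage), n_per_lineage)
    cs <- cell_set(pos, cls)
    st <- find_clusters(cs, ...)
    fractions[r] <- st$clustered_fraction
    if (keep_cells) sims[[r]] <- list(cells = cs, stats = st)
  }
  structure(list(fractions = fractions, mean_fraction = mean(fractions),
                 n_reps = n_reps, sims = sims),
            class = "random_null")
}

.sample_region <- function(n, masks, max_tries = 1000) {
  inner <- masks$ln_semiaxes - masks$edge_margin
  lo <- masks$ln_center - inner
  hi <- masks$ln_center + inner
  out <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("placement failure: region too small for requested cell count")
    m <- max(2L * (n - nrow(out)), 64L)
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                  runif(m, lo[3], hi[3]))
    keep <- .in_placement_region(cand, masks)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Cluster Factor
#'
#' The ratio of the observed clustered-cell fraction to the clustered
#' fraction of matched random placements. A CF of 100 means 100 times
#' more cells sit in clusters than expected by chance; CF = 1 is
#' chance-level clustering.
#'
#' @param observed_fraction Observed clustered fraction, or a
#'   `cluster_stats` object.
#' @param simulated_fraction Mean simulated clustered fraction, or a
#'   `random_null` object.
#' @return Dimensionless CF (with a warning and `Inf` when the simulated
#'   fraction is zero but the observed is not).
#' @export
cluster_factor <- function(observed_fraction, simulated_fraction) {
  if (inherits(observed_fraction, "cluster_stats"))
    observed_fraction <- observed_fraction$clustered_fraction
  if (inherits(simulated_fraction, "random_null"))
    simulated_fraction <- simulated_fraction$mean_fraction
  if (simulated_fraction == 0) {
    if (observed_fraction == 0) return(NaN)
    warning("undefined CF: simulated clustered fraction is zero")
    return(Inf)
  }
  observed_fraction / simulated_fraction
}

#' Cluster Factor as a function of distance from the nearest HEV
#'
#' Cells (observed and simulated) are binned by their distance to the
#' nearest HEV surface; within each bin the CF is the ratio of the
#' observed to the pooled simulated clustered fraction. Bins with no
#' cells, or no simulated clustered cells, yield `NA`.
#'
#' @param cells Observed [cell_set()].
#' @param stats Matching [find_clusters()] result.
#' @param null A [simulate_random()] result created with
#'   `keep_cells = TRUE`.
#' @param masks A [region_masks()] with HEV cylinders.
#' @param bin_width Bin width in µm, default 50.
#' @return Data frame with `bin_lo`, `bin_hi`, `cf`, and the per-bin
#'   observed/simulated fractions.
#' @export
cf_by_hev_distance <- function(cells, stats, null, masks, bin_width = 50) {
  stopifnot(inherits(cells, "cell_set"), inherits(stats, "cluster_stats"),
            inherits(null, "random_null"))
  if (is.null(null$sims))
    stop("null must be simulated with keep_cells = TRUE")
  d_obs <- hev_surface_distance(cells$positions, masks)
  obs_cl <- !is.na(stats$assignment)
  d_sim <- cl_sim <- NULL
  for (s in null$sims) {
    d_sim <- c(d_sim, hev_surface_distance(s$cells$positions, masks))
    cl_sim <- c(cl_sim, !is.na(s$stats$assignment))
  }
  dmax <- max(c(d_obs, d_sim))
  breaks <- seq(0, bin_width * ceiling(dmax / bin_width + 1e-9), by = bin_width)
  bo <- findInterval(d_obs, breaks, rightmost.closed = TRUE)
  bs <- findInterval(d_sim, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  res <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    obs_fraction = NA_real_, sim_fraction = NA_real_,
                    cf = NA_real_)
  for (b in seq_len(nb)) {
    no <- sum(bo == b); ns <- sum(bs == b)
    if (no > 0) res$obs_fraction[b] <- sum(obs_cl[bo == b]) / no
    if (ns > 0) res$sim_fraction[b] <- sum(cl_sim[bs == b]) / ns
    if (no > 0 && ns > 0 && res$sim_fraction[b] > 0)
      res$cf[b] <- res$obs_fraction[b] / res$sim_fraction[b]
  }
  res
}

#' Cluster-size frequency distribution
#'
#' Percentage of clusters per cluster-size bin, normalised to 100%.
#'
#' @param stats A [find_clusters()] result with at least one cluster.
#' @return Named numeric vector of percentages, names = cluster size.
#' @export
cluster_size_distribution <- function(stats) {
  stopifnot(inherits(stats, "cluster_stats"))
  if (stats$n_clusters == 0) return(setNames(numeric(0), character(0)))
  tab <- table(stats$sizes)
  setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}
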