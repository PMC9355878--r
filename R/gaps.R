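#' Binary stromal-network mask
#'
#' Wraps a 2D slice, 2D stack or 3D volume of logicals where `TRUE` marks
#' network (foreground) and `FALSE` gap space. `pixel_size` is the
#' isotropic in-plane pixel size in µm; for stacks/volumes an optional
#' `z_spacing` (µm) records the slice distance, and [fill_gaps_3d()]
#' resamples to isotropic voxels when it differs from `pixel_size`.
#'
#' @param voxels Logical (or 0/1 numeric) array of 2 or 3 dimensions.
#' @param pixel_size In-plane pixel size, µm per px.
#' @param z_spacing Optional z slice spacing, µm (3D only); defaults to
#'   `pixel_size`.
#' @return An object of class `network_mask`.
#' @export
network_mask <- function(voxels, pixel_size, z_spacing = pixel_size) {
  if (is.null(dim(voxels)) || !(length(dim(voxels)) %in% c(2, 3)))
    stop("voxels must be a 2D or 3D array")
  if (pixel_size <= 0 || z_spacing <= 0) stop("pixel sizes must be positive")
  v <- array(as.logical(voxels), dim = dim(voxels))
  if (any(is.na(v))) stop("mask contains NA")
  structure(list(voxels = v, pixel_size = pixel_size, z_spacing = z_spacing),
            class = "network_mask")
}

#' Remove small foreground specks from a mask
#'
#' Connected foreground components (full 8/26 connectivity) smaller than
#' `min_object_px` pixels are deleted; components of exactly
#' `min_object_px` pixels are retained.
#'
#' @param mask A [network_mask()].
#' @param min_object_px Minimum component size (pixels) to keep.
#' @return A cleaned `network_mask`.
#' @export
clean_mask <- function(mask, min_object_px) {
  stopifnot(inherits(mask, "network_mask"))
  lab <- .cpp_label(mask$voxels, dim(mask$voxels))
  if (max(lab) > 0) {
    sizes <- tabulate(lab)
    drop <- which(sizes < min_object_px)
    if (length(drop)) mask$voxels[lab %in% drop] <- FALSE
  }
  mask
}

.pore_fill <- function(res, mode, mask) {
  structure(list(centers = res$centers, diameter_px = res$diameter,
                 n_pixels = res$n_pixels, mode = mode,
                 pixel_size = mask$pixel_size,
                 total_gap_px = sum(!mask$voxels)),
            class = "pore_fill")
}

#' Pack maximal inscribed circles into 2D network gaps
#'
#' Greedy pore-size analysis: starting from the largest circle admitted by
#' the Euclidean distance transform of the network, circles are placed one
#' by one into the gaps; once no circle of the current diameter fits, the
#' diameter shrinks by one pixel, down to single-pixel circles, until the
#' whole gap area is filled. Placed circles claim their pixels and act as
#' obstacles for subsequent placements, so the fill is non-overlapping.
#' Among equally good centres the first in raster (column-major) order is
#' taken; circles must lie entirely inside the image.
#'
#' @param mask A 2D [network_mask()].
#' @return An object of class `pore_fill` with per-element centres (px),
#'   diameters (px) and pixel counts.
#' @export
fill_gaps_2d <- function(mask) {
  stopifnot(inherits(mask, "network_mask"))
  if (length(dim(mask$voxels)) != 2) stop("fill_gaps_2d needs a 2D mask")
  .pore_fill(.cpp_greedy_fill(mask$voxels, dim(mask$voxels)), "2D-circle", mask)
}

#' Pack maximal inscribed spheres into 3D network gaps
#'
#' The 3D analogue of [fill_gaps_2d()]: spheres are packed greedily into
#' the gap space using a 3D Euclidean distance transform. If the z spacing
#' differs from the in-plane pixel size the volume is first resampled
#' (nearest-neighbour) to isotropic voxels.
#'
#' @param mask A 3D [network_mask()].
#' @return An object of class `pore_fill`.
#' @export
fill_gaps_3d <- function(mask) {
  stopifnot(inherits(mask, "network_mask"))
  v <- mask$voxels
  if (length(dim(v)) != 3) stop("fill_gaps_3d needs a 3D mask")
  if (abs(mask$z_spacing - mask$pixel_size) > 1e-9) {
    nz <- max(1L, round(dim(v)[3] * mask$z_spacing / mask$pixel_size))
    zi <- pmin(dim(v)[3], pmax(1L, round((seq_len(nz) - 0.5) *
                                           dim(v)[3] / nz + 0.5)))
    v <- v[, , zi, drop = FALSE]
    mask <- network_mask(v, mask$pixel_size)
  }
  .pore_fill(.cpp_greedy_fill(v, dim(v)), "3D-sphere", mask)
}

#' Pore-size distribution of a gap fill
#'
#' Per unit-diameter bin, the area (or volume) fraction is the share of
#' the total gap space covered by elements of that diameter. The weighted
#' fraction multiplies each area fraction by its diameter in µm; the mean
#' fitted diameter is by default the weighted-fraction-weighted mean (the
#' quantity plotted against inflammation time), with the plain
#' area-fraction-weighted mean also reported.
#'
#' @param fill A [fill_gaps_2d()]/[fill_gaps_3d()] result.
#' @param mask The `network_mask` the fill was produced from (optional;
#'   total gap space is carried on the fill).
#' @return An object of class `pore_size_distribution` with
#'   `diameter_um`, `area_fraction`, `weighted_fraction`,
#'   `mean_fitted_diameter` (weighted) and `mean_diameter_area` (plain).
#' @export
pore_size_distribution <- function(fill, mask = NULL) {
  stopifnot(inherits(fill, "pore_fill"))
  total <- if (!is.null(mask)) sum(!mask$voxels) else fill$total_gap_px
  if (length(fill$diameter_px) == 0 || total == 0)
    stop("empty fill: pore-size distribution undefined")
  dpx <- sort(unique(fill$diameter_px))
  af <- vapply(dpx, function(d) sum(fill$n_pixels[fill$diameter_px == d]) / total,
               numeric(1))
  dum <- dpx * fill$pixel_size
  wf <- af * dum
  structure(list(diameter_um = dum, area_fraction = af, weighted_fraction = wf,
                 mean_fitted_diameter = sum(dum * wf) / sum(wf),
                 mean_diameter_area = sum(dum * af) / sum(af),
                 pixel_size = fill$pixel_size),
            class = "pore_size_distribution")
}

#' Average pore-size distributions over a z stack
#'
#' Distributions from consecutive optical sections are aligned on the
#' union of their diameter grids (missing bins count as zero) and averaged
#' bin-wise; summary diameters are recomputed from the averaged
#' distribution.
#'
#' @param per_slice List of [pore_size_distribution()] objects.
#' @return A single averaged `pore_size_distribution`.
#' @export
average_over_stack <- function(per_slice) {
  if (!length(per_slice)) stop("invalid input: empty slice list")
  stopifnot(all(vapply(per_slice, inherits, logical(1), "pore_size_distribution")))
  grid <- sort(unique(unlist(lapply(per_slice, `[[`, "diameter_um"))))
  acc_a <- acc_w <- numeric(length(grid))
  for (d in per_slice) {
    idx <- match(d$diameter_um, grid)
    a <- numeric(length(grid)); a[idx] <- d$area_fraction
    w <- numeric(length(grid)); w[idx] <- d$weighted_fraction
    acc_a <- acc_a + a
    acc_w <- acc_w + w
  }
  af <- acc_a / length(per_slice)
  wf <- acc_w / length(per_slice)
  structure(list(diameter_um = grid, area_fraction = af,
                 weighted_fraction = wf,
                 mean_fitted_diameter = sum(grid * wf) / sum(wf),
                 mean_diameter_area = sum(grid * af) / sum(af),
                 pixel_size = per_slice[[1]]$pixel_size),
            class = "pore_size_distribution")
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  cat(sprintf("Pore-size distribution: %d diameter bins (%.3g-%.3g um)\n",
              length(x$diameter_um), min(x$diameter_um), max(x$diameter_um)))
  cat(sprintf("  mean fitted diameter (weighted) = %.3g um\n",
              x$mean_fitted_diameter))
  cat(sprintf("  mean fitted diameter (area)     = %.3g um\n",
              x$mean_diameter_area))
  invisible(x)
}

#' Squared Euclidean distance transform
#'
#' Exact squared distance from every pixel to the nearest `TRUE` pixel of
#' `blocked` (any rank), computed with the separable lower-envelope
#' algorithm. With `border_blocked = TRUE` the image border behaves as an
#' obstacle one pixel beyond the edge, so inscribed elements cannot
#' protrude out of the field of view.
#'
#' @param blocked Logical array (2D or 3D).
#' @param border_blocked Should the border act as an obstacle?
#' @return Numeric array of squared distances (px²).
#' @export
sq_distance_transform <- function(blocked, border_blocked = FALSE) {
  if (is.null(dim(blocked))) stop("blocked must be an array")
  .cpp_sedt(array(as.logical(blocked), dim(blocked)), dim(blocked),
            border_blocked)
}
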