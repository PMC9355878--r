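test_that("clean_mask removes specks below and keeps components at the threshold", {
  m <- matrix(FALSE, 12, 12)
  m[3, 3] <- TRUE                       # 1-px speck
  m[6:10, 6] <- TRUE                    # 5-px line
  nm <- clean_mask(network_mask(m, 1), 5)
  expect_false(nm$voxels[3, 3])
  expect_true(all(nm$voxels[6:10, 6]))

  set.seed(8)
  sp <- matrix(runif(40 * 40) < 0.15, 40, 40)
  cleaned <- clean_mask(network_mask(sp, 1), 4)
  # oracle: label with the package labeller, count sizes independently
  lab <- lnmech:::.cpp_label(sp, dim(sp))
  sizes <- tabulate(lab)
  expect_equal(sum(cleaned$voxels), sum(sizes[sizes >= 4]))
})

test_that("2D packing handles degenerate masks and recovers a circular gap", {
  allnet <- network_mask(matrix(TRUE, 8, 8), 1)
  expect_length(fill_gaps_2d(allnet)$diameter_px, 0)

  n <- 41; r <- 12
  m <- matrix(TRUE, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - 21)^2 + (j - 21)^2 < r^2) m[i, j] <- FALSE
  f <- fill_gaps_2d(network_mask(m, 1))
  expect_equal(as.numeric(f$centers[1, ]), c(21, 21))
  expect_lte(abs(f$diameter_px[1] - 2 * r), 1)
  # complete fill
  expect_equal(sum(f$n_pixels), sum(!m))
})

test_that("greedy packer matches the exhaustive brute-force packer (2D)", {
  set.seed(101)
  for (k in 1:6) {
    m <- matrix(runif(24 * 24) < 0.25, 24, 24)
    fast <- fill_gaps_2d(network_mask(m, 1))
    slow <- brute_pack(m)
    expect_equal(fast$diameter_px, slow$diameter)
    expect_equal(unname(as.matrix(fast$centers)), unname(slow$centers))
    expect_equal(sum(fast$n_pixels), sum(slow$n_pixels))
  }
})

test_that("3D packing finds the inscribed sphere of a cubic cavity and matches brute force", {
  a <- 7
  v <- array(TRUE, c(12, 12, 12))
  v[3:(2 + a), 3:(2 + a), 3:(2 + a)] <- FALSE
  f <- fill_gaps_3d(network_mask(v, 1))
  expect_lte(abs(f$diameter_px[1] - a), 1)

  set.seed(33)
  for (k in 1:3) {
    v <- array(runif(10^3) < 0.3, c(10, 10, 10))
    fast <- fill_gaps_3d(network_mask(v, 1))
    slow <- brute_pack(v)
    expect_equal(fast$diameter_px, slow$diameter)
    expect_equal(sum(fast$n_pixels), sum(slow$n_pixels))
  }
})

test_that("a z-constant volume admits spheres at least as large as its slices' circles", {
  g <- gen_network_mask("2d", size = 40, lattice_pitch = 13, strand_width = 3)
  slice <- g$mask$voxels
  vol <- array(rep(slice, 20), dim = c(dim(slice), 20))
  f2 <- fill_gaps_2d(network_mask(slice, 1))
  f3 <- fill_gaps_3d(network_mask(vol, 1))
  expect_gte(max(f3$diameter_px), max(f2$diameter_px))
})

test_that("packing is invariant under mask translation", {
  g <- gen_network_mask("2d", size = 30, lattice_pitch = 11, strand_width = 3,
                        jitter = 2, seed = 5)
  m <- g$mask$voxels
  shifted <- matrix(TRUE, 34, 34)
  shifted[3:32, 4:33] <- m
  # interior gaps only: surround the original with network so borders match
  base <- matrix(TRUE, 34, 34)
  base[1:30 + 1, 1:30 + 1] <- m
  f0 <- fill_gaps_2d(network_mask(base, 1))
  m2 <- matrix(TRUE, 36, 36)
  m2[1:30 + 3, 1:30 + 2] <- m
  f1 <- fill_gaps_2d(network_mask(m2, 1))
  expect_equal(f1$diameter_px, f0$diameter_px)
  expect_equal(unname(f1$centers[, 1] - f0$centers[, 1]),
               rep(2, nrow(f1$centers)))
  expect_equal(unname(f1$centers[, 2] - f0$centers[, 2]),
               rep(1, nrow(f1$centers)))
})

test_that("coverage accumulates monotonically within the gap space", {
  g <- gen_network_mask("2d", size = 48, lattice_pitch = 16, strand_width = 5,
                        jitter = 3, seed = 9)
  f <- fill_gaps_2d(g$mask)
  expect_true(all(diff(f$diameter_px) <= 0))
  expect_lte(sum(f$n_pixels), sum(!g$mask$voxels))
})

test_that("pore-size distribution reproduces the stated weighting", {
  # two diameters covering half the gap area each
  fill <- structure(list(centers = matrix(0, 2, 2), diameter_px = c(4, 2),
                         n_pixels = c(10, 10), mode = "2D-circle",
                         pixel_size = 1, total_gap_px = 20),
                    class = "pore_fill")
  d <- pore_size_distribution(fill)
  expect_equal(d$area_fraction, c(0.5, 0.5))
  expect_equal(d$weighted_fraction, c(1, 2))
  expect_equal(d$mean_fitted_diameter, (4 * 2 + 2 * 1) / 3, tolerance = 1e-12)

  fill1 <- structure(list(centers = matrix(0, 1, 2), diameter_px = 6,
                          n_pixels = 20, mode = "2D-circle",
                          pixel_size = 1, total_gap_px = 20),
                     class = "pore_fill")
  expect_equal(pore_size_distribution(fill1)$mean_fitted_diameter, 6)

  fill2 <- fill; fill2$pixel_size <- 2
  expect_equal(pore_size_distribution(fill2)$mean_fitted_diameter,
               2 * d$mean_fitted_diameter)
})

test_that("lattice masks recover the constructed gap size as the modal diameter", {
  g <- gen_network_mask("2d", size = 84, lattice_pitch = 21, strand_width = 5)
  f <- fill_gaps_2d(g$mask)
  d <- pore_size_distribution(f, g$mask)
  modal <- d$diameter_um[which.max(d$weighted_fraction)] / g$mask$pixel_size
  expect_lte(abs(modal - g$truth$gap_diameter_px), 1)
})

test_that("stack averaging is an idempotent per-bin mean", {
  g <- gen_network_mask("2d", size = 40, lattice_pitch = 13, strand_width = 4)
  d1 <- pore_size_distribution(fill_gaps_2d(g$mask), g$mask)
  avg <- average_over_stack(list(d1, d1, d1))
  expect_equal(avg$area_fraction, d1$area_fraction)
  expect_equal(avg$mean_fitted_diameter, d1$mean_fitted_diameter)

  mk <- function(d_um) structure(list(diameter_um = d_um, area_fraction = 1,
                                      weighted_fraction = d_um,
                                      mean_fitted_diameter = d_um,
                                      mean_diameter_area = d_um,
                                      pixel_size = 1),
                                 class = "pore_size_distribution")
  two <- average_over_stack(list(mk(2), mk(4)))
  expect_equal(two$diameter_um, c(2, 4))
  expect_equal(two$area_fraction, c(0.5, 0.5))

  # brute-force mean over a 12-slice stack with varying gap sizes
  slices <- lapply(1:12, function(z) {
    gz <- gen_network_mask("2d", size = 36, lattice_pitch = 12,
                           strand_width = 3, jitter = 2, seed = z)
    pore_size_distribution(fill_gaps_2d(gz$mask), gz$mask)
  })
  avg <- average_over_stack(slices)
  grid <- avg$diameter_um
  manual <- rowMeans(vapply(slices, function(s) {
    out <- numeric(length(grid))
    out[match(s$diameter_um, grid)] <- s$area_fraction
    out
  }, numeric(length(grid))))
  expect_equal(avg$area_fraction, manual)
  expect_error(average_over_stack(list()), "empty")
})

test_that("the distance transform agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  m <- matrix(runif(30 * 22) < 0.2, 30, 22)
  mine <- sqrt(sq_distance_transform(m))
  # EBImage::distmap computes distance from foreground to background
  ref <- EBImage::distmap(EBImage::Image(1 - m), metric = "euclidean")
  expect_equal(as.numeric(mine), as.numeric(ref@.Data), tolerance = 1e-6)
})

test_that("anisotropic stacks are resampled to isotropic voxels before packing", {
  v <- array(FALSE, c(20, 20, 5))
  v[10, , ] <- TRUE
  mask <- network_mask(v, pixel_size = 1, z_spacing = 4)
  f <- fill_gaps_3d(mask)
  # resampled to ~20 z-slices; the largest sphere must exceed the 5-voxel
  # native depth, which would cap diameters at 5 without resampling
  expect_gt(max(f$diameter_px), 5)
})
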