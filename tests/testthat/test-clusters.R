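test_that("ICP recovers identity, pure shifts and small rotations", {
  set.seed(4)
  cloud <- matrix(runif(240, 0, 120), 80, 3)
  tf0 <- icp_register(cloud, cloud)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)

  shifted <- sweep(cloud, 2, c(3, -2, 1), `+`)
  tf1 <- icp_register(shifted, cloud)
  expect_equal(tf1$translation, c(-3, 2, -1), tolerance = 1e-6)

  moved <- sweep(cloud %*% t(rot_z(5)), 2, c(3, -2, 1), `+`)
  tf2 <- icp_register(moved, cloud)
  expect_lt(max(abs(apply_rigid(moved, tf2) - cloud)), 1e-6)
  expect_equal(det(tf2$rotation), 1, tolerance = 1e-9)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_register(line, cloud), "rank deficiency")
})

test_that("registration is idempotent: re-registering the corrected cloud gives identity", {
  set.seed(5)
  cloud <- matrix(runif(150, 0, 80), 50, 3)
  moved <- sweep(cloud %*% t(rot_z(4)), 2, c(-2, 5, 0.5), `+`)
  tf <- icp_register(moved, cloud)
  corrected <- apply_rigid(moved, tf)
  tf2 <- icp_register(corrected, cloud)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-6)
  expect_lt(sqrt(sum(tf2$translation^2)), 1e-6)
})

test_that("colour classification merges mutual pairs and conserves spots", {
  g <- spot_set(rbind(c(0, 0, 0)), "green")
  r <- spot_set(rbind(c(0, 0, 2)), "red")
  cs <- classify_colors(g, r, cell_radius = 6)
  expect_equal(as.character(cs$color_class), "yellow")
  expect_equal(cs$positions[1, ], c(0, 0, 1))

  r_far <- spot_set(rbind(c(0, 0, 20)), "red")
  cs2 <- classify_colors(g, r_far, cell_radius = 6)
  expect_setequal(as.character(cs2$color_class), c("green", "red"))

  cs3 <- classify_colors(g, spot_set(matrix(numeric(0), 0, 3), "red"))
  expect_equal(as.character(cs3$color_class), "green")

  set.seed(6)
  G <- matrix(runif(90, 0, 200), 30, 3)
  R <- rbind(G[1:10, ] + matrix(rnorm(30, 0, 1), 10, 3),
             matrix(runif(60, 300, 500), 20, 3))
  cs4 <- classify_colors(spot_set(G, "green"), spot_set(R, "red"),
                         cell_radius = 6)
  tab <- table(cs4$color_class)
  expect_equal(unname(tab[["green"]] + tab[["red"]] + 2 * tab[["yellow"]]),
               nrow(G) + nrow(R))
  expect_equal(unname(tab[["yellow"]]), 10)
})

test_that("edge and HEV exclusions implement the 100-um rule", {
  masks <- region_masks(ln_semiaxes = c(600, 400, 400), edge_margin = 100)
  pos <- rbind(c(700, 0, 0),     # outside the node
               c(550, 0, 0),     # 50 um deep: excluded
               c(450, 0, 0),     # 150 um deep: kept
               c(0, 0, 0))
  cells <- cell_set(pos, rep("green", 4))
  kept <- apply_exclusions(cells, masks)
  expect_equal(nrow(kept$positions), 2)
  expect_true(all(kept$positions[, 1] %in% c(450, 0)))

  masks0 <- region_masks(ln_semiaxes = c(600, 400, 400), edge_margin = 0)
  kept0 <- apply_exclusions(cells, masks0)
  expect_equal(nrow(kept0$positions), 3)

  hev <- region_masks(hev = list(list(p0 = c(0, 0, -200), p1 = c(0, 0, 200),
                                      radius = 20)))
  inhev <- cell_set(rbind(c(5, 0, 0), c(100, 0, 0)), c("red", "red"))
  expect_equal(nrow(apply_exclusions(inhev, hev)$positions), 1)
})

test_that("three same-lineage cells within reach form one cluster; two do not", {
  # pairwise centre distance 30 um = sphere gap 18 um <= 20 um search radius
  tri <- rbind(c(0, 0, 0), c(30, 0, 0), c(15, 15 * sqrt(3), 0))
  st <- find_clusters(cell_set(tri, rep("green", 3)))
  expect_equal(st$n_clusters, 1)
  expect_equal(st$sizes, 3)
  expect_equal(st$clustered_fraction, 1)

  st2 <- find_clusters(cell_set(tri[1:2, ], rep("green", 2)))
  expect_equal(st2$n_clusters, 0)
  expect_error(find_clusters(cell_set(tri, rep("green", 3)), min_cells = 1),
               "invalid parameter")

  # mixed lineages never join across colours; yellow stays out of clusters
  mixed <- cell_set(tri, c("green", "red", "yellow"))
  stm <- find_clusters(mixed)
  expect_equal(stm$n_clusters, 0)
  # but yellow counts in the denominator
  quad <- cell_set(rbind(tri, c(15, 5, 0)), c(rep("green", 3), "yellow"))
  stq <- find_clusters(quad)
  expect_equal(stq$clustered_fraction, 3 / 4)
  stq2 <- find_clusters(quad, yellow_in_total = FALSE)
  expect_equal(stq2$clustered_fraction, 1)
})

test_that("the sphere-gap neighbourhood radius follows the chosen semantics", {
  pair_at <- function(d, ...) {
    pos <- rbind(c(0, 0, 0), c(d, 0, 0), c(0, 5, 0))
    find_clusters(cell_set(pos, rep("green", 3)), ...)$n_clusters
  }
  expect_equal(pair_at(31.9), 1)   # gap semantics: eps = 20 + 12 = 32
  expect_equal(pair_at(32.1), 0)
  expect_equal(pair_at(25.9, radius_mode = "surface_to_center"), 1) # eps 26
  expect_equal(pair_at(26.1, radius_mode = "surface_to_center"), 0)
})

test_that("DBSCAN agrees with the brute-force density-reachability oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(100:300, 1)
    # mixture of clumps and background to exercise border cases
    centers <- matrix(runif(30, 0, 400), 10, 3)
    pos <- rbind(centers[sample(10, n %/% 2, replace = TRUE), ] +
                   matrix(rnorm(3 * (n %/% 2), 0, 15), ncol = 3),
                 matrix(runif(3 * (n - n %/% 2), 0, 400), ncol = 3))
    lab_pkg <- lnmech:::.dbscan(pos, eps = 32, minPts = 3)
    lab_ora <- brute_dbscan(pos, eps = 32, minPts = 3)
    expect_true(same_clustering(lab_pkg, lab_ora))
  }
})

test_that("the cluster factor is the observed-to-simulated fraction ratio", {
  expect_equal(cluster_factor(1.0, 0.01), 100)
  expect_equal(cluster_factor(0.3, 0.3), 1)
  expect_equal(cluster_factor(0, 0.05), 0)
  expect_warning(cf <- cluster_factor(0.5, 0), "undefined CF")
  expect_identical(cf, Inf)
})

test_that("the random null is seed-reproducible and rejects impossible regions", {
  masks <- region_masks()
  a <- simulate_random(c(green = 50, red = 50), masks, n_reps = 3, seed = 9)
  b <- simulate_random(c(green = 50, red = 50), masks, n_reps = 3, seed = 9)
  expect_identical(a$fractions, b$fractions)

  # an HEV blocking the entire placement region
  blocked <- region_masks(ln_semiaxes = c(120, 110, 110), edge_margin = 0,
                          hev = list(list(p0 = c(-200, 0, 0),
                                          p1 = c(200, 0, 0), radius = 500)))
  expect_error(simulate_random(c(green = 3), blocked, n_reps = 1, seed = 1),
               "placement failure")
})

test_that("three cells in a large region almost never cluster by chance", {
  masks <- region_masks(ln_semiaxes = c(600, 500, 500), edge_margin = 0)
  s <- simulate_random(c(green = 3), masks, n_reps = 400, seed = 13)
  expect_lte(s$mean_fraction, 0.01)
})

test_that("cluster-size histograms are percentages of clusters", {
  st <- structure(list(sizes = c(3, 3, 4), n_clusters = 3),
                  class = "cluster_stats")
  h <- cluster_size_distribution(st)
  expect_equal(unname(h[["3"]]), 200 / 3, tolerance = 1e-10)
  expect_equal(unname(h[["4"]]), 100 / 3, tolerance = 1e-10)
  st1 <- structure(list(sizes = 5, n_clusters = 1), class = "cluster_stats")
  expect_equal(unname(cluster_size_distribution(st1)), 100)
})

test_that("clustered data from the clone generator recovers memberships and CF >> 1", {
  masks <- region_masks()
  g <- gen_madm_cells(masks, n_parents = 15, offspring_per_parent = 10,
                      dispersion_sd_um = 8, n_singletons = 150, seed = 42)
  cells <- classify_colors(g$green, g$red)
  st <- find_clusters(cells)
  # clone recovery against ground truth via pairwise Rand index; compare
  # on the generated order (no channel transform, so positions identify cells)
  key <- paste(round(g$truth$positions[, 1], 6),
               round(g$truth$positions[, 2], 6))
  got <- paste(round(cells$positions[, 1], 6), round(cells$positions[, 2], 6))
  m <- match(key, got)
  assigned <- st$assignment[m]
  assigned[is.na(assigned)] <- 0
  ri <- rand_index(g$truth$clone, assigned)
  expect_gte(ri, 0.9)

  null <- simulate_random(table(cells$color_class)[c("green", "red")],
                          masks, n_reps = 10, seed = 77)
  expect_gt(cluster_factor(st, null), 10)
})

test_that("CSR data yields a chance-level cluster factor", {
  masks <- region_masks()
  obs <- simulate_random(c(green = 300, red = 300), masks, n_reps = 1,
                         seed = 55, keep_cells = TRUE)
  null <- simulate_random(c(green = 300, red = 300), masks, n_reps = 10,
                          seed = 56)
  cf <- cluster_factor(obs$mean_fraction, null$mean_fraction)
  expect_gt(cf, 0.2)
  expect_lt(cf, 5)
})

test_that("the CF-by-HEV-distance profile is flat for CSR data and defined per bin", {
  hev <- list(list(p0 = c(-300, 0, 0), p1 = c(300, 0, 0), radius = 20),
              list(p0 = c(0, -250, 100), p1 = c(0, 250, 100), radius = 20))
  masks <- region_masks(hev = hev)
  obs <- simulate_random(c(green = 400, red = 400), masks, n_reps = 1,
                         seed = 70, keep_cells = TRUE)
  cells <- obs$sims[[1]]$cells
  st <- obs$sims[[1]]$stats
  null <- simulate_random(c(green = 400, red = 400), masks, n_reps = 10,
                          seed = 71, keep_cells = TRUE)
  prof <- cf_by_hev_distance(cells, st, null, masks, bin_width = 100)
  expect_true(all(prof$bin_hi > prof$bin_lo))
  ok <- !is.na(prof$cf)
  expect_gt(sum(ok), 0)
  expect_true(all(prof$cf[ok] >= 0))
  # distances are well-defined wherever HEVs exist
  d <- hev_surface_distance(cells$positions, masks)
  expect_true(all(is.finite(d)))
})
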