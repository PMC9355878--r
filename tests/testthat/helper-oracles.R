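# Independent brute-force oracles. These deliberately avoid the package's
# distance-transform / clustering code paths: fits are checked pixel by
# pixel, density reachability is computed by transitive closure on the
# full distance matrix.

# Exhaustive greedy packer: same placement convention as the fast packer
# (descending integer diameters, first fitting centre in column-major
# raster order, elements claim pixels with 4*||p-c||^2 < d^2), but every
# fit is tested by direct enumeration of the pixels inside the element.
brute_pack <- function(network) {
  dims <- dim(network)
  nd <- length(dims)
  free <- !network
  coords <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  res_c <- NULL; res_d <- integer(0); res_n <- integer(0)

  disk_offsets <- function(d) {
    r <- (d - 1) %/% 2 + 1
    box <- as.matrix(do.call(expand.grid, rep(list(-r:r), nd)))
    box[4 * rowSums(box^2) < d * d, , drop = FALSE]
  }

  # independent upper bound on the first diameter: an element of diameter
  # d contains a free run of >= d - 1 pixels along every axis
  max_run <- 0
  for (axis in seq_len(nd)) {
    runs <- apply(free, setdiff(seq_len(nd), axis), function(line) {
      r <- rle(line)
      m <- r$lengths[r$values]
      if (length(m)) max(m) else 0
    })
    max_run <- max(max_run, runs)
  }

  for (d in seq(min(max_run + 1, max(dims)), 1, by = -1)) {
    off <- disk_offsets(d)
    repeat {
      placed <- FALSE
      for (i in seq_len(nrow(coords))) {
        ctr <- coords[i, ]
        if (!free[matrix(ctr, 1)]) next
        px <- off + matrix(ctr, nrow(off), nd, byrow = TRUE)
        if (any(px < 1) || any(sweep(px, 2, dims, `>`))) next
        if (all(free[px])) {
          free[px] <- FALSE
          res_c <- rbind(res_c, ctr)
          res_d <- c(res_d, d)
          res_n <- c(res_n, nrow(px))
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
  }
  list(centers = res_c, diameter = res_d, n_pixels = res_n)
}

# Brute-force DBSCAN by transitive closure of density reachability.
brute_dbscan <- function(pos, eps, minPts) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  D <- as.matrix(dist(pos))
  nb <- D <= eps
  core <- rowSums(nb) >= minPts
  lab <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & lab == 0L &
                      apply(nb[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    lab[comp] <- cl
  }
  # border points attach to the cluster of a core neighbour
  for (i in which(!core)) {
    cn <- which(core & nb[i, ])
    if (length(cn)) lab[i] <- lab[cn[1]]
  }
  lab
}

# agreement of two clusterings as partitions of the clustered points
same_clustering <- function(lab1, lab2) {
  if (length(lab1) != length(lab2)) return(FALSE)
  if (!all((lab1 > 0) == (lab2 > 0))) return(FALSE)
  idx <- which(lab1 > 0)
  key1 <- lab1[idx]; key2 <- lab2[idx]
  all(outer(key1, key1, "==") == outer(key2, key2, "=="))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

rand_index <- function(a, b) {
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  ut <- upper.tri(sa)
  mean(sa[ut] == sb[ut])
}

# Deterministic cell configurations with known clustered fractions:
# `all_clustered_cells` puts every cell in a tight same-lineage triplet;
# `sparse_null_cells` isolates all but one triplet on a wide lattice.
all_clustered_cells <- function(n_cells = 300) {
  n_tri <- n_cells / 3
  grid <- as.matrix(expand.grid(x = seq_len(ceiling(n_tri^(1 / 2))),
                                y = seq_len(ceiling(n_tri^(1 / 2)))))[seq_len(n_tri), ]
  centers <- cbind(grid * 200, 0)
  pos <- do.call(rbind, lapply(seq_len(n_tri), function(i)
    rbind(centers[i, ], centers[i, ] + c(5, 0, 0), centers[i, ] + c(0, 5, 0))))
  cell_set(pos, rep("green", n_cells))
}

sparse_null_cells <- function(n_cells = 300, n_clustered = 3) {
  n_single <- n_cells - n_clustered
  side <- ceiling(n_single^(1 / 3))
  lat <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
  singles <- lat[seq_len(n_single), ] * 40          # 40 um >> 32 um reach
  triplet <- rbind(c(0, 0, 5000), c(5, 0, 5000), c(0, 5, 5000))
  cell_set(rbind(singles, triplet), rep("green", n_cells))
}
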