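# Readers and writers for the bench file formats: force traces and spot
# tables as CSV, geometry as JSON, masks as (multi-page) TIFF, fibril
# traces as SWC-like whitespace text.

#' Read a force trace from CSV
#'
#' Expects a two-column CSV with header `t_s, F_uN`.
#'
#' @param path CSV file.
#' @param strain_onset_t Passed to [force_trace()].
#' @return A [force_trace()].
#' @export
read_force_trace <- function(path, strain_onset_t = 0) {
  df <- read.csv(path)
  if (!all(c("t_s", "F_uN") %in% names(df)))
    stop("expected columns t_s and F_uN")
  force_trace(df$t_s, df$F_uN, strain_onset_t)
}

#' Write a force trace to CSV
#'
#' @param trace A [force_trace()].
#' @param path Output CSV file.
#' @export
write_force_trace <- function(trace, path) {
  write.csv(data.frame(t_s = trace$t, F_uN = trace$F), path,
            row.names = FALSE)
  invisible(path)
}

#' Read plate geometry from JSON
#'
#' Expects keys `h0_mm, h_eq_mm, L_mm, R1_mm, R2_mm, R3_mm`.
#'
#' @param path JSON file.
#' @return A [plate_geometry()].
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plate_geometry(j$h0_mm, j$h_eq_mm, j$L_mm, j$R1_mm, j$R2_mm, j$R3_mm)
}

#' Write plate geometry to JSON
#'
#' @param geom A [plate_geometry()].
#' @param path Output JSON file.
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(list(h0_mm = geom$h0, h_eq_mm = geom$h_eq,
                            L_mm = geom$L, R1_mm = geom$R1,
                            R2_mm = geom$R2, R3_mm = geom$R3),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary network mask from TIFF
#'
#' Pages of a multi-page TIFF become z slices. Pixels above `threshold`
#' (on the 0-1 scale used by the TIFF reader) count as network.
#'
#' @param path TIFF file.
#' @param pixel_size µm per px.
#' @param z_spacing µm between slices (stacks only).
#' @param threshold Foreground threshold on normalised intensity.
#' @return A [network_mask()].
#' @export
read_mask_tiff <- function(path, pixel_size, z_spacing = pixel_size,
                           threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  take2d <- function(p) if (length(dim(p)) == 3) p[, , 1] else p
  slices <- lapply(pages, function(p) take2d(p) > threshold)
  vox <- if (length(slices) == 1) slices[[1]] else
    array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  network_mask(vox, pixel_size, z_spacing)
}

#' Write a binary mask to (multi-page) TIFF
#'
#' @param mask A [network_mask()] or logical array.
#' @param path Output TIFF file.
#' @export
write_mask_tiff <- function(mask, path) {
  v <- if (inherits(mask, "network_mask")) mask$voxels else mask
  if (length(dim(v)) == 2) {
    tiff::writeTIFF(v * 1, path)
  } else {
    tiff::writeTIFF(lapply(seq_len(dim(v)[3]), function(z) v[, , z] * 1), path)
  }
  invisible(path)
}

#' Read spot coordinates from CSV
#'
#' Expects columns `x_um, y_um, z_um`.
#'
#' @param path CSV file.
#' @param channel Channel label (`"green"` or `"red"`).
#' @return A [spot_set()].
#' @export
read_spots <- function(path, channel) {
  df <- read.csv(path)
  if (!all(c("x_um", "y_um", "z_um") %in% names(df)))
    stop("expected columns x_um, y_um, z_um")
  spot_set(cbind(df$x_um, df$y_um, df$z_um), channel)
}

#' Write spot coordinates to CSV
#'
#' @param spots A [spot_set()] or n x 3 matrix (µm).
#' @param path Output CSV file.
#' @export
write_spots <- function(spots, path) {
  m <- if (inherits(spots, "spot_set")) spots$coords else as.matrix(spots)
  write.csv(data.frame(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3]), path,
            row.names = FALSE)
  invisible(path)
}

#' Read fibril traces from SWC-like text
#'
#' Whitespace-separated columns `id parent x_nm y_nm z_nm`; points with
#' `parent == -1` start a new fibril, each further point chains to its
#' parent. Lines starting with `#` are comments.
#'
#' @param path Text file.
#' @return List of [fibril_trace()]s.
#' @export
read_fibrils_swc <- function(path) {
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "parent", "x", "y", "z"))
  roots <- df$id[df$parent == -1]
  lapply(seq_along(roots), function(k) {
    pts <- NULL
    cur <- roots[k]
    repeat {
      row <- df[df$id == cur, ]
      pts <- rbind(pts, c(row$x, row$y, row$z))
      nxt <- df$id[df$parent == cur]
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    fibril_trace(pts, id = k)
  })
}

#' Write fibril traces to SWC-like text
#'
#' @param fibrils List of [fibril_trace()]s.
#' @param path Output file.
#' @export
write_fibrils_swc <- function(fibrils, path) {
  if (inherits(fibrils, "fibril_trace")) fibrils <- list(fibrils)
  rows <- NULL
  nid <- 0
  for (f in fibrils) {
    n <- nrow(f$points)
    ids <- nid + seq_len(n)
    par <- c(-1, ids[-n])
    rows <- rbind(rows, cbind(ids, par, f$points))
    nid <- nid + n
  }
  write.table(rows, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
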