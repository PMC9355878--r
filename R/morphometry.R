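#' Exclusive compartment volumes and fractions
#'
#' Overlaps between the T-zone, follicle and lymphatic masks are removed
#' by the fixed subtraction order: lymphatics keep everything
#' (`L' = L`), the T-zone loses lymphatic voxels (`T' = T \ L`), and
#' follicles lose both (`B' = B \ L \ T`). Absolute volumes are exclusive
#' voxel counts times the voxel volume; fractions are of the exclusive
#' sum.
#'
#' @param t_zone,follicles,lymphatics Same-shape logical (or 0/1) arrays.
#' @param voxel_volume µm³ per voxel.
#' @return An object of class `compartment_volumes` with `absolute_mm3`
#'   and `fractions` (named: t_zone, follicles, lymphatics).
#' @export
exclusive_compartments <- function(t_zone, follicles, lymphatics,
                                   voxel_volume) {
  tz <- as.logical(t_zone); b <- as.logical(follicles); l <- as.logical(lymphatics)
  if (length(tz) != length(b) || length(b) != length(l))
    stop("masks must have the same shape")
  if (voxel_volume <= 0) stop("voxel_volume must be positive")
  t_ex <- tz & !l
  b_ex <- b & !l & !tz
  counts <- c(t_zone = sum(t_ex), follicles = sum(b_ex), lymphatics = sum(l))
  if (sum(counts) == 0) stop("all-empty masks: fractions undefined")
  abs_mm3 <- counts * voxel_volume * 1e-9       # um^3 -> mm^3
  structure(list(absolute_mm3 = abs_mm3, fractions = counts / sum(counts),
                 exclusive_counts = counts),
            class = "compartment_volumes")
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity inside the nuclear mask divided by the mean intensity
#' of the adjacent cytoplasm mask; a ratio above 1 flags nuclear
#' localisation of the stain.
#'
#' @param nuclear_mask,cyto_mask Disjoint, non-empty logical arrays.
#' @param image Intensity array of the same shape.
#' @return An object of class `nc_ratio` with `nuclear_mean`,
#'   `cytoplasmic_mean`, `ratio` and `nuclear_localized`.
#' @export
nc_ratio <- function(nuclear_mask, cyto_mask, image) {
  nm <- as.logical(nuclear_mask); cm <- as.logical(cyto_mask)
  if (length(nm) != length(image) || length(cm) != length(image))
    stop("masks and image must have the same shape")
  if (!any(nm) || !any(cm)) stop("invalid input: empty mask")
  if (any(nm & cm)) stop("invalid input: masks overlap")
  nmean <- mean(image[nm]); cmean <- mean(image[cm])
  if (cmean == 0) stop("undefined ratio: zero cytoplasmic mean")
  structure(list(nuclear_mean = nmean, cytoplasmic_mean = cmean,
                 ratio = nmean / cmean, nuclear_localized = nmean / cmean > 1),
            class = "nc_ratio")
}

#' Average capsule thickness
#'
#' Arithmetic mean of at least three per-location measurements (µm).
#'
#' @param measurements Numeric vector of thickness values (µm), length
#'   >= 3.
#' @return Mean thickness (µm).
#' @export
capsule_thickness <- function(measurements) {
  if (length(measurements) < 3)
    stop("insufficient measurements: at least three locations required")
  mean(measurements)
}

#' Normalise intensities to the control mean
#'
#' @param samples Numeric vector of sample intensities.
#' @param controls Numeric vector of control intensities, length >= 1.
#' @return `samples / mean(controls)`.
#' @export
normalize_to_controls <- function(samples, controls) {
  if (!length(controls)) stop("at least one control required")
  m <- mean(controls)
  if (m == 0) stop("undefined normalisation: zero control mean")
  samples / m
}
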