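#' Kymograph of a laser-cut recoil
#'
#' A space-by-time intensity matrix sampled along the recoil axis.
#' Pixel `i` sits at position `(i - 1) * px_size` µm; frame `j` at time
#' `(j - 1) * frame_interval` s. `cut_frame` is the first frame after the
#' cut.
#'
#' @param intensity Numeric matrix, space x time.
#' @param px_size µm per pixel.
#' @param frame_interval s per frame.
#' @param cut_frame Index of the first post-cut frame.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, px_size, frame_interval, cut_frame) {
  intensity <- as.matrix(intensity)
  if (px_size <= 0 || frame_interval <= 0)
    stop("px_size and frame_interval must be positive")
  if (cut_frame < 1 || cut_frame > ncol(intensity))
    stop("cut_frame outside the time range")
  structure(list(intensity = intensity, px_size = px_size,
                 frame_interval = frame_interval, cut_frame = cut_frame),
            class = "kymograph")
}

#' Track the retracting edge in a kymograph
#'
#' For every post-cut frame the edge is located at the maximum of the
#' absolute spatial intensity gradient, refined to sub-pixel precision by
#' a parabola through the three bracketing gradient samples. The method
#' requires a single dominant edge: a frame is accepted only when its
#' gradient peak exceeds the strongest gradient elsewhere in the profile
#' by `min_dominance` (pure noise and pure texture have many peaks of
#' comparable height and are rejected). Tracking stops at the first
#' frame where the edge is lost (e.g. it left the field of view); a
#' kymograph with no detectable edge at all raises an error.
#'
#' @param kymo A [kymograph()].
#' @param min_dominance Minimum ratio of the gradient peak to the
#'   largest gradient more than 10 px away from it, default 1.4.
#' @param smooth_px Gaussian sigma (px) applied to each spatial profile
#'   before differentiation; 0 disables smoothing.
#' @return An object of class `edge_track` with `t` (s, measured from the
#'   cut) and `position` (µm).
#' @export
extract_edge <- function(kymo, min_dominance = 1.4, smooth_px = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  frames <- kymo$cut_frame:ncol(kymo$intensity)
  pos <- numeric(0)
  for (k in seq_along(frames)) {
    prof <- kymo$intensity[, frames[k]]
    if (smooth_px > 0)
      prof <- as.numeric(.gauss_blur(matrix(prof, ncol = 1), smooth_px))
    g <- abs(diff(prof))
    i <- which.max(g)
    rival <- max(g[abs(seq_along(g) - i) > 10], 0)
    if (g[i] < min_dominance * max(rival, 1e-12)) break  # edge lost/absent
    delta <- 0
    if (i > 1 && i < length(g)) {
      y <- g[(i - 1):(i + 1)]
      den <- y[1] - 2 * y[2] + y[3]
      if (den < 0) delta <- 0.5 * (y[1] - y[3]) / den
    }
    pos[k] <- (i - 0.5 + delta) * kymo$px_size   # gradient lives between pixels
  }
  if (!length(pos))
    stop("edge not found: gradient peak below the noise floor")
  structure(list(t = (seq_along(pos) - 1) * kymo$frame_interval,
                 position = pos),
            class = "edge_track")
}

#' Recoil velocity from an edge track
#'
#' Least-squares slope of the edge position over the first
#' `window_frames` samples after the cut.
#'
#' @param track An [extract_edge()] result (or any list with `t` and
#'   `position`).
#' @param window_frames Number of frames in the fit window, default 5.
#' @return Velocity in µm/s (positive = motion towards larger positions).
#' @export
recoil_velocity <- function(track, window_frames = 5) {
  if (window_frames > length(track$t))
    stop("invalid parameter: window exceeds track length")
  if (window_frames < 2) stop("invalid parameter: window needs >= 2 frames")
  idx <- seq_len(window_frames)
  unname(coef(lm(track$position[idx] ~ track$t[idx]))[2])
}

#' Cut geometry and analysis region
#'
#' @param cut_line 2 x 2 matrix: the two endpoints of the cut (µm).
#' @param roi Rectangle `c(xmin, xmax, ymin, ymax)` around the cut (µm).
#' @return An object of class `cut_geometry`.
#' @export
cut_geometry <- function(cut_line, roi) {
  cut_line <- as.matrix(cut_line)
  if (!all(dim(cut_line) == c(2, 2)) || all(cut_line[1, ] == cut_line[2, ]))
    stop("cut_line needs two distinct 2D endpoints")
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) stop("empty roi")
  structure(list(cut_line = cut_line, roi = as.numeric(roi)),
            class = "cut_geometry")
}

# separable Gaussian blur with replicate-edge padding
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {           # filter along rows of m
    n <- nrow(m)
    mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Bandpass filter an image (difference of Gaussians)
#'
#' @param img Numeric matrix.
#' @param band `c(sigma_low, sigma_high)` in px; structure between these
#'   scales is retained.
#' @return Filtered matrix.
#' @export
bandpass <- function(img, band = c(1, 8)) {
  .gauss_blur(img, band[1]) - .gauss_blur(img, band[2])
}

#' Block-wise displacement field between two frames (PIV)
#'
#' Both frames are bandpass filtered, tiled into interrogation windows,
#' and each window pair is matched by normalised cross-correlation
#' (computed via FFT) over shifts up to half the window size; the
#' correlation peak is refined to sub-pixel precision with a
#' three-point Gaussian fit. Windows whose correlation peak falls below
#' `min_corr` (e.g. featureless or decorrelated regions) are flagged
#' invalid.
#'
#' @param frame_pre,frame_post Equal-size numeric matrices (x = rows,
#'   y = columns; pixel `i` at `(i-1)*px_size` µm).
#' @param window_px Interrogation window size (px), >= 8.
#' @param overlap Fraction of window overlap between neighbouring
#'   windows, default 0.5.
#' @param px_size µm per pixel.
#' @param dt Time between the frames (s).
#' @param band Bandpass sigmas (px) passed to [bandpass()].
#' @param min_corr Validity threshold on the correlation peak.
#' @param min_peak_ratio Minimum ratio of the correlation peak to the
#'   best peak elsewhere; lower ratios flag the window ambiguous.
#' @return An object of class `velocity_field` with window-centre
#'   positions (µm), velocity components `vx`, `vy` (µm/s), the
#'   correlation peaks and a `valid` flag.
#' @export
piv_displacement <- function(frame_pre, frame_post, window_px = 32,
                             overlap = 0.5, px_size = 1, dt = 1,
                             band = c(1, 8), min_corr = 0.3,
                             min_peak_ratio = 1.2) {
  if (!all(dim(frame_pre) == dim(frame_post)))
    stop("frames must have identical size")
  if (window_px < 8) stop("window_px must be >= 8")
  A <- bandpass(frame_pre, band)
  B <- bandpass(frame_post, band)
  step <- max(1L, round(window_px * (1 - overlap)))
  xs <- seq(1L, nrow(A) - window_px + 1L, by = step)
  ys <- seq(1L, ncol(A) - window_px + 1L, by = step)
  w <- window_px
  maxs <- w %/% 3          # shifts beyond w/3 lose too much overlap
  n <- length(xs) * length(ys)
  px <- py <- vx <- vy <- corr <- numeric(n)
  valid <- logical(n)
  k <- 0L
  for (x0 in xs) for (y0 in ys) {
    k <- k + 1L
    a <- A[x0:(x0 + w - 1L), y0:(y0 + w - 1L)]
    b <- B[x0:(x0 + w - 1L), y0:(y0 + w - 1L)]
    a <- a - mean(a); b <- b - mean(b)
    px[k] <- (x0 - 1 + (w - 1) / 2) * px_size
    py[k] <- (y0 - 1 + (w - 1) / 2) * px_size
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) next
    # circular cross-correlation on a zero-padded grid
    P <- 2L * w
    ap <- matrix(0, P, P); bp <- matrix(0, P, P)
    ap[1:w, 1:w] <- a; bp[1:w, 1:w] <- b
    cc <- Re(fft(Conj(fft(ap)) * fft(bp), inverse = TRUE)) / (P * P)
    cc <- cc / (na * nb)
    sh <- function(i) ifelse(i - 1 > P / 2, i - 1 - P, i - 1)
    ix <- sh(row(cc)); iy <- sh(col(cc))
    cc[abs(ix) > maxs | abs(iy) > maxs] <- -Inf
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pkv <- cc[pk[1], pk[2]]
    corr[k] <- pkv
    if (pkv < min_corr) next
    # peak must dominate its runners-up (guards against quasi-periodic
    # texture, whose correlation ridge is ambiguous)
    cc2 <- cc
    cc2[pmin(abs(row(cc) - pk[1]), P - abs(row(cc) - pk[1])) <= 2 &
          pmin(abs(col(cc) - pk[2]), P - abs(col(cc) - pk[2])) <= 2] <- -Inf
    second <- max(cc2)
    if (is.finite(second) && second > 0 && pkv / second < min_peak_ratio) next
    dx <- sh(pk[1]); dy <- sh(pk[2])
    gfit <- function(c0, cm, cp) {
      if (!is.finite(cm) || !is.finite(cp)) return(0)
      if (cm > 0 && c0 > 0 && cp > 0 && (log(cm) - 2 * log(c0) + log(cp)) < 0)
        0.5 * (log(cm) - log(cp)) / (log(cm) - 2 * log(c0) + log(cp))
      else if ((cm - 2 * c0 + cp) < 0) 0.5 * (cm - cp) / (cm - 2 * c0 + cp)
      else 0
    }
    wrap <- function(i) ((i - 1) %% P) + 1
    # partial window overlap tilts the correlation linearly in the shift;
    # divide the three-point stencil by the overlap fraction before the
    # sub-pixel fit (peak finding above stays on the raw correlation)
    ov <- function(ddx, ddy) pmax((w - abs(ddx)) * (w - abs(ddy)), 1) / (w * w)
    cval <- function(i, j) cc[wrap(i), wrap(j)] / ov(sh(wrap(i)), sh(wrap(j)))
    ddx <- gfit(cval(pk[1], pk[2]), cval(pk[1] - 1, pk[2]), cval(pk[1] + 1, pk[2]))
    ddy <- gfit(cval(pk[1], pk[2]), cval(pk[1], pk[2] - 1), cval(pk[1], pk[2] + 1))
    vx[k] <- (dx + ddx) * px_size / dt
    vy[k] <- (dy + ddy) * px_size / dt
    valid[k] <- TRUE
  }
  structure(list(x = px, y = py, vx = vx, vy = vy, corr = corr,
                 valid = valid, px_size = px_size, dt = dt),
            class = "velocity_field")
}

#' Mean recoil velocity perpendicular to the cut
#'
#' Averages, over the valid vectors inside the region of interest, the
#' velocity component along the unit normal of the cut line; the normal
#' is oriented away from the cut towards the roi centroid, so recoil away
#' from the cut is positive.
#'
#' @param field A [piv_displacement()] result.
#' @param cut A [cut_geometry()].
#' @return Velocity in µm/s.
#' @export
perpendicular_recoil <- function(field, cut) {
  stopifnot(inherits(field, "velocity_field"), inherits(cut, "cut_geometry"))
  dirv <- cut$cut_line[2, ] - cut$cut_line[1, ]
  nrm <- c(-dirv[2], dirv[1]) / sqrt(sum(dirv^2))
  mid <- colMeans(cut$cut_line)
  cen <- c(mean(cut$roi[1:2]), mean(cut$roi[3:4]))
  if (sum(nrm * (cen - mid)) < 0) nrm <- -nrm
  inroi <- field$x >= cut$roi[1] & field$x <= cut$roi[2] &
    field$y >= cut$roi[3] & field$y <= cut$roi[4]
  sel <- inroi & field$valid
  if (!any(sel)) stop("undefined recoil: no valid vectors in the roi")
  mean(field$vx[sel] * nrm[1] + field$vy[sel] * nrm[2])
}
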