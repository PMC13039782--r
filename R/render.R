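#' Three-lobed orifice boundary radius
#'
#' The synthetic valve opening is a rounded three-lobed curve
#' r(theta) = r0 * (1 + lobe * cos(3 theta)), echoing the tri-leaflet
#' geometry; its enclosed area is pi * r0^2 * (1 + lobe^2 / 2), so `r0` can
#' be solved exactly for a requested area.
#'
#' @param area target orifice area (any squared length unit)
#' @param lobe lobe modulation amplitude in [0, 1)
#' @return base radius `r0` in the matching length unit
#' @keywords internal
orifice_r0 <- function(area, lobe) sqrt(area / (pi * (1 + lobe^2 / 2)))

#' Render synthetic endoscope-like frames with known orifice area
#'
#' Produces greyscale frames mimicking raw endoscope video of the valve from
#' the aortic side: a bright leaflet annulus inside the valve housing circle,
#' a dark three-lobed orifice of known area at its centre, and a dark
#' background outside the housing. Frames are rasterised on a 4x supersampled
#' grid and block-averaged, so the stored ground-truth pixel area is stable;
#' Gaussian noise is added last, seeded.
#'
#' @param ava an `ava_series` (see [ava_series()]) or a plain numeric vector
#'   of orifice areas over time, cm^2
#' @param timestamps sample times in s (defaults to `ava$t` or an index grid)
#' @param shape frame size in px, `c(rows, cols)`
#' @param px_per_cm pixels per cm
#' @param valve_radius valve housing radius in px (the circular ROI)
#' @param lobe lobe modulation of the orifice outline, in [0,1)
#' @param noise_sd additive Gaussian intensity noise (intensities are in [0,1])
#' @param seed integer RNG seed
#' @return a `frame_stack`: list with `frames` (list of matrices in [0,1]),
#'   `px_per_cm`, `timestamps`, `valve_center` (row, col), `valve_radius`, and
#'   `true_area_cm2` (supersampled ground-truth area per frame)
#' @export
render_endoscope_frames <- function(ava, timestamps = NULL,
                                    shape = c(256, 256), px_per_cm = 100,
                                    valve_radius = 110, lobe = 0.25,
                                    noise_sd = 0, seed = 1L) {
  areas <- if (inherits(ava, "ava_series")) ava$area else as.numeric(ava)
  if (any(areas < 0)) stop("orifice areas must be >= 0")
  if (is.null(timestamps))
    timestamps <- if (inherits(ava, "ava_series")) ava$t else seq_along(areas) - 1
  if (!(px_per_cm > 0)) stop("px_per_cm must be > 0")
  nr <- shape[1]; nc <- shape[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (center[1] + valve_radius > nr || center[2] + valve_radius > nc ||
      center[1] - valve_radius < 1 || center[2] - valve_radius < 1)
    stop("valve circle does not fit inside the frame")
  ss <- 4L  # supersampling factor
  # supersample pixel-centre coordinates relative to the valve centre (px)
  rr <- (rep(seq_len(nr * ss), times = nc * ss) - 0.5) / ss + 0.5 / ss - center[1]
  cc <- (rep(seq_len(nc * ss), each = nr * ss) - 0.5) / ss + 0.5 / ss - center[2]
  rad <- sqrt(rr^2 + cc^2)
  th <- atan2(rr, cc)
  in_valve <- rad <= valve_radius
  rng <- local_seed(seed)
  on.exit(rng(), add = TRUE)
  frames <- vector("list", length(areas))
  truth <- numeric(length(areas))
  for (k in seq_along(areas)) {
    a_px <- areas[k] * px_per_cm^2  # orifice area in px^2
    if (a_px > 0) {
      r0 <- orifice_r0(a_px, lobe)
      if (r0 * (1 + lobe) >= valve_radius)
        stop("orifice larger than the valve circle")
      in_orifice <- in_valve & (rad <= r0 * (1 + lobe * cos(3 * th)))
    } else in_orifice <- rep(FALSE, length(rad))
    # uniform bright field (housing + leaflets) with a dark orifice: the
    # orifice is the only below-field structure, as in the illuminated video
    img <- 0.85 - 0.70 * in_orifice
    m <- matrix(img, nr * ss, nc * ss)
    # block-average ss x ss supersamples into each output pixel
    m <- (m[seq(1, nr * ss, 2), ] + m[seq(2, nr * ss, 2), ]) / 2
    m <- (m[seq(1, nrow(m), 2), ] + m[seq(2, nrow(m), 2), ]) / 2
    m <- (m[, seq(1, nc * ss, 2)] + m[, seq(2, nc * ss, 2)]) / 2
    m <- (m[, seq(1, ncol(m), 2)] + m[, seq(2, ncol(m), 2)]) / 2
    truth[k] <- sum(in_orifice) / ss^2 / px_per_cm^2
    if (noise_sd > 0)
      m <- pmin(pmax(m + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0), 1)
    frames[[k]] <- m
  }
  structure(list(frames = frames, px_per_cm = px_per_cm,
                 timestamps = timestamps, valve_center = center,
                 valve_radius = valve_radius, true_area_cm2 = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames %dx%d px, %g px/cm, valve r = %g px\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$px_per_cm, x$valve_radius))
  invisible(x)
}

#' Generate a 3D tri-leaflet point cloud with a known orifice
#'
#' Samples the three leaflet surfaces of an open valve as a 3D point cloud:
#' points cover the annular region between a central three-lobed orifice of
#' prescribed projected area and the valve tube wall. Points lie on gently
#' bellied leaflet surfaces (out-of-plane coordinate grows towards the
#' centre), are labelled 1-3 by angular sector, and are sampled on a jittered
#' regular grid so the downstream rasterisation sees a gap-free surface.
#'
#' @param opening_area projected orifice area along the valve axis, cm^2
#' @param n_points approximate number of points (minimum 5000, documented:
#'   fewer points leave empty raster cells that masquerade as holes)
#' @param seed integer RNG seed for the jitter
#' @param tube_radius_mm valve tube (annulus) radius in mm
#' @param lobe orifice lobe modulation in [0,1)
#' @param calcified_fraction fraction of points flagged calcified (by sector
#'   proximity, mimicking focal deposits), default 0
#' @return a `leaflet_cloud`: `points` (n x 3 matrix, mm), `leaflet_label`
#'   (1,2,3), `calcified` (logical), `axis` (unit 3-vector)
#' @export
generate_leaflet_cloud <- function(opening_area, n_points = 60000L, seed = 1L,
                                   tube_radius_mm = 13, lobe = 0.25,
                                   calcified_fraction = 0) {
  if (opening_area < 0) stop("opening_area must be >= 0")
  if (n_points < 5000)
    stop("n_points too small to resolve the orifice (minimum 5000)")
  R <- tube_radius_mm
  a_mm2 <- opening_area * 100  # cm^2 -> mm^2
  r0 <- if (a_mm2 > 0) orifice_r0(a_mm2, lobe) else 0
  if (r0 * (1 + lobe) >= R) stop("orifice larger than the valve tube")
  # jittered regular grid over the bounding square, kept if inside annulus
  spacing <- sqrt((2 * R)^2 / n_points)
  g <- seq(-R + spacing / 2, R - spacing / 2, by = spacing)
  xy <- expand.grid(x = g, y = g)
  rng <- local_seed(seed)
  on.exit(rng(), add = TRUE)
  xy$x <- xy$x + stats::runif(nrow(xy), -0.35, 0.35) * spacing
  xy$y <- xy$y + stats::runif(nrow(xy), -0.35, 0.35) * spacing
  rad <- sqrt(xy$x^2 + xy$y^2)
  th <- atan2(xy$y, xy$x)
  r_in <- if (r0 > 0) r0 * (1 + lobe * cos(3 * th)) else 0
  keep <- rad <= R & rad >= r_in
  x <- xy$x[keep]; y <- xy$y[keep]; rad <- rad[keep]; th <- th[keep]
  # leaflet belly: surfaces rise towards the free edge (centre)
  z <- 2.5 * (1 - rad / R)
  pts <- cbind(x, y, z)
  lab <- (floor((th + pi) / (2 * pi / 3)) %% 3) + 1L
  calc <- rep(FALSE, length(x))
  if (calcified_fraction > 0) {
    k <- max(1L, round(calcified_fraction * length(x)))
    # focal deposit: the k points nearest a fixed spot on leaflet 1
    spot <- c(0.6 * R, 0.25 * R)
    d2 <- (x - spot[1])^2 + (y - spot[2])^2
    calc[order(d2)[seq_len(k)]] <- TRUE
  }
  structure(list(points = pts, leaflet_label = lab, calcified = calc,
                 axis = c(0, 0, 1)), class = "leaflet_cloud")
}

#' @export
print.leaflet_cloud <- function(x, ...) {
  cat(sprintf("<leaflet_cloud> %d points, leaflets {%s}, %d calcified\n",
              nrow(x$points), paste(sort(unique(x$leaflet_label)), collapse = ","),
              sum(x$calcified)))
  invisible(x)
}

#' Rotate a leaflet cloud (and its axis) rigidly
#'
#' Utility for invariance checks: applies the same rotation matrix to the
#' points and to the valve axis, so projection along the rotated axis must
#' recover the same orifice area.
#'
#' @param cloud a `leaflet_cloud`
#' @param rotation 3x3 rotation matrix
#' @return the rotated `leaflet_cloud`
#' @export
rotate_cloud <- function(cloud, rotation) {
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  cloud$points <- cloud$points %*% t(rotation)
  cloud$axis <- as.numeric(rotation %*% cloud$axis)
  cloud
}
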