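#' Configuration of the mesh-projection AVA extraction
#'
#' @param resolution grid resolution (cells per side), default 150
#' @param projection_axis unit 3-vector (valve axis); `NULL` means take the
#'   cloud's own axis, or the best-fit plane normal when that is absent
#' @param physical_extent side length of the square raster, cm; `NULL` means
#'   tight bounding square of the projected points plus one cell of margin
#' @param sensitivity resolution multipliers for the envelopes, default
#'   `c(0.9, 1.1)`
#' @return a `raster_config`
#' @export
raster_config <- function(resolution = 150L, projection_axis = NULL,
                          physical_extent = NULL, sensitivity = c(0.9, 1.1)) {
  if (resolution < 16) stop("resolution must be >= 16")
  if (!is.null(physical_extent) && !(physical_extent > 0))
    stop("physical_extent must be > 0")
  structure(list(resolution = as.integer(resolution),
                 projection_axis = projection_axis,
                 physical_extent = physical_extent,
                 sensitivity = sort(sensitivity)),
            class = "raster_config")
}

# best-fit plane normal of a point set (smallest principal direction)
best_fit_normal <- function(points) {
  p <- sweep(points, 2, colMeans(points))
  v <- svd(p, nu = 0)$v[, 3]
  v / sqrt(sum(v^2))
}

#' Project a 3D leaflet cloud onto the plane normal to the valve axis
#'
#' Orthogonal projection: a deterministic in-plane orthonormal basis is built
#' from the axis, and point coordinates (mm) are returned in that basis in cm.
#'
#' @param cloud a `leaflet_cloud` (points in mm) or an n x 3 matrix
#' @param axis unit 3-vector; defaults to the cloud's axis, else the best-fit
#'   plane normal of the points
#' @return n x 2 matrix of in-plane coordinates, cm
#' @export
project_points <- function(cloud, axis = NULL) {
  pts <- if (inherits(cloud, "leaflet_cloud")) cloud$points else as.matrix(cloud)
  if (is.null(axis))
    axis <- if (inherits(cloud, "leaflet_cloud")) cloud$axis else best_fit_normal(pts)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("degenerate projection axis")
  a <- axis / nrm
  helper <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(a[2] * helper[3] - a[3] * helper[2],
          a[3] * helper[1] - a[1] * helper[3],
          a[1] * helper[2] - a[2] * helper[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  cbind(x = pts %*% e1, y = pts %*% e2) / 10  # mm -> cm
}

#' Rasterise projected points to a binary occupancy grid
#'
#' Cells are half-open intervals `[x_i, x_{i+1})`; a point exactly on the
#' maximum boundary belongs to the last cell. A cell is 1 iff at least one
#' projected point falls in it. Points outside the extent are clipped with a
#' warning that counts them.
#'
#' @param points2d n x 2 matrix, cm (from [project_points()])
#' @param cfg a [raster_config()]
#' @return binary matrix (resolution x resolution); row 1 is minimum y. The
#'   grid origin and cell size (cm) are attached as attributes `origin`,
#'   `cell_cm`.
#' @export
rasterize <- function(points2d, cfg = raster_config()) {
  res <- cfg$resolution
  ctr <- colMeans(points2d)
  ext <- cfg$physical_extent
  if (is.null(ext)) {
    half <- max(abs(sweep(points2d, 2, ctr)))
    ext <- 2 * half * (1 + 2 / res)
  }
  x0 <- ctr[1] - ext / 2; y0 <- ctr[2] - ext / 2
  cell <- ext / res
  ix <- floor((points2d[, 1] - x0) / cell) + 1L
  iy <- floor((points2d[, 2] - y0) / cell) + 1L
  ix[points2d[, 1] == x0 + ext] <- res  # max-boundary points -> last cell
  iy[points2d[, 2] == y0 + ext] <- res
  out_of <- ix < 1 | ix > res | iy < 1 | iy > res
  if (any(out_of)) {
    warning(sum(out_of), " points outside the raster extent were clipped")
    ix <- ix[!out_of]; iy <- iy[!out_of]
  }
  grid <- matrix(0L, res, res)  # rows = y, cols = x
  grid[cbind(iy, ix)] <- 1L
  attr(grid, "origin") <- c(x0, y0)
  attr(grid, "cell_cm") <- cell
  grid
}

#' Orifice area of a binary occupancy grid
#'
#' Fills the holes of the occupancy image, subtracts the original image, and
#' takes the largest 8-connected component of the difference as the valve
#' opening; its cell count is converted to cm^2 with the grid cell size.
#'
#' @param grid binary matrix from [rasterize()] (must carry `cell_cm`), or any
#'   binary matrix with `cell_cm` supplied
#' @param cell_cm cell side length in cm (defaults to the grid attribute)
#' @return orifice area, cm^2 (0 when there is no hole)
#' @export
orifice_area <- function(grid, cell_cm = attr(grid, "cell_cm")) {
  if (is.null(cell_cm)) stop("cell size unknown: pass cell_cm")
  m <- matrix(as.numeric(grid != 0), nrow(grid), ncol(grid))
  filled <- matrix(as.numeric(EBImage::fillHull(m) > 0), nrow(m), ncol(m))
  holes <- filled - m
  lab <- label_components_8(holes)
  if (max(lab) == 0) return(0)
  max(tabulate(lab[lab > 0])) * cell_cm^2
}

#' Mesh-projection AVA with resolution envelopes
#'
#' Computes the orifice area at the nominal grid resolution and at 110% and
#' 90% of it (rounded). By the method's reporting convention, the higher
#' resolution provides the lower limit and the lower resolution the upper
#' limit; because the sign of the grid bias also depends on point density,
#' the reported `lower`/`upper` are additionally sorted so that
#' `lower <= upper` always holds (the raw per-resolution values are kept).
#'
#' @param cloud a `leaflet_cloud` or n x 3 point matrix (mm)
#' @param cfg a [raster_config()]
#' @return list with `area`, `lower`, `upper` (cm^2) and `by_resolution`,
#'   a data.frame of the three raw (resolution, area) pairs
#' @export
ava_with_resolution_bounds <- function(cloud, cfg = raster_config()) {
  p2 <- project_points(cloud, cfg$projection_axis)
  at_res <- function(res) {
    c2 <- cfg; c2$resolution <- as.integer(res)
    g <- rasterize(p2, c2)
    orifice_area(g)
  }
  res0 <- cfg$resolution
  res_hi <- round(max(cfg$sensitivity) * res0)
  res_lo <- round(min(cfg$sensitivity) * res0)
  a  <- at_res(res0)
  a_hi <- at_res(res_hi)  # higher resolution -> lower limit (convention)
  a_lo <- at_res(res_lo)
  list(area = a,
       lower = min(a_hi, a_lo, a),
       upper = max(a_hi, a_lo, a),
       by_resolution = data.frame(resolution = c(res_lo, res0, res_hi),
                                  area = c(a_lo, a, a_hi)))
}
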