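#' AVA-over-time series with uncertainty envelopes
#'
#' @param t sample times, s
#' @param area nominal aortic valve area, cm^2
#' @param area_lower,area_upper lower/upper envelopes, cm^2 (threshold or
#'   resolution sensitivity); the pointwise ordering
#'   `0 <= lower <= area <= upper` is enforced
#' @return an `ava_series`
#' @export
ava_series <- function(t, area, area_lower = area, area_upper = area) {
  stopifnot(length(t) == length(area), length(area_lower) == length(area),
            length(area_upper) == length(area))
  if (any(area_lower < -1e-12) || any(area_lower > area + 1e-12) ||
      any(area > area_upper + 1e-12))
    stop("ava_series ordering violated: need 0 <= lower <= area <= upper")
  structure(list(t = as.numeric(t), area = as.numeric(area),
                 area_lower = pmin(area_lower, area),
                 area_upper = pmax(area_upper, area)),
            class = "ava_series")
}

#' @export
print.ava_series <- function(x, ...) {
  cat(sprintf("<ava_series> %d samples, max area %.3f cm^2 [%.3f, %.3f]\n",
              length(x$t), max(x$area), x$area_lower[which.max(x$area)],
              x$area_upper[which.max(x$area)]))
  invisible(x)
}

#' Per-cycle maximum AVA
#'
#' The cycle-based maximum aortic valve area: the series is split into cycles
#' and the maximum of each cycle is reported with its envelopes at the
#' maximising frame.
#'
#' @param series an `ava_series`
#' @param cycle_time cycle duration, s
#' @return data.frame with one row per cycle: `cycle`, `max_area`, `lower`, `upper`
#' @export
max_ava_per_cycle <- function(series, cycle_time) {
  cyc <- floor(series$t / cycle_time)
  idx <- split(seq_along(series$t), cyc)
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[[k]][which.max(series$area[idx[[k]]])]
    data.frame(cycle = k, max_area = series$area[i],
               lower = series$area_lower[i], upper = series$area_upper[i])
  })
  do.call(rbind, rows)
}

#' Configuration of the video AVA extraction
#'
#' @param threshold fixed intensity threshold in (0,1) applied to the
#'   preprocessed (inverted, normalised) frame; `NULL` selects a per-stack
#'   Otsu threshold, used only when no fixed value is supplied
#' @param min_object_px components smaller than this are removed
#' @param closing_radius_px disc radius of the morphological closing (0 = skip)
#' @param valve_center `(row, col)` of the valve housing centre, px
#' @param valve_radius housing radius, px (circular region of interest)
#' @param px_per_cm pixel calibration, obtained from the known housing circle
#' @param sensitivity threshold multipliers for the envelopes (upper-area,
#'   lower-area); defaults `c(0.9, 1.1)`
#' @param min_contrast frames whose raw dynamic range (on the [0,1] sensor
#'   scale) is below this are treated as showing a closed valve (area 0):
#'   with no orifice there is no contrast, and min-max normalisation of a
#'   near-constant frame would only amplify sensor noise into speckle.
#'   Set to 0 to disable.
#' @return an `ava_image_config`
#' @export
ava_image_config <- function(threshold = NULL, min_object_px = 50,
                             closing_radius_px = 3, valve_center = NULL,
                             valve_radius = NULL, px_per_cm = NULL,
                             sensitivity = c(0.9, 1.1), min_contrast = 0.35) {
  if (!is.null(threshold) && !(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0,1)")
  if (!is.null(valve_radius) && !(valve_radius > 0))
    stop("valve_radius must be > 0")
  structure(list(threshold = threshold, min_object_px = min_object_px,
                 closing_radius_px = closing_radius_px,
                 valve_center = valve_center, valve_radius = valve_radius,
                 px_per_cm = px_per_cm, sensitivity = sort(sensitivity),
                 min_contrast = min_contrast),
            class = "ava_image_config")
}

#' Preprocess one video frame
#'
#' Converts to a single grey channel (averaging RGB planes if present),
#' inverts so the valve opening becomes the brightest structure, and min-max
#' normalises to [0,1]. A constant frame degenerates under normalisation and
#' is returned as all zeros with a warning.
#'
#' @param frame numeric matrix or rows x cols x 3 array
#' @return numeric matrix with values in [0,1]
#' @export
preprocess_frame <- function(frame) {
  if (length(dim(frame)) == 3) frame <- apply(frame, c(1, 2), mean)
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("constant frame: normalisation degenerate, returning zeros")
    return(matrix(0, nrow(frame), ncol(frame)))
  }
  inv <- rng[2] - frame
  inv / diff(rng)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged with a union-find pass.
label_components_8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Threshold a preprocessed frame and clean the binary mask
#'
#' Applies the fixed intensity threshold, then the morphological clean-up in
#' the order used on the bench videos: hole filling within objects, removal
#' of small isolated regions, closing of small gaps, and finally the circular
#' region-of-interest mask defined by the valve centre and radius.
#'
#' @param grid preprocessed intensity matrix in [0,1]
#' @param cfg an [ava_image_config()] with `threshold`, `valve_center`,
#'   `valve_radius` set
#' @return logical matrix
#' @export
binarize_and_clean <- function(grid, cfg) {
  stopifnot(!is.null(cfg$threshold), !is.null(cfg$valve_center),
            !is.null(cfg$valve_radius))
  mask <- grid > cfg$threshold
  m <- matrix(as.numeric(mask), nrow(grid), ncol(grid))
  m <- matrix(as.numeric(EBImage::fillHull(m) > 0), nrow(m), ncol(m))
  if (cfg$min_object_px > 0) {
    lab <- label_components_8(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= cfg$min_object_px)
      m <- matrix(as.numeric(lab %in% keep), nrow(m), ncol(m))
    }
  }
  if (cfg$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * cfg$closing_radius_px + 1, shape = "disc")
    m <- matrix(as.numeric(EBImage::closing(m, brush) > 0), nrow(m), ncol(m))
  }
  rr <- row(m) - cfg$valve_center[1]
  cc <- col(m) - cfg$valve_center[2]
  m[rr^2 + cc^2 > cfg$valve_radius^2] <- 0
  m > 0
}

#' Area of the two largest connected components
#'
#' The two largest 8-connected regions of the cleaned mask are taken to be
#' the valve opening (the orifice often splits into lobes between leaflets);
#' their pixel count is converted to cm^2 with the pixel calibration. With a
#' single component its area is returned; with none, zero.
#'
#' @param mask logical or 0/1 matrix
#' @param px_per_cm pixels per cm
#' @return area in cm^2
#' @export
two_largest_area <- function(mask, px_per_cm) {
  lab <- label_components_8(mask)
  if (max(lab) == 0) return(0)
  sizes <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  sum(utils::head(sizes, 2)) / px_per_cm^2
}

#' Extract an AVA time series with threshold-sensitivity envelopes
#'
#' Runs the full video pipeline on every frame at the nominal threshold and
#' at 110% / 90% of it. On the inverted image a higher threshold selects a
#' smaller region, so 110% of the threshold yields the lower AVA limit and
#' 90% the upper one.
#'
#' @param frames a `frame_stack` from [render_endoscope_frames()] (or a
#'   compatible list)
#' @param cfg an [ava_image_config()]; `valve_center`, `valve_radius` and
#'   `px_per_cm` default to the stack's values, and a missing threshold is
#'   chosen by Otsu's method on the first preprocessed frame
#' @return an [ava_series()]
#' @export
ava_series_with_bounds <- function(frames, cfg = ava_image_config()) {
  if (is.null(cfg$valve_center)) cfg$valve_center <- frames$valve_center
  if (is.null(cfg$valve_radius)) cfg$valve_radius <- frames$valve_radius
  if (is.null(cfg$px_per_cm)) cfg$px_per_cm <- frames$px_per_cm
  pre <- lapply(frames$frames, preprocess_frame)
  if (is.null(cfg$threshold)) {
    cfg$threshold <- as.numeric(EBImage::otsu(pre[[1]], range = c(0, 1)))
  }
  th <- cfg$threshold
  th_lo_area <- th * max(cfg$sensitivity)  # higher threshold -> lower area
  th_hi_area <- th * min(cfg$sensitivity)
  if (th_lo_area >= 1) {
    warning("1.1 * threshold >= 1; clamping to 1 - 1e-6")
    th_lo_area <- 1 - 1e-6
  }
  contrast_ok <- vapply(frames$frames, function(f)
    diff(range(f)) >= cfg$min_contrast, logical(1))
  one <- function(g, ok, theta) {
    if (!ok) return(0)
    c2 <- cfg; c2$threshold <- theta
    two_largest_area(binarize_and_clean(g, c2), cfg$px_per_cm)
  }
  area  <- mapply(one, pre, contrast_ok, MoreArgs = list(theta = th))
  lower <- mapply(one, pre, contrast_ok, MoreArgs = list(theta = th_lo_area))
  upper <- mapply(one, pre, contrast_ok, MoreArgs = list(theta = th_hi_area))
  ava_series(frames$timestamps, area, pmin(lower, area), pmax(upper, area))
}
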