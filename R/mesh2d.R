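#' 2D triangle mesh with tagged boundaries
#'
#' Container for the desk-scale FSI meshes: node coordinates (m), triangle
#' connectivity (counter-clockwise), named node sets, and tagged boundary
#' edges with outward unit normals. Construction validates that all triangle
#' areas are positive and that every boundary edge carries exactly one tag.
#'
#' @param nodes n x 2 matrix of coordinates (m)
#' @param tri m x 3 integer matrix of node indices, counter-clockwise
#' @param node_sets named list of integer index vectors (e.g. `inflow`,
#'   `outflow`, `inside`, `leaflets`, `outside`)
#' @param edge_tagger function(p, q) -> tag string, given the two endpoint
#'   coordinates of a boundary edge
#' @return a `mesh2d`
#' @export
mesh2d <- function(nodes, tri, node_sets = list(), edge_tagger = NULL) {
  geom <- tri_geometry(nodes, tri)
  if (any(geom$area <= 0)) stop("mesh has non-positive triangle areas")
  edges <- boundary_edges(nodes, tri)
  if (!is.null(edge_tagger)) {
    edges$tag <- vapply(seq_len(nrow(edges)), function(k)
      edge_tagger(nodes[edges$a[k], ], nodes[edges$b[k], ]), character(1))
    if (anyNA(edges$tag)) stop("untagged boundary edge")
  } else edges$tag <- "boundary"
  structure(list(nodes = nodes, tri = tri, node_sets = node_sets,
                 edges = edges), class = "mesh2d")
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("<mesh2d> %d nodes, %d triangles; sets: %s\n",
              nrow(x$nodes), nrow(x$tri),
              paste(names(x$node_sets), collapse = ", ")))
  invisible(x)
}

# boundary edges (appearing in exactly one triangle) with outward normals
boundary_edges <- function(nodes, tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  onb <- cnt[key] == 1
  e <- e[onb, , drop = FALSE]
  # triangles are CCW, so the domain lies left of each directed edge;
  # outward normal is the right-hand normal of (a -> b)
  tx <- nodes[e[, 2], 1] - nodes[e[, 1], 1]
  ty <- nodes[e[, 2], 2] - nodes[e[, 1], 2]
  len <- sqrt(tx^2 + ty^2)
  data.frame(a = e[, 1], b = e[, 2], nx = ty / len, ny = -tx / len, len = len)
}

#' Build the channel-with-flexible-leaflet FSI geometry
#'
#' Constructs conforming fluid and solid meshes on a shared structured grid:
#' a rectangular channel (length `length_m`, height `height_m`) with a
#' flexible leaflet (flap) of thickness `flap_thickness` rising from the
#' bottom wall at `flap_x` to height `flap_tip`. Grid lines are aligned with
#' the flap faces so fluid and solid share interface nodes one-to-one.
#' With `flap_x = NULL` a straight channel (no leaflet) is returned.
#'
#' Fluid node sets: `inflow` (x = 0), `outflow` (x = length), `inside`
#' (channel walls), `leaflets` (interface). Solid node sets: `outside`
#' (clamped base, y = 0), `leaflets` (interface).
#'
#' @param length_m,height_m channel dimensions, m
#' @param flap_x leaflet centreline x position, m (NULL = no leaflet)
#' @param flap_tip leaflet height, m
#' @param flap_thickness leaflet thickness, m
#' @param flap_lean downstream lean of the leaflet as a shear factor
#'   (x -> x + lean * y applied to the whole geometry): a leaning leaflet
#'   mimics a partially open valve, and its tip gap then responds at first
#'   order to bending, which is what makes the stroke volume sensitive to
#'   the leaflet stiffness
#' @param nx,ny approximate number of cells along and across the channel
#' @param refine_flap extra grid columns on each side of the leaflet
#' @return list with `fluid` (`mesh2d`), `solid` (`mesh2d` or NULL), `map`
#'   (data.frame `fluid`, `solid` of matched interface node indices), and the
#'   geometry parameters
#' @export
fsi_channel_geometry <- function(length_m = 0.1, height_m = 0.02,
                                 flap_x = 0.03, flap_tip = 0.014,
                                 flap_thickness = 0.002, flap_lean = 0,
                                 nx = 30, ny = 10, refine_flap = 2) {
  xb <- seq(0, length_m, length.out = nx + 1)
  yb <- seq(0, height_m, length.out = ny + 1)
  if (!is.null(flap_x)) {
    x0 <- flap_x - flap_thickness / 2
    x1 <- flap_x + flap_thickness / 2
    # align grid with the flap faces and refine around it
    xb <- xb[xb < x0 - 1e-12 | xb > x1 + 1e-12]
    extra <- c(x0, x1, seq(x0, x1, length.out = refine_flap + 2))
    xb <- sort(unique(round(c(xb, extra), 12)))
    yb <- sort(unique(round(c(yb, flap_tip), 12)))
  }
  nxn <- length(xb); nyn <- length(yb)
  nodes <- cbind(rep(xb, times = nyn), rep(yb, each = nxn))
  nid <- function(i, j) (j - 1L) * nxn + i
  # cell list with solid/fluid classification by centroid
  cells <- expand.grid(i = seq_len(nxn - 1), j = seq_len(nyn - 1))
  cx <- (xb[cells$i] + xb[cells$i + 1]) / 2
  cy <- (yb[cells$j] + yb[cells$j + 1]) / 2
  in_flap <- if (is.null(flap_x)) rep(FALSE, nrow(cells)) else
    cx > flap_x - flap_thickness / 2 & cx < flap_x + flap_thickness / 2 &
    cy < flap_tip
  tri_of <- function(sel) {
    i <- cells$i[sel]; j <- cells$j[sel]
    n1 <- nid(i, j); n2 <- nid(i + 1, j); n3 <- nid(i + 1, j + 1); n4 <- nid(i, j + 1)
    rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  }
  eps <- 1e-12
  build <- function(tri_glob, tagger, sets_of) {
    used <- sort(unique(as.vector(tri_glob)))
    remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
    nd <- nodes[used, , drop = FALSE]
    tr <- matrix(remap[tri_glob], ncol = 3)
    m <- mesh2d(nd, tr, node_sets = sets_of(nd), edge_tagger = tagger)
    m$global <- used
    m
  }
  on_line <- function(v, c0) abs(v - c0) < eps
  if (is.null(flap_x)) {
    tagger <- function(p, q) {
      if (on_line(p[1], 0) && on_line(q[1], 0)) "inflow"
      else if (on_line(p[1], length_m) && on_line(q[1], length_m)) "outflow"
      else "inside"
    }
    fluid <- build(tri_of(!in_flap), tagger, function(nd) list(
      inflow = which(on_line(nd[, 1], 0)),
      outflow = which(on_line(nd[, 1], length_m)),
      inside = which((on_line(nd[, 2], 0) | on_line(nd[, 2], height_m))),
      leaflets = integer(0)))
    return(list(fluid = fluid, solid = NULL,
                map = data.frame(fluid = integer(0), solid = integer(0)),
                length_m = length_m, height_m = height_m, flap_x = NULL))
  }
  x0 <- flap_x - flap_thickness / 2
  x1 <- flap_x + flap_thickness / 2
  on_flap_boundary <- function(p) {
    inx <- p[1] > x0 - eps & p[1] < x1 + eps
    (on_line(p[1], x0) | on_line(p[1], x1)) & p[2] < flap_tip + eps |
      (on_line(p[2], flap_tip) & inx)
  }
  fluid_tagger <- function(p, q) {
    if (on_line(p[1], 0) && on_line(q[1], 0)) return("inflow")
    if (on_line(p[1], length_m) && on_line(q[1], length_m)) return("outflow")
    if (on_flap_boundary(p) && on_flap_boundary(q) &&
        !(on_line(p[2], 0) && on_line(q[2], 0))) return("leaflets")
    "inside"
  }
  solid_tagger <- function(p, q) {
    if (on_line(p[2], 0) && on_line(q[2], 0)) "outside" else "leaflets"
  }
  fluid <- build(tri_of(!in_flap), fluid_tagger, function(nd) {
    onfb <- apply(nd, 1, on_flap_boundary)
    list(
      inflow = which(on_line(nd[, 1], 0)),
      outflow = which(on_line(nd[, 1], length_m)),
      inside = which((on_line(nd[, 2], 0) | on_line(nd[, 2], height_m)) & !onfb),
      leaflets = which(onfb & nd[, 2] > eps))
  })
  solid <- build(tri_of(in_flap), solid_tagger, function(nd) list(
    outside = which(on_line(nd[, 2], 0)),
    leaflets = integer(0)))
  # interface node sets from the tagged boundary edges (boundary nodes only)
  edge_nodes <- function(m, tag) {
    e <- m$edges[m$edges$tag == tag, ]
    sort(unique(c(e$a, e$b)))
  }
  solid$node_sets$leaflets <- setdiff(edge_nodes(solid, "leaflets"),
                                      solid$node_sets$outside)
  lf <- edge_nodes(fluid, "leaflets")
  base <- lf[fluid$nodes[lf, 2] <= eps]  # flap base corners: clamped walls
  fluid$node_sets$leaflets <- setdiff(lf, base)
  fluid$node_sets$inside <- sort(union(fluid$node_sets$inside, base))
  # one-to-one interface map via shared global grid indices
  gi_f <- fluid$global[fluid$node_sets$leaflets]
  gi_s <- solid$global[solid$node_sets$leaflets]
  common <- intersect(gi_f, gi_s)
  map <- data.frame(
    fluid = fluid$node_sets$leaflets[match(common, gi_f)],
    solid = solid$node_sets$leaflets[match(common, gi_s)])
  if (flap_lean != 0) {
    # shear the whole geometry downstream (det = 1: areas and the structured
    # topology are preserved; boundary tags stay valid, normals recomputed)
    shear <- function(m) {
      m$nodes[, 1] <- m$nodes[, 1] + flap_lean * m$nodes[, 2]
      e <- boundary_edges(m$nodes, m$tri)
      m$edges[, c("nx", "ny", "len")] <- e[, c("nx", "ny", "len")]
      m
    }
    fluid <- shear(fluid)
    solid <- shear(solid)
  }
  list(fluid = fluid, solid = solid, map = map,
       length_m = length_m, height_m = height_m,
       flap_x = flap_x, flap_tip = flap_tip,
       flap_thickness = flap_thickness, flap_lean = flap_lean)
}

#' Rectangular solid mesh clamped along its base
#'
#' Convenience builder for structural benchmarks (cantilever bending, free
#' vibration): a `width_m` x `height_m` rectangle of structured triangles
#' with the base (y = 0) in node set `outside` (clamped) and the remaining
#' boundary in `leaflets`.
#'
#' @param width_m,height_m rectangle dimensions, m
#' @param nx,ny cells across width and height
#' @return a `mesh2d`
#' @export
rect_solid_mesh <- function(width_m, height_m, nx = 2, ny = 10) {
  xb <- seq(0, width_m, length.out = nx + 1)
  yb <- seq(0, height_m, length.out = ny + 1)
  nxn <- length(xb); nyn <- length(yb)
  nodes <- cbind(rep(xb, times = nyn), rep(yb, each = nxn))
  nid <- function(i, j) (j - 1L) * nxn + i
  cells <- expand.grid(i = seq_len(nxn - 1), j = seq_len(nyn - 1))
  i <- cells$i; j <- cells$j
  n1 <- nid(i, j); n2 <- nid(i + 1, j); n3 <- nid(i + 1, j + 1); n4 <- nid(i, j + 1)
  tri <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  eps <- 1e-12
  mesh2d(nodes, tri,
         node_sets = list(
           outside = which(nodes[, 2] < eps),
           leaflets = which(nodes[, 2] >= eps &
                              (nodes[, 1] < eps | nodes[, 1] > width_m - eps |
                               nodes[, 2] > height_m - eps))),
         edge_tagger = function(p, q)
           if (p[2] < eps && q[2] < eps) "outside" else "leaflets")
}
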