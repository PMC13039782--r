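#' ALE mesh motion by linear elasticity
#'
#' Propagates the fluid-structure interface displacement into the fluid
#' domain interior by solving a compressible linear elasticity problem on
#' the reference mesh: interface nodes carry the prescribed displacement,
#' all other boundary nodes are fixed, interior nodes follow. The elasticity
#' operator lives on the reference configuration, so it is assembled and
#' factorised once per geometry.
#'
#' @param ref_mesh the reference (undeformed) fluid `mesh2d`
#' @param interface_disp k x 2 displacements of the `leaflets` node set, m
#' @param cache optional precomputed factorisation from [mesh_motion_cache()]
#' @return list with `nodes` (displaced coordinates) and `disp` (n x 2 total
#'   displacement from the reference configuration)
#' @export
move_mesh <- function(ref_mesh, interface_disp, cache = NULL) {
  if (is.null(cache)) cache <- mesh_motion_cache(ref_mesh)
  n <- nrow(ref_mesh$nodes)
  d <- numeric(2 * n)
  lf <- ref_mesh$node_sets$leaflets
  d[cache$dir_idx] <- 0
  d[c(lf, lf + n)] <- c(interface_disp[, 1], interface_disp[, 2])
  rhs <- -as.numeric(cache$K[, cache$dir_idx, drop = FALSE] %*% d[cache$dir_idx])
  free <- cache$free
  d[free] <- as.numeric(Matrix::solve(cache$Kff, rhs[free]))
  disp <- cbind(d[1:n], d[n + 1:n])
  nodes <- ref_mesh$nodes + disp
  if (any(tri_geometry(nodes, ref_mesh$tri)$area <= 0))
    stop("mesh motion inverted an element (re-meshing is out of scope); ",
         "max interface displacement ", signif(max(abs(interface_disp)), 3), " m")
  list(nodes = nodes, disp = disp)
}

#' @rdname move_mesh
#' @export
mesh_motion_cache <- function(ref_mesh) {
  n <- nrow(ref_mesh$nodes)
  geom <- tri_geometry(ref_mesh$nodes, ref_mesh$tri)
  # stiffen small elements (near the interface) so deformation is absorbed
  # by the large far-field cells: standard inverse-area weighting
  K <- fem_elasticity_stiffness_weighted(ref_mesh$nodes, ref_mesh$tri, geom,
                                         weight = min(geom$area) / geom$area)
  bset <- sort(unique(c(ref_mesh$node_sets$inflow, ref_mesh$node_sets$outflow,
                        ref_mesh$node_sets$inside, ref_mesh$node_sets$leaflets)))
  dir_idx <- c(bset, bset + n)
  free <- setdiff(seq_len(2 * n), dir_idx)
  list(K = K, Kff = K[free, free], dir_idx = dir_idx, free = free)
}

# refresh boundary-edge normals/lengths after node motion
refresh_edges <- function(mesh) {
  e <- mesh$edges
  tx <- mesh$nodes[e$b, 1] - mesh$nodes[e$a, 1]
  ty <- mesh$nodes[e$b, 2] - mesh$nodes[e$a, 2]
  len <- sqrt(tx^2 + ty^2)
  e$nx <- ty / len; e$ny <- -tx / len; e$len <- len
  mesh$edges <- e
  mesh
}

# map boundary edges to their owning triangle (needed for stress evaluation)
edge_triangles <- function(mesh) {
  tri <- mesh$tri
  all_e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  tid <- rep(seq_len(nrow(tri)), 3)
  key <- paste(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  bkey <- paste(pmin(mesh$edges$a, mesh$edges$b), pmax(mesh$edges$a, mesh$edges$b))
  tid[match(bkey, key)]
}

#' Fluid traction force on the interface
#'
#' Evaluates the fluid Cauchy stress `sigma = -p I + mu (grad u + grad u^T)`
#' on each leaflet-tagged boundary edge (element-constant gradient of the
#' adjacent triangle, edge-averaged pressure) and integrates the traction
#' `sigma . n_s` exerted by the fluid on the solid, with `n_s` the solid's
#' outward normal (the negative of the fluid boundary normal), into nodal
#' forces.
#'
#' @param state a `fluid_state` (current velocity and pressure)
#' @param ops current mesh operators (for the element geometry)
#' @param edge_tri edge-to-triangle map from `edge_triangles()`
#' @return n x 2 nodal force matrix (nonzero only on interface nodes)
#' @export
fluid_interface_force <- function(state, ops = NULL, edge_tri = NULL) {
  mesh <- state$mesh
  if (is.null(ops)) ops <- fluid_operators(mesh)
  if (is.null(edge_tri)) edge_tri <- edge_triangles(mesh)
  n <- nrow(mesh$nodes)
  f <- matrix(0, n, 2)
  sel <- which(mesh$edges$tag == "leaflets")
  if (length(sel) == 0) return(f)
  grad <- element_velocity_gradient(mesh$tri, ops$geom, state$u)
  mu <- state$mu
  for (k in sel) {
    e <- mesh$edges[k, ]
    te <- edge_tri[k]
    g <- grad[te, ]
    pbar <- (state$p[e$a] + state$p[e$b]) / 2
    sxx <- -pbar + 2 * mu * g[1]
    syy <- -pbar + 2 * mu * g[4]
    sxy <- mu * (g[2] + g[3])
    # solid outward normal = -(fluid outward normal)
    tx <- -(sxx * e$nx + sxy * e$ny)
    ty <- -(sxy * e$nx + syy * e$ny)
    half <- e$len / 2
    f[e$a, ] <- f[e$a, ] + half * c(tx, ty)
    f[e$b, ] <- f[e$b, ] + half * c(tx, ty)
  }
  f
}

# out-of-balance (interface) residual norm of the solid for a candidate
# displacement, with the fluid force held fixed: the line-search objective
solid_oob_norm <- function(solid, u, u_pred, minv, f_ext) {
  fint <- solid_internal_force(solid, u)
  if (is.null(fint)) return(Inf)
  acc <- (u - u_pred) * minv
  R <- cbind(solid$mass * acc[, 1], solid$mass * acc[, 2]) + fint - f_ext
  cl <- solid$mesh$node_sets$outside
  R[cl, ] <- 0
  sqrt(sum(R^2))
}

# golden-section search for s in [0,1] minimising fn(s); <= max_eval calls
golden_search <- function(fn, max_eval = 8) {
  phi <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  evals <- 2
  while (evals < max_eval) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - phi * (b - a); f1 <- fn(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + phi * (b - a); f2 <- fn(x2) }
    evals <- evals + 1
  }
  if (f1 <= f2) x1 else x2
}

#' One strongly coupled FSI time step
#'
#' Advances the coupled system by one time step with partitioned
#' Newton-Raphson iterations: fluid solve on the current ALE mesh with the
#' interface velocity of the solid, traction transfer to the solid, implicit
#' Newmark solid solve, optional golden-section line search on the interface
#' displacement update (minimising the out-of-balance force), ALE mesh
#' update, until the normalised interface-displacement change drops below
#' `cfg$epsilon`. The interface solid mass augments the pressure operator
#' diagonal (added-mass stabilisation) when `cfg$added_mass` is TRUE.
#'
#' @param fluid a `fluid_state` (its mesh is the current configuration)
#' @param solid a `solid_state` at time t^n
#' @param cfg an [fsi_coupling_config()]
#' @param bc fluid boundary conditions (inlet pressure etc.)
#' @param geo geometry list from [fsi_channel_geometry()] (for the interface
#'   map and reference mesh)
#' @param cache mesh-motion factorisation (from [mesh_motion_cache()])
#' @return list `fluid`, `solid`, `iterations`, `line_search_s`
#' @export
couple_step <- function(fluid, solid, cfg, bc, geo, cache = NULL) {
  dt <- cfg$dt
  map <- geo$map
  ref_mesh <- geo$fluid_ref
  if (is.null(ref_mesh)) ref_mesh <- fluid$mesh
  if (is.null(cache)) cache <- mesh_motion_cache(ref_mesh)
  n_s <- nrow(solid$mesh$nodes)
  gamma <- cfg$newmark_gamma; beta <- cfg$newmark_beta
  u_pred <- solid$u + dt * solid$v + dt^2 * (0.5 - beta) * solid$a
  minv <- 1 / (beta * dt^2)
  # displacement cap standing in for contact: keep the tip gap open
  max_uy <- if (!is.null(geo$height_m) && !is.null(geo$flap_tip))
    (1 - cfg$min_gap_frac) * geo$height_m - geo$flap_tip else Inf
  u_iter <- solid$u
  v_iter <- solid$v
  s_used <- NA_real_
  s <- 1
  du_prev <- NULL
  x_n <- fluid$mesh$nodes
  cur_mesh <- fluid$mesh
  cur_umesh <- fluid$u_mesh
  fluid_try <- fluid
  solid_new <- solid
  for (i in seq_len(cfg$max_newton_iters)) {
    # fluid solve on the current interface configuration
    lf <- cur_mesh$node_sets$leaflets
    lf_vel <- matrix(0, length(lf), 2)
    # "mesh": geometrically consistent wall velocity du/dt (the velocity the
    # moving mesh actually sweeps; mismatched BC and mesh velocities inject
    # spurious interface volume flux proportional to the acceleration);
    # "end" uses the Newmark end-of-step velocity, "midpoint" their average
    v_bc <- switch(cfg$interface_velocity,
                   mesh = (u_iter - solid$u) / dt,
                   end = v_iter,
                   midpoint = (v_iter + solid$v) / 2)
    lf_vel[match(map$fluid, lf), ] <- v_bc[map$solid, ]
    bc_i <- bc
    bc_i$leaflet_velocity <- lf_vel
    ops <- fluid_operators(cur_mesh, pressure_operator = cfg$pressure_operator)
    amd <- NULL
    if (isTRUE(cfg$added_mass)) {
      # interface solid inertia added to the pressure operator diagonal:
      # scales with the fluid-to-solid nodal mass ratio, damping the
      # pressure response to interface motion that otherwise makes the
      # partitioned iteration diverge at density ratio ~ 1
      amd <- numeric(nrow(cur_mesh$nodes))
      amd[map$fluid] <- cfg$added_mass_scale * fluid$rho *
        ops$ML[map$fluid] / solid$mass[map$solid]
    }
    fluid_try <- fluid
    fluid_try$mesh <- cur_mesh
    fluid_try$u_mesh <- cur_umesh
    fluid_try <- fluid_step(fluid_try, dt, bc_i, ops,
                            max_subiters = cfg$max_pressure_subiters,
                            added_mass_diag = amd,
                            pressure_form = cfg$pressure_form)
    ff <- fluid_interface_force(fluid_try, ops)
    f_ext <- matrix(0, n_s, 2)
    f_ext[map$solid, ] <- ff[map$fluid, ]
    if (cfg$solid_damping > 0)  # mass-proportional (Rayleigh) damping
      f_ext <- f_ext - cfg$solid_damping *
        cbind(solid$mass * v_iter[, 1], solid$mass * v_iter[, 2])
    solid_new <- newmark_solid_step(solid, f_ext, dt, gamma, beta)
    du <- solid_new$u - u_iter
    # relaxation of the interface update along du: Aitken's delta-squared
    # secant step (a one-dimensional minimisation of the interface
    # out-of-balance along the update direction, without fluid re-solves)
    if (isTRUE(cfg$line_search) && i > 1) {
      dr <- du - du_prev
      denom <- sum(dr^2)
      if (denom > 0) s <- max(1e-3, min(1, -s * sum(du_prev * dr) / denom))
    } else s <- if (isTRUE(cfg$line_search)) 0.5 else 1
    du_prev <- du
    s_used <- s
    u_new <- u_iter + s * du
    if (is.finite(max_uy)) u_new[, 2] <- pmin(u_new[, 2], max_uy)
    rel <- sqrt(sum((u_new - u_iter)^2)) / max(sqrt(sum(u_new^2)), 1e-14)
    u_iter <- u_new
    # Newmark-consistent velocity/acceleration of the current iterate
    a_iter <- (u_iter - u_pred) * minv
    v_iter <- solid$v + dt * ((1 - gamma) * solid$a + gamma * a_iter)
    # move the fluid mesh to the new interface position
    if_disp <- matrix(0, length(ref_mesh$node_sets$leaflets), 2)
    if_disp[match(map$fluid, ref_mesh$node_sets$leaflets), ] <- u_iter[map$solid, ]
    mv <- move_mesh(ref_mesh, if_disp, cache)
    cur_mesh$nodes <- mv$nodes
    cur_mesh <- refresh_edges(cur_mesh)
    cur_umesh <- (mv$nodes - x_n) / dt
    if (rel < cfg$epsilon) break
    if (i == cfg$max_newton_iters)
      stop("FSI coupling did not converge in ", cfg$max_newton_iters,
           " iterations (last relative change ", signif(rel, 3), ")")
  }
  fluid_try$mesh <- cur_mesh
  fluid_try$u_mesh <- cur_umesh
  solid_new$u <- u_iter
  solid_new$a <- (u_iter - u_pred) * minv
  solid_new$v <- solid$v + dt * ((1 - gamma) * solid$a + gamma * solid_new$a)
  list(fluid = fluid_try, solid = solid_new, iterations = i,
       line_search_s = s_used)
}
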