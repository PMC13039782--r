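#' Leaflet material specification
#'
#' Nearly incompressible Neo-Hookean material, optionally two-phase: a
#' calcified element subset with a (much) higher shear modulus. The plane
#' Lame parameter is `lambda = 2 G nu / (1 - 2 nu)`. Calcified elements
#' share the tissue density (the deposits and the surrounding material have
#' similar densities on the bench as well).
#'
#' @param shear_modulus tissue shear modulus G, Pa
#' @param poisson_ratio tissue Poisson ratio, in (0, 0.5)
#' @param density mass density, kg/m^3
#' @param calcified_mask logical per-element vector (NULL = homogeneous)
#' @param shear_modulus_calcified G of the calcified elements, Pa
#' @param poisson_ratio_calcified Poisson ratio of the calcified elements
#'   (see [poisson_for_bulk_match()] for the bulk-modulus-matching choice)
#' @return a `material_spec`
#' @export
material_spec <- function(shear_modulus, poisson_ratio = 0.45, density = 1000,
                          calcified_mask = NULL,
                          shear_modulus_calcified = NULL,
                          poisson_ratio_calcified = NULL) {
  if (!(shear_modulus > 0)) stop("shear modulus must be > 0")
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5))
    stop("Poisson ratio must lie in (0, 0.5)")
  structure(list(shear_modulus = shear_modulus, poisson_ratio = poisson_ratio,
                 density = density, calcified_mask = calcified_mask,
                 shear_modulus_calcified = shear_modulus_calcified,
                 poisson_ratio_calcified = poisson_ratio_calcified),
            class = "material_spec")
}

# per-element (G, lambda) honouring the calcified mask
material_fields <- function(mat, n_el) {
  G <- rep(mat$shear_modulus, n_el)
  nu <- rep(mat$poisson_ratio, n_el)
  if (!is.null(mat$calcified_mask) && any(mat$calcified_mask)) {
    msk <- rep_len(mat$calcified_mask, n_el)
    G[msk] <- mat$shear_modulus_calcified
    nu[msk] <- if (is.null(mat$poisson_ratio_calcified))
      mat$poisson_ratio else mat$poisson_ratio_calcified
  }
  list(G = G, lambda = 2 * G * nu / (1 - 2 * nu))
}

#' Solid (leaflet) state
#'
#' Lagrangian displacement, velocity and acceleration fields on the solid
#' mesh, with precomputed reference geometry and lumped mass.
#'
#' @param mesh a `mesh2d` with node set `outside` (clamped boundary)
#' @param material a [material_spec()]
#' @return a `solid_state`
#' @export
solid_state <- function(mesh, material) {
  n <- nrow(mesh$nodes)
  geom0 <- tri_geometry(mesh$nodes, mesh$tri)
  ml <- fem_mass_lumped(mesh$nodes, mesh$tri, geom0, coef = material$density)
  mf <- material_fields(material, nrow(mesh$tri))
  structure(list(mesh = mesh, material = material, geom0 = geom0,
                 mass = ml, G_el = mf$G, lambda_el = mf$lambda,
                 u = matrix(0, n, 2), v = matrix(0, n, 2),
                 a = matrix(0, n, 2)),
            class = "solid_state")
}

# per-element nodal displacements (m x 6: u1x u2x u3x u1y u2y u3y)
element_disp <- function(tri, u) {
  cbind(u[tri[, 1], 1], u[tri[, 2], 1], u[tri[, 3], 1],
        u[tri[, 1], 2], u[tri[, 2], 2], u[tri[, 3], 2])
}

# Neo-Hookean plane-strain element forces from per-element displacements.
# Returns m x 6 nodal internal forces (same layout as element_disp) and,
# if energy = TRUE, the per-element strain energy.
nh_element_forces <- function(geom0, G, lambda, ue, energy = FALSE) {
  gx <- geom0$gx; gy <- geom0$gy; A <- geom0$area
  F11 <- 1 + gx[, 1] * ue[, 1] + gx[, 2] * ue[, 2] + gx[, 3] * ue[, 3]
  F12 <-     gy[, 1] * ue[, 1] + gy[, 2] * ue[, 2] + gy[, 3] * ue[, 3]
  F21 <-     gx[, 1] * ue[, 4] + gx[, 2] * ue[, 5] + gx[, 3] * ue[, 6]
  F22 <- 1 + gy[, 1] * ue[, 4] + gy[, 2] * ue[, 5] + gy[, 3] * ue[, 6]
  J <- F11 * F22 - F12 * F21
  if (any(J <= 0)) return(NULL)  # element inversion: caller must cut the step
  lnJ <- log(J)
  # first Piola-Kirchhoff stress P = G (F - F^-T) + lambda lnJ F^-T
  iT11 <-  F22 / J; iT12 <- -F21 / J
  iT21 <- -F12 / J; iT22 <-  F11 / J
  cf <- lambda * lnJ - G
  P11 <- G * F11 + cf * iT11
  P12 <- G * F12 + cf * iT12
  P21 <- G * F21 + cf * iT21
  P22 <- G * F22 + cf * iT22
  f <- cbind(A * (P11 * gx[, 1] + P12 * gy[, 1]),
             A * (P11 * gx[, 2] + P12 * gy[, 2]),
             A * (P11 * gx[, 3] + P12 * gy[, 3]),
             A * (P21 * gx[, 1] + P22 * gy[, 1]),
             A * (P21 * gx[, 2] + P22 * gy[, 2]),
             A * (P21 * gx[, 3] + P22 * gy[, 3]))
  if (energy) {
    I1 <- F11^2 + F12^2 + F21^2 + F22^2
    W <- A * (G / 2 * (I1 - 2 - 2 * lnJ) + lambda / 2 * lnJ^2)
    attr(f, "energy") <- sum(W)
  }
  f
}

# global internal force vector (n x 2) for a displacement field
solid_internal_force <- function(solid, u) {
  tri <- solid$mesh$tri
  fe <- nh_element_forces(solid$geom0, solid$G_el, solid$lambda_el,
                          element_disp(tri, u))
  if (is.null(fe)) return(NULL)
  n <- nrow(solid$mesh$nodes)
  fx <- tapply_add(tri[, 1], fe[, 1], n) + tapply_add(tri[, 2], fe[, 2], n) +
    tapply_add(tri[, 3], fe[, 3], n)
  fy <- tapply_add(tri[, 1], fe[, 4], n) + tapply_add(tri[, 2], fe[, 5], n) +
    tapply_add(tri[, 3], fe[, 6], n)
  cbind(fx, fy)
}

#' Total mechanical energy of the solid
#'
#' Kinetic energy (lumped mass) plus Neo-Hookean strain energy; used for the
#' Newmark numerical-damping diagnostics.
#'
#' @param solid a `solid_state`
#' @return energy in J (per unit depth)
#' @export
solid_energy <- function(solid) {
  fe <- nh_element_forces(solid$geom0, solid$G_el, solid$lambda_el,
                          element_disp(solid$mesh$tri, solid$u), energy = TRUE)
  w <- if (is.null(fe)) NA_real_ else attr(fe, "energy")
  0.5 * sum(solid$mass * (solid$v[, 1]^2 + solid$v[, 2]^2)) + w
}

# consistent tangent by per-element finite differences (6 extra vectorised
# force evaluations); returns a sparse 2n x 2n matrix, dof order (x..., y...)
solid_tangent <- function(solid, u, h = NULL) {
  tri <- solid$mesh$tri
  n <- nrow(solid$mesh$nodes)
  ue <- element_disp(tri, u)
  f0 <- nh_element_forces(solid$geom0, solid$G_el, solid$lambda_el, ue)
  if (is.null(f0)) return(NULL)
  if (is.null(h)) h <- 1e-5 * (sqrt(mean(solid$geom0$area)) + max(abs(ue)))
  gdof <- cbind(tri, tri + n)  # global dof of local columns 1..6
  ii <- jj <- xx <- vector("list", 6)
  for (ld in 1:6) {
    up <- ue
    up[, ld] <- up[, ld] + h
    fp <- nh_element_forces(solid$geom0, solid$G_el, solid$lambda_el, up)
    if (is.null(fp)) return(NULL)
    kcol <- (fp - f0) / h  # m x 6: dforce/d(dof ld)
    ii[[ld]] <- as.vector(gdof)
    jj[[ld]] <- rep(gdof[, ld], 6)
    xx[[ld]] <- as.vector(kcol)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * n, 2 * n))
}

#' One implicit Newmark step of the Neo-Hookean solid
#'
#' Solves the momentum balance `div(sigma) + rho f = rho d2u/dt2` for one
#' time step with the Newmark scheme (gamma, beta) and a Newton loop on the
#' displacement. The `outside` node set is clamped (zero displacement).
#' With gamma > 1/2 the integrator is numerically dissipative, which damps
#' unresolved high-frequency structural modes.
#'
#' @param solid a `solid_state`
#' @param f_ext external nodal force (n x 2), e.g. the fluid traction
#' @param dt time step, s
#' @param gamma,beta Newmark parameters (defaults 0.6, 0.4)
#' @param tol Newton tolerance on the residual norm, relative to the force
#'   scale
#' @param max_iters Newton iteration cap
#' @return the updated `solid_state` (iteration count in attribute `iters`)
#' @export
newmark_solid_step <- function(solid, f_ext = NULL, dt, gamma = 0.6,
                               beta = 0.4, tol = 1e-9, max_iters = 50L) {
  n <- nrow(solid$mesh$nodes)
  if (is.null(f_ext)) f_ext <- matrix(0, n, 2)
  clamp <- solid$mesh$node_sets$outside
  cl2 <- c(clamp, clamp + n)
  u_pred <- solid$u + dt * solid$v + dt^2 * (0.5 - beta) * solid$a
  minv <- 1 / (beta * dt^2)
  u <- solid$u
  force_scale <- max(sqrt(sum(f_ext^2)), max(solid$mass) * 9.81, 1e-12)
  hist <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    fint <- solid_internal_force(solid, u)
    if (is.null(fint)) stop("solid element inversion during Newton step")
    acc <- (u - u_pred) * minv
    R <- cbind(solid$mass * acc[, 1], solid$mass * acc[, 2]) + fint - f_ext
    Rv <- c(R[, 1], R[, 2]); Rv[cl2] <- 0
    rn <- sqrt(sum(Rv^2))
    hist <- c(hist, rn)
    if (rn <= tol * force_scale) { converged <- TRUE; break }
    # accept a stalled residual at the finite-difference-tangent noise
    # floor: tiny relative to the load, it cannot be reduced further
    if (length(hist) > 5 && rn < 1e-5 * force_scale &&
        rn > 0.95 * hist[length(hist) - 5]) { converged <- TRUE; break }
    Kt <- solid_tangent(solid, u)
    if (is.null(Kt)) stop("solid element inversion during tangent assembly")
    Keff <- Kt + Matrix::Diagonal(2 * n, x = rep(solid$mass * minv, 2))
    sys <- apply_dirichlet(Keff, -Rv, cl2, 0)
    du <- as.numeric(Matrix::solve(sys$A, sys$b))
    # backtracking on residual increase (robustness at large load steps)
    step <- 1
    repeat {
      u_try <- u + step * cbind(du[1:n], du[n + 1:n])
      fint_try <- solid_internal_force(solid, u_try)
      if (!is.null(fint_try)) {
        acc_t <- (u_try - u_pred) * minv
        Rt <- cbind(solid$mass * acc_t[, 1], solid$mass * acc_t[, 2]) +
          fint_try - f_ext
        Rtv <- c(Rt[, 1], Rt[, 2]); Rtv[cl2] <- 0
        if (sqrt(sum(Rtv^2)) < rn || step < 0.06) break
      }
      step <- step / 2
      if (step < 1e-3) break
    }
    u <- u + step * cbind(du[1:n], du[n + 1:n])
  }
  if (!converged) {
    stop("solid Newton loop did not converge; residual history: ",
         paste(signif(hist, 3), collapse = " "))
  }
  a_new <- (u - u_pred) * minv
  v_new <- solid$v + dt * ((1 - gamma) * solid$a + gamma * a_new)
  solid$u <- u; solid$v <- v_new; solid$a <- a_new
  attr(solid, "iters") <- it
  solid
}

#' Static solve of the solid under a fixed load
#'
#' Newton solve of `f_int(u) = f_ext` with the clamp applied, using load
#' stepping for robustness; used by the bending benchmarks.
#'
#' @param solid a `solid_state`
#' @param f_ext external nodal force (n x 2)
#' @param n_load_steps number of proportional load increments
#' @return the `solid_state` with the equilibrium displacement
#' @export
solid_static_solve <- function(solid, f_ext, n_load_steps = 4L) {
  n <- nrow(solid$mesh$nodes)
  clamp <- solid$mesh$node_sets$outside
  cl2 <- c(clamp, clamp + n)
  u <- solid$u
  for (ls in seq_len(n_load_steps)) {
    f <- f_ext * (ls / n_load_steps)
    for (it in 1:60) {
      fint <- solid_internal_force(solid, u)
      if (is.null(fint)) stop("element inversion in static solve")
      R <- fint - f
      Rv <- c(R[, 1], R[, 2]); Rv[cl2] <- 0
      if (sqrt(sum(Rv^2)) <= 1e-9 * max(sqrt(sum(f^2)), 1e-12)) break
      Kt <- solid_tangent(solid, u)
      sys <- apply_dirichlet(Kt, -Rv, cl2, 0)
      du <- as.numeric(Matrix::solve(sys$A, sys$b))
      s <- 1
      repeat {
        u_try <- u + s * cbind(du[1:n], du[n + 1:n])
        if (!is.null(solid_internal_force(solid, u_try)) || s < 1e-3) break
        s <- s / 2
      }
      u <- u + s * cbind(du[1:n], du[n + 1:n])
    }
  }
  solid$u <- u
  solid
}

#' Newmark discrete energy
#'
#' The functional that the Newmark scheme with gamma >= 1/2 and
#' beta >= gamma/2 dissipates monotonically in free vibration: the physical
#' energy (kinetic + strain) augmented by
#' `(dt^2/4) (2 beta - gamma) a' M a`. The plain physical energy may show
#' tiny step-to-step oscillations that this augmented form absorbs.
#'
#' @param solid a `solid_state`
#' @param dt time step used to advance the state, s
#' @param gamma,beta Newmark parameters
#' @return energy in J (per unit depth)
#' @export
newmark_energy <- function(solid, dt, gamma = 0.6, beta = 0.4) {
  solid_energy(solid) + dt^2 / 4 * (2 * beta - gamma) *
    sum(solid$mass * (solid$a[, 1]^2 + solid$a[, 2]^2))
}

#' Initialise the acceleration consistently with the current state
#'
#' Sets `a = (f_ext - f_int(u)) / M` on unclamped nodes so a run does not
#' start from an inconsistent (zero) acceleration.
#'
#' @param solid a `solid_state`
#' @param f_ext external nodal force (n x 2), default zero
#' @return the `solid_state` with consistent `a`
#' @export
solid_init_acceleration <- function(solid, f_ext = NULL) {
  n <- nrow(solid$mesh$nodes)
  if (is.null(f_ext)) f_ext <- matrix(0, n, 2)
  fint <- solid_internal_force(solid, solid$u)
  solid$a <- (f_ext - fint) / solid$mass
  solid$a[solid$mesh$node_sets$outside, ] <- 0
  solid
}
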