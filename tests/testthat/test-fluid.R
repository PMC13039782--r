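make_channel <- function(nx = 20, ny = 6, L = 0.05, H = 0.01) {
  fsi_channel_geometry(length_m = L, height_m = H, flap_x = NULL,
                       nx = nx, ny = ny)$fluid
}

test_that("predictor reproduces a direct solve of the assembled system", {
  mesh <- make_channel()
  ops <- valveverify:::fluid_operators(mesh)
  st <- fluid_state(mesh, rho = 1000, mu = 0.01)
  set.seed(3)
  n <- nrow(mesh$nodes)
  st$u <- matrix(rnorm(2 * n, 0, 0.01), n, 2)
  st$u_prev <- matrix(rnorm(2 * n, 0, 0.01), n, 2)
  st$p <- rnorm(n, 0, 5)
  dt <- 1e-3
  u_star <- predictor_velocity(st, dt, list(conv_stab = FALSE), ops)
  # independent oracle: assemble the same weak form directly and solve
  uL <- 2 * st$u - st$u_prev
  A <- ops$M + (2 / 3) * dt *
    (valveverify:::fem_stiffness(mesh$nodes, mesh$tri, ops$geom, coef = st$nu) +
     valveverify:::fem_convection(mesh$nodes, mesh$tri, uL, ops$geom))
  rhs <- as.matrix(ops$M %*% (2 * st$u - 0.5 * st$u_prev))
  rhs[, 1] <- rhs[, 1] - (dt / st$rho) * as.numeric(ops$Gx %*% st$p)
  rhs[, 2] <- rhs[, 2] - (dt / st$rho) * as.numeric(ops$Gy %*% st$p)
  bidx <- ops$vel_dirichlet
  s1 <- valveverify:::apply_dirichlet(A, rhs[, 1], bidx, 0)
  s2 <- valveverify:::apply_dirichlet(s1$A, rhs[, 2], bidx, 0)
  ref <- cbind(as.numeric(Matrix::solve(s2$A, s1$b)),
               as.numeric(Matrix::solve(s2$A, s2$b)))
  expect_equal(max(abs(u_star - ref)) / max(abs(ref)), 0, tolerance = 1e-10)
})

test_that("a uniform field passes through the full fractional step unchanged", {
  mesh <- make_channel()
  # let every wall carry the uniform velocity so no Dirichlet conflict exists
  mesh$node_sets$leaflets <- mesh$node_sets$inside
  mesh$node_sets$inside <- integer(0)
  ops <- valveverify:::fluid_operators(mesh)
  c0 <- c(0.4, 0)
  st <- fluid_state(mesh)
  n <- nrow(mesh$nodes)
  st$u <- st$u_prev <- matrix(rep(c0, each = n), n, 2)
  lfv <- matrix(rep(c0, each = length(mesh$node_sets$leaflets)),
                ncol = 2)
  bc <- list(inlet_p = 0, leaflet_velocity = lfv, backflow_beta = 0,
             conv_stab = FALSE)
  u_star <- predictor_velocity(st, 1e-3, bc, ops)
  expect_equal(u_star[, 1], rep(1.5 * c0[1], n), tolerance = 1e-10)
  st2 <- fluid_step(st, 1e-3, bc, ops)
  expect_equal(st2$u[, 1], rep(c0[1], n), tolerance = 1e-9)
  expect_equal(st2$p, st$p, tolerance = 1e-8)
})

test_that("predictor errors without any Dirichlet anchor and decays at large viscosity", {
  mesh <- make_channel()
  free_mesh <- mesh
  free_mesh$node_sets$inside <- integer(0)
  free_mesh$node_sets$leaflets <- integer(0)
  ops_free <- valveverify:::fluid_operators(free_mesh)
  st <- fluid_state(free_mesh)
  expect_error(predictor_velocity(st, 1e-3, list(), ops_free), "Dirichlet")
  # nu -> large with zero forcing and zero boundary values: u* -> 0
  ops <- valveverify:::fluid_operators(mesh)
  st2 <- fluid_state(mesh, mu = 1e6)
  set.seed(1)
  st2$u <- st2$u_prev <- matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.1),
                                nrow(mesh$nodes), 2)
  u_star <- predictor_velocity(st2, 1e-3, list(conv_stab = FALSE), ops)
  expect_lt(max(abs(u_star)), 1e-4 * max(abs(st2$u)))
})

test_that("pressure solve matches a direct solve and gives linear channel profiles", {
  mesh <- make_channel()
  ops <- valveverify:::fluid_operators(mesh)
  st <- fluid_state(mesh)
  dt <- 1e-3
  # zero divergence and unchanged boundary values leave the pressure alone
  p0 <- pressure_poisson(matrix(0, nrow(mesh$nodes), 2), st, dt,
                         list(inlet_p = 0), ops)
  expect_equal(p0, st$p, tolerance = 1e-12)
  # 40 mmHg at the inlet, 0 at the outlet: linear profile along the channel
  p1 <- pressure_poisson(matrix(0, nrow(mesh$nodes), 2), st, dt,
                         list(inlet_p = 5332.9), ops)
  x <- mesh$nodes[, 1]
  expect_equal(p1, 5332.9 * (1 - x / 0.05), tolerance = 1e-6 * 5332.9)
  # manufactured divergence: solver output equals an independent direct solve
  set.seed(7)
  u_star <- matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.01), nrow(mesh$nodes), 2)
  p2 <- pressure_poisson(u_star, st, dt, list(inlet_p = 100), ops)
  ut <- u_star; ut[ops$vel_dirichlet, ] <- 0
  r <- (st$rho / dt) * as.numeric(ops$Gx %*% ut[, 1] + ops$Gy %*% ut[, 2])
  Ff <- ops$p_free; Fd <- ops$p_dirichlet
  pbc <- numeric(nrow(mesh$nodes)); pbc[mesh$node_sets$inflow] <- 100
  rhs <- r[Ff] - as.numeric(ops$L[Ff, Fd] %*% pbc[Fd])
  ref <- numeric(nrow(mesh$nodes)); ref[Fd] <- pbc[Fd]
  ref[Ff] <- as.numeric(Matrix::solve(ops$L[Ff, Ff], rhs))
  expect_equal(max(abs(p2 - ref)) / max(abs(ref)), 0, tolerance = 1e-10)
})

test_that("velocity correction is exact: 2/3 scaling and discrete divergence removal", {
  mesh <- make_channel()
  ops <- valveverify:::fluid_operators(mesh)
  st <- fluid_state(mesh)
  set.seed(11)
  n <- nrow(mesh$nodes)
  u_star <- matrix(rnorm(2 * n, 0, 0.01), n, 2)
  # equal pressures: u = (2/3) u* on free nodes
  u1 <- correct_velocity(u_star, st$p, st$p, st, 1e-3, list(), ops)
  free <- setdiff(seq_len(n), ops$vel_dirichlet)
  expect_equal(u1[free, ], (2 / 3) * u_star[free, ], tolerance = 1e-12)
  # after the full projection the discrete divergence vanishes
  st$u <- matrix(rnorm(2 * n, 0, 0.01), n, 2)
  st$u_prev <- st$u
  st2 <- fluid_step(st, 1e-3, list(inlet_p = 50, conv_stab = FALSE), ops)
  expect_lt(attr(st2, "div_norm"), 1e-8)
})

test_that("Smagorinsky eddy viscosity matches closed forms and is non-negative", {
  expect_equal(smagorinsky_nu_t(c(0, 0, 0, 0), 0.18, 1e-3), 0)
  g <- 150  # pure shear du/dy
  expect_equal(smagorinsky_nu_t(c(0, g, 0, 0), 0.18, 2e-3),
               (0.18 * 2e-3)^2 * g, tolerance = 1e-12)
  set.seed(2)
  grads <- matrix(rnorm(400), 100, 4)
  expect_true(all(smagorinsky_nu_t(grads, 0.18, 1e-3) >= 0))
})

test_that("Pope criterion reproduces the reference configuration and its limits", {
  r <- pope_ratio(1.5, delta = 0.5, length_scale = 13)
  expect_equal(round(100 * r), 12)
  expect_lte(r, 0.2)  # at least 80% of the energy resolved
  expect_equal(pope_ratio(1.5, 0, 13), 0)
  # same answer in any consistent unit
  expect_equal(pope_ratio(1.5, 0.5e-3, 13e-3), r, tolerance = 1e-12)
})
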