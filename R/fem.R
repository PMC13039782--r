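#' Linear-triangle finite element utilities
#'
#' Internal P1 (linear triangle) machinery shared by the fluid and solid
#' solvers: element geometry, mass/stiffness/convection assembly, weak
#' gradient operators and boundary-edge handling. All quantities are SI.
#'
#' @name fem
#' @keywords internal
NULL

# areas and shape-function gradients of all triangles
# returns list(area, gx, gy): gx[e, a] = d phi_a / dx on element e
tri_geometry <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)  # 2A, signed
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  list(area = a2 / 2, gx = gx, gy = gy)
}

# stiffness matrix with an element-wise coefficient:
# K[a,b] = sum_e coef_e * A_e * (grad phi_a . grad phi_b)
fem_stiffness <- function(nodes, tri, geom = tri_geometry(nodes, tri), coef = 1) {
  m <- nrow(tri); n <- nrow(nodes)
  coef <- rep_len(coef, m)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- coef * geom$area *
      (geom$gx[, a] * geom$gx[, b] + geom$gy[, a] * geom$gy[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# consistent mass matrix, optional element-wise density
fem_mass <- function(nodes, tri, geom = tri_geometry(nodes, tri), coef = 1) {
  m <- nrow(tri); n <- nrow(nodes)
  coef <- rep_len(coef, m)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- coef * geom$area / ifelse(a == b, 6, 12)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# lumped (row-sum) mass vector
fem_mass_lumped <- function(nodes, tri, geom = tri_geometry(nodes, tri), coef = 1) {
  n <- nrow(nodes)
  coef <- rep_len(coef, nrow(tri))
  v <- numeric(n)
  for (a in 1:3) {
    inc <- coef * geom$area / 3
    v <- v + unname(tapply_add(tri[, a], inc, n))
  }
  v
}

# fast scatter-add: sum values x into bins idx of a length-n vector
tapply_add <- function(idx, x, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# convection matrix for a nodal velocity field w (n x 2), element-mean w:
# C[a,b] = sum_e (A_e / 3) * (wbar . grad phi_b)
fem_convection <- function(nodes, tri, w, geom = tri_geometry(nodes, tri)) {
  n <- nrow(nodes)
  wx <- (w[tri[, 1], 1] + w[tri[, 2], 1] + w[tri[, 3], 1]) / 3
  wy <- (w[tri[, 1], 2] + w[tri[, 2], 2] + w[tri[, 3], 2]) / 3
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- geom$area / 3 * (wx * geom$gx[, b] + wy * geom$gy[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# weak first-derivative operators: (Gx p)_a = integral phi_a dp/dx
fem_grad_ops <- function(nodes, tri, geom = tri_geometry(nodes, tri)) {
  n <- nrow(nodes)
  make <- function(g) {
    ii <- jj <- xx <- vector("list", 9)
    k <- 0
    for (a in 1:3) for (b in 1:3) {
      k <- k + 1
      ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
      xx[[k]] <- geom$area / 3 * g[, b]
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(n, n))
  }
  list(Gx = make(geom$gx), Gy = make(geom$gy))
}

# impose Dirichlet conditions on A x = b by row/column elimination
apply_dirichlet <- function(A, b, idx, vals) {
  if (length(idx) == 0) return(list(A = A, b = b))
  vals <- rep_len(vals, length(idx))
  xfix <- numeric(nrow(A)); xfix[idx] <- vals
  b <- b - as.numeric(A %*% xfix)
  A[idx, ] <- 0; A[, idx] <- 0
  A[cbind(idx, idx)] <- 1
  b[idx] <- vals
  list(A = A, b = b)
}

# element-constant velocity gradient of a nodal field u (n x 2):
# returns matrix m x 4 with columns du_x/dx, du_x/dy, du_y/dx, du_y/dy
element_velocity_gradient <- function(tri, geom, u) {
  gcomp <- function(comp, g) {
    g[, 1] * u[tri[, 1], comp] + g[, 2] * u[tri[, 2], comp] +
      g[, 3] * u[tri[, 3], comp]
  }
  cbind(dudx = gcomp(1, geom$gx), dudy = gcomp(1, geom$gy),
        dvdx = gcomp(2, geom$gx), dvdy = gcomp(2, geom$gy))
}

# signed flux of u (n x 2) through a set of boundary edges
# edges: data.frame(a, b, nx, ny) with outward unit normal and node indices
edge_flux <- function(nodes, edges, u) {
  if (nrow(edges) == 0) return(0)
  len <- sqrt((nodes[edges$b, 1] - nodes[edges$a, 1])^2 +
              (nodes[edges$b, 2] - nodes[edges$a, 2])^2)
  una <- u[edges$a, 1] * edges$nx + u[edges$a, 2] * edges$ny
  unb <- u[edges$b, 1] * edges$nx + u[edges$b, 2] * edges$ny
  sum(len * (una + unb) / 2)
}

# row-wise max absolute value of a sparse matrix
apply_abs_rowmax <- function(A) {
  At <- as(abs(A), "TsparseMatrix")
  out <- numeric(nrow(A))
  if (length(At@x)) {
    s <- rowsum(pmax(At@x, 0), At@i + 1L)  # upper bound; exact max not needed
    out[as.integer(rownames(s))] <- s
  }
  out
}

# plane-strain linear elasticity stiffness (CST); dof order (x..., y...)
fem_elasticity_stiffness <- function(nodes, tri, geom = tri_geometry(nodes, tri),
                                     E = 1, nu = 0.3) {
  fem_elasticity_stiffness_weighted(nodes, tri, geom, weight = 1, E = E, nu = nu)
}

# elasticity stiffness with a per-element weight on the moduli
fem_elasticity_stiffness_weighted <- function(nodes, tri,
                                              geom = tri_geometry(nodes, tri),
                                              weight = 1, E = 1, nu = 0.3) {
  n <- nrow(nodes)
  weight <- rep_len(weight, nrow(tri))
  lam <- weight * E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- weight * E / (2 * (1 + nu))
  gx <- geom$gx; gy <- geom$gy; A <- geom$area
  ii <- jj <- xx <- vector("list", 36)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    ga_x <- gx[, a]; ga_y <- gy[, a]
    gb_x <- gx[, b]; gb_y <- gy[, b]
    kxx <- A * ((lam + 2 * mu) * ga_x * gb_x + mu * ga_y * gb_y)
    kxy <- A * (lam * ga_x * gb_y + mu * ga_y * gb_x)
    kyx <- A * (lam * ga_y * gb_x + mu * ga_x * gb_y)
    kyy <- A * ((lam + 2 * mu) * ga_y * gb_y + mu * ga_x * gb_x)
    for (blk in 1:4) {
      k <- k + 1
      ii[[k]] <- tri[, a] + if (blk > 2) n else 0L
      jj[[k]] <- tri[, b] + if (blk %% 2 == 0) n else 0L
      xx[[k]] <- switch(blk, kxx, kxy, kyx, kyy)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * n, 2 * n))
}
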