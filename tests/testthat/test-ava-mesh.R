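test_that("projection is orthogonal, idempotent, and distance-preserving under rotation", {
  cl <- generate_leaflet_cloud(0.5, seed = 1)
  p2 <- project_points(cl)
  # points already in the projection plane: projecting again is the identity
  # up to the in-plane rotation convention (checked via pairwise distances)
  emb <- cbind(p2 * 10, 0)  # back to mm in the plane
  p2b <- project_points(emb, axis = c(0, 0, 1))
  ii <- c(1, 77, 1234); jj <- c(5, 600, 4321)
  d_a <- sqrt(rowSums((p2[ii, ] - p2[jj, ])^2))
  d_b <- sqrt(rowSums((p2b[ii, ] - p2b[jj, ])^2))
  expect_equal(d_b, d_a, tolerance = 1e-12)
  # rotating cloud and axis together preserves pairwise in-plane distances
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  clr <- rotate_cloud(cl, R)
  p2r <- project_points(clr)
  i <- c(1, 50, 400); j <- c(2, 90, 700)
  d0 <- sqrt(rowSums((p2[i, ] - p2[j, ])^2))
  d1 <- sqrt(rowSums((p2r[i, ] - p2r[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-10)
  expect_error(project_points(cl, axis = c(0, 0, 0)), "degenerate")
})

test_that("rasterisation uses half-open cells and marks occupied cells only", {
  cfg <- raster_config(16, physical_extent = 1.6)
  pts <- rbind(c(0, 0))
  g <- rasterize(pts, cfg)
  expect_equal(sum(g), 1)
  expect_true(all(dim(g) == 16))
  # empty-ish input: single point occupies exactly one cell regardless
  ring_t <- seq(0, 2 * pi, length.out = 4000)
  ring <- cbind(0.5 * cos(ring_t), 0.5 * sin(ring_t))
  g2 <- rasterize(ring, raster_config(150, physical_extent = 1.6))
  lab <- valveverify:::label_components_8(g2)
  expect_equal(max(lab), 1)  # connected ring at this resolution
  expect_warning(rasterize(rbind(c(0, 0), c(50, 50)), cfg), "clipped")
})

test_that("orifice area comes from the largest filled hole", {
  cfg <- raster_config(150, physical_extent = 4)
  # dense deterministic sampling so every covered raster cell is hit
  g0 <- seq(-1.9, 1.9, by = 0.01)
  grid <- as.matrix(expand.grid(x = g0, y = g0))
  rad <- sqrt(rowSums(grid^2))
  # solid disk: no hole
  g <- rasterize(grid[rad <= 1.5, ], cfg)
  expect_equal(orifice_area(g), 0)
  # annulus with circular hole r = 0.40 cm -> area pi * 0.16 = 0.503 cm^2
  ann <- grid[rad <= 1.9 & rad >= 0.4, ]
  g2 <- rasterize(ann, cfg)
  expect_equal(orifice_area(g2), pi * 0.16, tolerance = 0.08)
  # two holes: returns the largest only
  keep <- !(ann[, 1] > 0.8 & ann[, 1] < 1.1 & abs(ann[, 2]) < 0.12)
  g3 <- rasterize(ann[keep, ], cfg)
  expect_equal(orifice_area(g3), pi * 0.16, tolerance = 0.1)
})

test_that("resolution envelopes bracket the analytic circle area within 10%", {
  cl <- generate_leaflet_cloud(0.5, seed = 3, lobe = 0)
  res <- ava_with_resolution_bounds(cl, raster_config(150, physical_extent = 3))
  expect_true(res$lower <= res$upper)
  expect_equal(res$area, 0.5, tolerance = 0.05)
  expect_true(all(abs(res$by_resolution$area - 0.5) <= 0.1 * 0.5))
  # recovered area converges with resolution on the circle case (the cloud
  # must stay denser than the finest grid, hence the large point count)
  cl_dense <- generate_leaflet_cloud(0.5, n_points = 400000, seed = 3, lobe = 0)
  errs <- vapply(c(150, 300, 600), function(rs) {
    abs(ava_with_resolution_bounds(cl_dense,
      raster_config(rs, physical_extent = 3))$area - 0.5)
  }, numeric(1))
  expect_true(errs[3] <= errs[1] + 1e-9)
})

test_that("recovered AVA is invariant to rigid rotation and scales like s^2", {
  cl <- generate_leaflet_cloud(0.5, seed = 4, lobe = 0.25)
  cfg <- raster_config(150, physical_extent = 3)
  a0 <- ava_with_resolution_bounds(cl, cfg)$area
  R <- rbind(c(1, 0, 0), c(0, cos(0.5), -sin(0.5)), c(0, sin(0.5), cos(0.5)))
  a1 <- ava_with_resolution_bounds(rotate_cloud(cl, R), cfg)$area
  expect_equal(a1, a0, tolerance = 0.05 * a0)
  cl2 <- cl; cl2$points <- cl$points * 1.3
  a2 <- ava_with_resolution_bounds(cl2, raster_config(150, physical_extent = 3 * 1.3))$area
  expect_equal(a2, a0 * 1.3^2, tolerance = 0.05 * a0 * 1.69)
})

test_that("image and mesh pipelines agree on the same ground-truth orifice", {
  area_true <- 0.5
  cl <- generate_leaflet_cloud(area_true, seed = 5, lobe = 0.25)
  a_mesh <- ava_with_resolution_bounds(cl, raster_config(150, physical_extent = 3))$area
  fs <- render_endoscope_frames(area_true, px_per_cm = 130, valve_radius = 150,
                                shape = c(340, 340), lobe = 0.25, noise_sd = 0)
  a_img <- ava_series_with_bounds(fs, ava_image_config(threshold = 0.5))$area[1]
  expect_equal(a_mesh, a_img, tolerance = 0.10 * a_img)
})
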