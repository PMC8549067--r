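test_that("the distance-to-byte mapping hits its endpoints exactly", {
  for (L in c(0.5, 1.5, 4)) {
    expect_identical(density_byte(-L, L), 255L)
    expect_identical(density_byte(0, L), 128L)
    expect_identical(density_byte(L, L), 0L)
    # clamped outside the band, linear inside
    expect_identical(density_byte(-2 * L, L), 255L)
    expect_identical(density_byte(2 * L, L), 0L)
    expect_identical(density_byte(c(-L / 2), L), as.integer(round(191.25)))
  }
})

test_that("ball densities put 128 on the sphere surface", {
  obj <- molecular_object("b", atom_table("C", matrix(0, 1, 3), radius = 4))
  g <- fill_density_grid(obj, "balls", spacing = 1)
  # grid point exactly on the surface: the origin sits on a grid point,
  # so points at distance 4 along an axis are exactly on the sphere
  org_idx <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
  expect_identical(g$density[org_idx[1] + 4, org_idx[2], org_idx[3]], 128L)
  expect_identical(g$density[org_idx[1], org_idx[2], org_idx[3]], 255L)
  far <- g$density[org_idx[1] + 6, org_idx[2], org_idx[3]]
  expect_identical(far, 0L)
})

test_that("the cut-plane estimator is exact for straight circular segments", {
  seg <- list(p0 = c(0, 0, 0), p1 = c(0, 0, 4), t0 = c(0, 0, 1),
              t1 = c(0, 0, 1), u0 = c(1, 0, 0), u1 = c(1, 0, 0),
              cross0 = list(kind = "circle", r = 1.5),
              cross1 = list(kind = "circle", r = 1.5))
  # on the axis: minus the radius
  expect_equal(estimate_surface_distance(c(0, 0, 2), seg), -1.5)
  set.seed(4)
  for (rep in 1:20) {
    p <- c(runif(2, -3, 3), runif(1, 0, 4))
    exact <- sqrt(sum(p[1:2]^2)) - 1.5
    expect_equal(estimate_surface_distance(p, seg), exact, tolerance = 1e-9)
  }
  # tapered circular segment: estimate within 10% of the sampled truth
  seg$cross1 <- list(kind = "circle", r = 0.5)
  set.seed(5)
  for (rep in 1:10) {
    p <- c(runif(2, -2, 2), runif(1, 0.5, 3.5))
    est <- estimate_surface_distance(p, seg)
    # dense sampling of the true cone surface
    ts <- seq(0, 1, length.out = 200)
    ang <- seq(0, 2 * pi, length.out = 90)
    surf <- do.call(rbind, lapply(ts, function(t) {
      r <- 1.5 + t * (0.5 - 1.5)
      cbind(r * cos(ang), r * sin(ang), 4 * t)
    }))
    truth <- min(sqrt(rowSums(sweep(surf, 2, p)^2)))
    expect_lt(abs(abs(est) - truth), max(0.1 * truth, 0.05))
  }
})

test_that("a straight tube rasterises within a quarter spacing of the cylinder", {
  chain <- straight_chain(10)
  g <- fill_density_grid(chain, "tube", spacing = 1)
  idx <- which(g$density > 0, arr.ind = TRUE)
  pts <- sweep((idx - 1) * g$spacing, 2, g$origin, "+")
  # interior points (away from the end caps)
  keep <- pts[, 1] > 5 & pts[, 1] < 30
  d_true <- sqrt(pts[keep, 2]^2 + pts[keep, 3]^2) - 0.75
  d_grid <- (128 - as.numeric(g$density[idx[keep, , drop = FALSE]])) *
    2 * g$spacing / 255
  expect_lt(max(abs(d_grid - d_true)), 0.25 * g$spacing + 2 * g$spacing / 255)
})

test_that("8-cell downsampling conserves the mean and votes colours", {
  obj <- molecular_object("b", atom_table("C", matrix(0, 1, 3), radius = 6))
  g <- fill_density_grid(obj, "balls", spacing = 0.75)
  g2 <- downsample_grid(g)
  expect_lte(abs(mean(g$density) - mean(g2$density)), 0.5)
  expect_equal(g2$spacing, 1.5)
  # a uniform grid stays uniform
  gu <- g; gu$density[] <- 77L; gu$color[] <- 3L
  g2u <- downsample_grid(gu)
  expect_true(all(g2u$density == 77L))
  expect_true(all(g2u$color == 3L))
})

test_that("isosurface meshes coarsen strictly across downsampling levels", {
  obj <- molecular_object("b", atom_table("C", matrix(0, 1, 3), radius = 9))
  g <- fill_density_grid(obj, "balls", spacing = 0.6)
  counts <- integer(0)
  for (lvl in 0:4) {
    counts <- c(counts, nrow(extract_isosurface(g)$vertices))
    if (lvl < 4) g <- downsample_grid(g)
  }
  expect_true(all(diff(counts) < 0))
})

test_that("isosurface extraction is accurate, watertight and component-aware", {
  obj <- molecular_object("b", atom_table("C", matrix(0, 1, 3), radius = 5))
  g <- fill_density_grid(obj, "balls", spacing = 0.8)
  mesh <- extract_isosurface(g)
  rr <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(rr - 5)), g$spacing)
  expect_equal(petworld:::mesh_euler_characteristic(mesh), 2)
  expect_equal(petworld:::mesh_components(mesh), 1)
  # two disjoint blobs give two components
  obj2 <- molecular_object("bb", atom_table(c("C", "C"),
                                            rbind(c(0, 0, 0), c(20, 0, 0)),
                                            radius = 4))
  g2 <- fill_density_grid(obj2, "balls", spacing = 0.8)
  m2 <- extract_isosurface(g2)
  expect_equal(petworld:::mesh_components(m2), 2)
  # an empty grid yields an empty mesh
  ge <- g; ge$density[] <- 0L
  expect_equal(nrow(extract_isosurface(ge)$vertices), 0)
})

test_that("segment overlap resolution is order-independent", {
  chain <- straight_chain(6)
  g1 <- fill_density_grid(chain, "tube", spacing = 1.2)
  # rebuild with segments processed in reverse order
  segs <- petworld:::spline_segments(chain, "tube")
  L <- g1$spacing
  g2 <- petworld:::new_lod_grid(g1$origin, g1$dims, L)
  for (s in rev(seq_along(segs)))
    g2 <- petworld:::rasterize_segment(g2, segs[[s]], s,
                                       1 + (s - 1) %% 6)
  expect_identical(g1$density, g2$density)
})
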