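test_that("grid spacing follows the power-of-two femtometre rule", {
  expect_identical(grid_spacing(0.1), 0.16384)
  expect_identical(grid_spacing(0.2), 0.32768)
  expect_identical(grid_spacing(0.3), 0.65536)
  expect_error(grid_spacing(0.4), "smallest pet radius")
})

test_that("density grid flags match a brute-force point-in-sphere count", {
  at <- atom_table("C", matrix(c(0.3, -0.1, 0.2), 1, 3), radius = 1)
  grid <- build_density_grid(at, 0.2)
  # brute force: count grid points within 1 A of the atom centre
  idx <- which(array(TRUE, grid$dims), arr.ind = TRUE)
  pts <- sweep((idx - 1) * grid$spacing, 2, grid$origin, "+")
  d <- sqrt(rowSums(sweep(pts, 2, c(0.3, -0.1, 0.2))^2))
  expect_equal(sum(grid$inside), sum(d <= 1))
  expect_error(build_density_grid(at[0, ], 0.2), "empty")
})

test_that("pass threshold identities hold for every radius index", {
  for (sm in c(0.1, 0.2, 0.3)) {
    sp <- grid_spacing(sm)
    radii <- seq(1.2, sm, by = -0.1)
    th <- pass_thresholds(radii, sp)
    n <- nrow(th)
    expect_equal(th$max_pass2, th$pet_points)
    expect_equal(th$min_pass1, th$max_pass2)
    expect_equal(th$min_pass2[-n], th$max_pass2[-1] / 2)
    expect_equal(th$min_pass2[n], th$pet_points[n] / 2)
  }
})

test_that("incremental X-sweep counts equal brute-force recounts exactly", {
  grid <- random_test_grid(dims = c(12, 10, 9), seed = 7)
  th <- pass_thresholds(seq(1.2, 0.1, by = -0.1), grid$spacing)
  set.seed(3)
  for (r in seq(1.2, 0.1, by = -0.1)) {
    for (pass in 1:2) {
      inc <- sweep_scores(grid, r, pass, thresholds = th,
                          method = "incremental", keep_all = TRUE)
      shf <- sweep_scores(grid, r, pass, thresholds = th,
                          method = "shift", keep_all = TRUE)
      expect_identical(inc[c("inner_count", "double_count", "outer_count")],
                       shf[c("inner_count", "double_count", "outer_count")])
      expect_identical(inc$score, shf$score)
    }
    # spot-check a few positions against the independent oracle
    tab <- sweep_scores(grid, r, 1, thresholds = th, method = "shift",
                        keep_all = TRUE)
    for (row in sample(nrow(tab), 3)) {
      bc <- brute_counts(grid, c(tab$ix[row], tab$iy[row], tab$iz[row]), r)
      expect_identical(unname(bc),
                       c(tab$inner_count[row], tab$double_count[row],
                         tab$outer_count[row]))
    }
  }
})

test_that("an all-outside grid yields no placement candidates", {
  grid <- random_test_grid(dims = c(8, 8, 8), p_inside = 0, p_covered = 0)
  tab <- sweep_scores(grid, 0.6, 1)
  expect_equal(nrow(tab), 0)
  out <- place_pet_atoms(grid, radii = c(1.2, 0.6))
  expect_equal(nrow(out$atoms), 0)
})

test_that("a fully-inside uncovered probe position reaches the pass-2 maximum", {
  grid <- random_test_grid(dims = c(13, 13, 13), p_inside = 1, p_covered = 0,
                           spacing = 0.32768)
  th <- pass_thresholds(c(0.6), grid$spacing)
  tab <- sweep_scores(grid, 0.6, 2, thresholds = th, keep_all = TRUE)
  ctr <- tab[tab$ix == 7 & tab$iy == 7 & tab$iz == 7, ]
  expect_equal(ctr$score, th$pet_points[1])
})

test_that("a spherical blob is seeded with the largest fitting pet atom", {
  # inside points: sphere of radius 1.25 A at the grid centre
  sp <- grid_spacing(0.2)
  dims <- c(15, 15, 15)
  ctr <- c(8, 8, 8)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  inside <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) * sp <= 1.25, dims)
  grid <- structure(list(spacing = sp, origin = c(0, 0, 0), dims = dims,
                         inside = inside, covered = array(FALSE, dims)),
                    class = "density_grid")
  out <- place_pet_atoms(grid, radii = seq(1.2, 0.2, by = -0.1))
  expect_gt(nrow(out$atoms), 0)
  first <- out$atoms[1, ]
  expect_equal(first$radius_index, 12)
  centre_xyz <- (ctr - 1) * sp
  expect_lt(sqrt(sum((unlist(first[c("x", "y", "z")]) - centre_xyz)^2)),
            sp + 1e-9)
  # every accepted atom satisfied its pass minimum (asserted during
  # placement); scores recorded are at acceptance time
  th <- pass_thresholds(seq(1.2, 0.2, by = -0.1), sp)
  for (r in seq_len(nrow(out$atoms))) {
    a <- out$atoms[r, ]
    lim <- th[match(a$radius, th$radius), ]
    expect_gte(a$score, if (a$pass == 1) lim$min_pass1 else lim$min_pass2)
  }
})

test_that("bonding joins overlaps, rescues loners and connects clusters", {
  # two overlapping atoms
  at <- data.frame(x = c(0, 0.9), y = 0, z = 0, radius = 0.5)
  expect_equal(nrow(bond_pet_atoms(at)), 1)
  # two tight clusters with a gap: exactly one bridging bond
  cl <- rbind(data.frame(x = c(0, 0.5, 0.25), y = c(0, 0, 0.4), z = 0,
                         radius = 0.5),
              data.frame(x = c(5, 5.5, 5.25), y = c(0, 0, 0.4), z = 0,
                         radius = 0.5))
  bonds <- bond_pet_atoms(cl)
  bridging <- sum(bonds[, 1] <= 3 & bonds[, 2] >= 4)
  expect_equal(bridging, 1)
  comp <- petworld:::bond_components(6, bonds)
  expect_equal(length(unique(comp)), 1)
  # single atom: no bonds, no error
  expect_equal(nrow(bond_pet_atoms(cl[1, ])), 0)
})

test_that("shrinking a protein yields a connected one-tenth-scale pet molecule", {
  cl <- make_globular_cloud(400, seed = 9)
  pet <- shrink_molecule(cl)
  expect_equal(pet$kind, "pet")
  expect_true(all(is_pet_element(pet$atoms$element)))
  expect_true(all(pet$atoms$bfactor == 0))
  comp <- petworld:::bond_components(nrow(pet$atoms), pet$bonds)
  expect_equal(length(unique(comp)), 1)
  # pet extent is about one tenth of the all-atom extent
  expect_lt(max(dist(xyz_of(pet))), 0.2 * max(dist(xyz_of(cl))))
  expect_identical(pet$allatom_backup$atoms, cl$atoms)
  expect_error(shrink_molecule(pet), "already")
})

test_that("placement count shrinks when acceptance thresholds tighten", {
  cl <- make_globular_cloud(300, seed = 5)
  pa <- cl$atoms
  pa[, c("x", "y", "z")] <- xyz_of(cl) * 0.1
  pa$radius <- pa$radius * 0.1
  grid <- build_density_grid(pa, 0.2)
  full <- place_pet_atoms(grid, radii = seq(1.2, 0.2, by = -0.1))
  coarse <- place_pet_atoms(build_density_grid(pa, 0.2),
                            radii = seq(1.2, 0.4, by = -0.1))
  # dropping the small radii (equivalent to raising the bar for what may
  # be placed) cannot increase the atom count
  expect_lte(nrow(coarse$atoms), nrow(full$atoms))
})
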