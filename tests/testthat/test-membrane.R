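test_that("TM detection accepts a fully exposed poly-Leu helix only", {
  hb <- make_helix_bundle(1, 20, tilt = 0, sequence_pattern = "LEU", seed = 1)
  segs <- detect_tm_elements(hb)
  expect_equal(length(segs), 1)
  expect_equal(segs[[1]]$kind, "helix")
  # a strongly polar residue anywhere in the element rejects it
  pat <- rep("LEU", 20); pat[10] <- "LYS"
  expect_equal(length(detect_tm_elements(
    make_helix_bundle(1, 20, 0, pat, 1))), 0)
  # below the 12-residue helix minimum
  expect_equal(length(detect_tm_elements(
    make_helix_bundle(1, 8, 0, "LEU", 1))), 0)
  # above the 29-residue maximum
  expect_equal(length(detect_tm_elements(
    make_helix_bundle(1, 35, 0, "LEU", 1))), 0)
})

test_that("TM detection is invariant under rigid-body transforms", {
  hb <- make_helix_bundle(1, 20, tilt = 0, sequence_pattern = "LEU", seed = 1)
  R <- petworld:::rotation_about_axis(c(1, 2, 0.5), 1.1)
  hb2 <- hb
  hb2$atoms[, c("x", "y", "z")] <- sweep(xyz_of(hb) %*% t(R), 2,
                                         c(11, -4, 7), "+")
  s1 <- detect_tm_elements(hb)
  s2 <- detect_tm_elements(hb2)
  expect_equal(length(s2), length(s1))
  expect_equal(s2[[1]]$range, s1[[1]]$range)
  # the axis rotates with the molecule
  expect_equal(abs(sum(s2[[1]]$axis$direction *
                         (R %*% s1[[1]]$axis$direction))), 1,
               tolerance = 1e-3)
})

test_that("membrane orientation aligns the summed segment axes with +Z", {
  hb <- make_helix_bundle(1, 20, tilt = 0, sequence_pattern = "LEU", seed = 1)
  segs <- detect_tm_elements(hb)
  o <- orient_for_membrane(hb, segs)
  # single vertical helix: rotation is essentially the identity
  expect_lt(acos(min(1, abs(o$normal[3]))) * 180 / pi, 2)
  expect_lt(max(abs(o$rotation - diag(3))), 0.05)
  # idempotence: re-orienting the rotated protein gives ~identity
  hb2 <- hb
  hb2$atoms[, c("x", "y", "z")] <- xyz_of(hb) %*% t(o$rotation)
  o2 <- orient_for_membrane(hb2, detect_tm_elements(hb2))
  ang <- acos(min(1, (sum(diag(o2$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("bundle orientation recovers the mean axis from tilted helices", {
  hb <- make_helix_bundle(3, 20, tilt = 10, sequence_pattern = "LEU", seed = 2)
  segs <- detect_tm_elements(hb)
  expect_equal(length(segs), 3)
  o <- orient_for_membrane(hb, segs)
  # sign-corrected mean of the true helix axes (alternating +/-10 degrees
  # about ring-tangent directions)
  dirs <- lapply(segs, function(s) {
    d <- s$axis$direction
    if (d[3] < 0) -d else d
  })
  mean_axis <- Reduce(`+`, dirs)
  mean_axis <- mean_axis / sqrt(sum(mean_axis^2))
  dev <- acos(min(1, abs(sum(o$normal * mean_axis)))) * 180 / pi
  expect_lt(dev, 1e-6)
  # brute-force check: no candidate direction on a coarse sphere grid
  # beats the returned normal at aligning the (sign-corrected) axes
  align <- function(n) sum(vapply(dirs, function(d) abs(sum(d * n)), 0))
  best <- align(o$normal)
  for (th in seq(0, pi, length.out = 13)) for (ph in seq(0, 2 * pi,
                                                         length.out = 25)) {
    n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    expect_lte(align(n), best + 0.02)
  }
})

test_that("the hydrophobic-band scan finds a constructed belt", {
  # 3 stacked helices along z: only the middle one is hydrophobic
  pat_polar <- rep("SER", 20)
  mk <- function(zoff, pat) {
    h <- make_helix_bundle(1, 20, 0, pat, 1)
    h$atoms[, "z"] <- h$atoms[, "z"] + zoff
    h
  }
  a <- mk(-31, pat_polar); b <- mk(0, rep("LEU", 20)); c2 <- mk(31, pat_polar)
  atoms <- rbind(a$atoms, b$atoms, c2$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$resno <- rep(1:60, each = 2)
  residues <- data.frame(name = c(rep("SER", 20), rep("LEU", 20),
                                  rep("SER", 20)),
                         start = seq(1, 119, by = 2), end = seq(2, 120, by = 2),
                         ss = "H", stringsAsFactors = FALSE)
  prot <- molecular_object("stack", atoms, kind = "protein",
                           residues = residues)
  segs <- list(list(range = 21:40, kind = "helix",
                    axis = list(point = c(0, 0, 0), direction = c(0, 0, 1))))
  o <- orient_for_membrane(prot, segs)
  belt <- c(min(xyz_of(b)[, 3]), max(xyz_of(b)[, 3]))
  centre <- mean(o$z_band)
  expect_gt(centre, belt[1]); expect_lt(centre, belt[2])
})

test_that("pet membrane blocks fill their footprint in two even layers", {
  for (shape in c("rectangle", "rhombus", "triangle")) {
    blk <- build_pet_membrane_block(shape, 12, layer_gap = 4)
    expect_true(all(blk$atoms$radius == 1.2))
    zs <- sort(unique(round(blk$atoms$z, 6)))
    expect_equal(zs, c(-2, 2))
    # all atoms inside the footprint polygon
    inside <- petworld:::point_in_polygon(as.matrix(blk$atoms[, c("x", "y")]),
                                          blk$block$polygon, tol = 1e-6)
    expect_true(all(inside))
    # per-layer packing is uniform
    lay <- blk$atoms[blk$atoms$z < 0, c("x", "y")]
    d <- as.matrix(dist(lay)); diag(d) <- Inf
    nn <- apply(d, 1, min)
    expect_lt(sd(nn) / mean(nn), 0.05)
  }
  expect_error(build_pet_membrane_block("rhombus", 0.5), "lattice cell")
  # triangle is half the rhombus give or take one lattice row
  rh <- build_pet_membrane_block("rhombus", 12, layer_gap = 4)
  tr <- build_pet_membrane_block("triangle", 12, layer_gap = 4)
  row_atoms <- 12 / 2.4 + 1
  expect_lt(abs(nrow(tr$atoms) - nrow(rh$atoms) / 2), 2 * row_atoms * 2)
})

test_that("edge-to-edge rhombic blocks tile without bumping", {
  blk <- build_pet_membrane_block("rhombus", 12, layer_gap = 4)
  a <- as.matrix(blk$atoms[, c("x", "y", "z")])
  b <- a; b[, 1] <- b[, 1] + 12  # translate by one side length
  cross <- sqrt(rowSums((a[rep(seq_len(nrow(a)), nrow(b)), ] -
                           b[rep(seq_len(nrow(b)), each = nrow(a)), ])^2))
  expect_gte(min(cross), blk$block$spacing - 1e-6)
})

test_that("bilayer classification recovers shape, size and leaflets", {
  cls <- classify_membrane_block(make_bilayer(c(60, 40), "rectangle",
                                              seed = 1))
  expect_equal(cls$shape, "rectangle")
  expect_lt(max(abs(sort(cls$size, decreasing = TRUE) - c(60, 40))), 8)
  expect_lt(abs(diff(cls$layer_z)) - 24.67, 1.5)
  expect_equal(classify_membrane_block(make_bilayer(60, "rhombus",
                                                    seed = 2))$shape,
               "rhombus")
  expect_equal(classify_membrane_block(make_bilayer(60, "triangle",
                                                    seed = 3))$shape,
               "triangle")
  # protein-only object fails the phospholipid precondition
  expect_error(classify_membrane_block(make_globular_cloud(50, 1)),
               "phospholipid")
  # monolayer: one z cluster
  mono <- make_bilayer(c(40, 40), "rectangle", seed = 4)
  keep <- mono$atoms$z > 0
  mono$atoms <- mono$atoms[keep, ]
  mono$atoms$eleno <- seq_len(nrow(mono$atoms))
  mono2 <- molecular_object("mono", mono$atoms, kind = "membrane_block")
  expect_error(classify_membrane_block(mono2), "monolayer")
})
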