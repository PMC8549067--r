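# Flat strip of 2N ideal equilateral triangles in the xy plane.
make_strip <- function(n_pairs, side = 1) {
  h <- side * sqrt(3) / 2
  verts <- list(); faces <- list()
  for (i in 0:n_pairs) {
    verts[[2 * i + 1]] <- c(i * side, 0, 0)
    verts[[2 * i + 2]] <- c(i * side + side / 2, h, 0)
  }
  for (i in seq_len(n_pairs)) {
    a <- 2 * i - 1
    faces[[2 * i - 1]] <- c(a, a + 1, a + 2)
    faces[[2 * i]] <- c(a + 1, a + 3, a + 2)
  }
  structure(list(vertices = do.call(rbind, verts),
                 faces = do.call(rbind, faces)), class = "tri_mesh")
}

test_that("the ideal rhombus scores the maximum and deviations score less", {
  strip <- make_strip(4)
  s_ideal <- rhombus_score(strip, 1, 2)
  expect_equal(s_ideal, 1, tolerance = 1e-12)
  # all ideal pairs score equally
  expect_equal(rhombus_score(strip, 3, 4), s_ideal, tolerance = 1e-12)
  # perturbing one vertex strictly lowers the score
  warp <- strip
  warp$vertices[1, ] <- warp$vertices[1, ] + c(0.05, 0.03, 0)
  expect_lt(rhombus_score(warp, 1, 2), s_ideal)
  # a sliver pair ranks below a near-ideal pair
  sliver <- strip
  sliver$vertices[4, 2] <- 0.05
  expect_lt(rhombus_score(sliver, 2, 3), rhombus_score(sliver, 1, 2))
  expect_error(rhombus_score(strip, 1, 4), "share")
})

test_that("an even ideal strip tessellates with zero holes", {
  strip <- make_strip(5)  # 10 faces
  tess <- tessellate_mesh(strip)
  expect_equal(length(tess$holes), 0)
  expect_equal(nrow(tess$rhombi), 5)
})

test_that("face usage is conserved: 2 rhombi + holes = faces", {
  for (s in 0:2) {
    ico <- make_icosphere(s)
    tess <- tessellate_mesh(ico)
    expect_equal(2 * nrow(tess$rhombi) + length(tess$holes),
                 nrow(ico$faces))
    used <- c(as.vector(tess$rhombi), tess$holes)
    expect_equal(sort(used), seq_len(nrow(ico$faces)))
  }
  # an odd-face strip leaves exactly one triangular hole
  odd <- make_strip(3)
  odd$faces <- odd$faces[1:5, ]
  t_odd <- tessellate_mesh(odd)
  expect_equal(length(t_odd$holes), 1)
})

test_that("sphere hole fraction does not grow with subdivision", {
  fr <- vapply(1:3, function(s) {
    ico <- make_icosphere(s)
    tess <- tessellate_mesh(ico)
    length(tess$holes) / nrow(ico$faces)
  }, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("tessellation and placement are deterministic under a seed", {
  ico <- make_icosphere(2)
  t1 <- tessellate_mesh(ico)
  t2 <- tessellate_mesh(ico)
  expect_identical(t1$rhombi, t2$rhombi)
  expect_identical(t1$total_score, t2$total_score)
  blk <- build_pet_membrane_block("rhombus", 2, layer_gap = 0.8,
                                  spacing = 0.5)
  p1 <- place_blocks(ico, t1, list(), blk, seed = 11)
  p2 <- place_blocks(ico, t1, list(), blk, seed = 11)
  expect_identical(p1$order, p2$order)
  expect_identical(p1$placements, p2$placements)
  p3 <- place_blocks(ico, t1, list(), blk, seed = 12)
  expect_false(identical(p3$order, p1$order))
})

test_that("with no protein blocks every rhombus and hole gets an empty block", {
  strip <- make_strip(3)
  strip$faces <- strip$faces[1:5, ]  # force one hole
  tess <- tessellate_mesh(strip)
  blk <- build_pet_membrane_block("rhombus", 1, layer_gap = 0.4,
                                  spacing = 0.4)
  pl <- place_blocks(strip, tess, list(), blk, seed = 1)
  expect_equal(nrow(pl$placements), nrow(tess$rhombi) + length(tess$holes))
  expect_true(all(pl$placements$block == "empty"))
  expect_equal(sum(pl$placements$site_kind == "hole"), 1)
})

test_that("protein blocks land on rhombi and colliding copies are skipped", {
  ico <- make_icosphere(1)
  tess <- tessellate_mesh(ico)
  blk <- build_pet_membrane_block("rhombus", 0.6, layer_gap = 0.3,
                                  spacing = 0.3)
  blk$protein_atoms <- seq_len(nrow(blk$atoms))
  # two copies: both placeable on a sphere with 40 rhombi
  pl <- place_blocks(ico, tess, list(blk, blk), NULL, seed = 3)
  expect_equal(sum(pl$placements$block == "protein"), 2)
  expect_equal(length(pl$unplaced), 0)
  # mapped block corners coincide with the mesh rhombus corners
  # corners map in least-squares sense (mesh rhombi are slightly
  # non-planar on a sphere)
  tr <- pl$transforms[[1]]
  mapped <- petworld:::affine_apply(cbind(blk$block$polygon, 0), tr)
  expect_lt(max(abs(mapped - pl$corners[[1]])), 0.1)
})
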