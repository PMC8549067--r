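# Greedy rhombus tessellation of triangle meshes and placement of
# membrane blocks on the resulting rhombi.
#
# Rhombus scoring. Adjacent face pairs are compared with the ideal
# rhombus: two equilateral triangles joined on an edge, corner angles
# 60/120 degrees, area 2 * sqrt(3)/4 * L^2 where L is the mesh's mean
# edge length (the reference size). The deviation is quantified by the
# product of the (relative) differences in area and in the four corner
# angles; the score is the reciprocal
#
#   score = 1 / [ (1 + |A - A0| / A0) * prod_k (1 + |th_k - th_k0| / th_k0) ]
#
# so ideal rhombi of the reference area score the maximum (1) and the
# score strictly decreases as the area or any corner angle deviates.

mesh_edge_key <- function(a, b) paste(min(a, b), max(a, b))

# Face adjacency over shared edges; returns list: for each face, the
# indices of faces sharing one edge with it.
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  edge_faces <- new.env()
  for (i in seq_len(nrow(f))) {
    vs <- f[i, ]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      key <- mesh_edge_key(vs[e[1]], vs[e[2]])
      edge_faces[[key]] <- c(edge_faces[[key]], i)
    }
  }
  adj <- vector("list", nrow(f))
  for (key in ls(edge_faces)) {
    fs <- edge_faces[[key]]
    if (length(fs) > 2) stop("non-manifold edge shared by >2 faces")
    if (length(fs) == 2) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  adj
}

# Corner vertices of the rhombus formed by two faces sharing an edge, in
# cycle order (apex_a, shared1, apex_b, shared2).
rhombus_corners <- function(mesh, fa, fb) {
  va <- mesh$faces[fa, ]; vb <- mesh$faces[fb, ]
  shared <- intersect(va, vb)
  if (length(shared) != 2) stop("faces do not share exactly one edge")
  c(setdiff(va, shared), shared[1], setdiff(vb, shared), shared[2])
}

#' Score a candidate rhombus formed by two adjacent faces
#'
#' @param mesh a `tri_mesh`.
#' @param fa,fb indices of two faces sharing exactly one edge.
#' @param ref_area reference area of the ideal rhombus (defaults to the
#'   ideal rhombus over the mesh's mean edge length).
#' @return score in (0, 1]; 1 is the ideal 60/120-degree rhombus of the
#'   reference area.
#' @export
rhombus_score <- function(mesh, fa, fb, ref_area = NULL) {
  if (is.null(ref_area)) ref_area <- mesh_ref_area(mesh)
  corners <- rhombus_corners(mesh, fa, fb)
  p <- mesh$vertices[corners, , drop = FALSE]
  angles <- vapply(1:4, function(i) {
    prev <- p[((i - 2) %% 4) + 1, ]; cur <- p[i, ]; nxt <- p[(i %% 4) + 1, ]
    rad2deg(bend_angle(prev, cur, nxt))
  }, 0)
  # corners alternate apex/shared; the apexes (opposite the shared edge)
  # carry the 60-degree angles, the shared-edge corners the 120-degree
  # sums of two triangle angles
  ideal <- c(60, 120, 60, 120)
  area <- triangle_area(mesh, fa) + triangle_area(mesh, fb)
  dev <- (1 + abs(area - ref_area) / ref_area) *
    prod(1 + abs(angles - ideal) / ideal)
  1 / dev
}

triangle_area <- function(mesh, f) {
  v <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
  vec_norm(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])) / 2
}

mesh_ref_area <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  L <- mean(len)
  2 * sqrt(3) / 4 * L^2
}

#' Tessellate a triangle mesh with rhombi
#'
#' Pairs mesh faces into rhombi greedily. The triangle with the highest
#' sum of its three rhombus scores seeds three alternative runs (one per
#' starting rhombus); each run repeatedly pops the best-scoring frontier
#' rhombus, skips it if either face is already used, and otherwise
#' accepts it and pushes the candidates across its four outer edges. The
#' run with the highest total score wins. Unpairable faces remain as
#' triangular holes; every face is used exactly once, so
#' 2 * |rhombi| + |holes| = |faces|.
#'
#' @param mesh a `tri_mesh`.
#' @return a `tessellation`: list with `rhombi` (two-column matrix of
#'   face pairs), `holes` (face indices), `scores` (per accepted rhombus,
#'   in placement order), `total_score`.
#' @export
tessellate_mesh <- function(mesh) {
  nf <- nrow(mesh$faces)
  if (nf < 2)
    return(structure(list(rhombi = matrix(integer(0), ncol = 2),
                          holes = seq_len(nf), scores = numeric(0),
                          total_score = 0), class = "tessellation"))
  adj <- mesh_adjacency(mesh)
  ref_area <- mesh_ref_area(mesh)
  score_pair <- function(a, b) rhombus_score(mesh, a, b, ref_area)
  # starting triangle: highest sum of its three rhombus scores
  sums <- vapply(seq_len(nf), function(i)
    sum(vapply(adj[[i]], function(j) score_pair(i, j), 0)), 0)
  start <- which.max(sums)  # ties break by index order
  runs <- lapply(adj[[start]], function(j) {
    run_tessellation(mesh, adj, start, j, score_pair)
  })
  best <- which.max(vapply(runs, `[[`, 0, "total_score"))
  structure(runs[[best]], class = "tessellation")
}

run_tessellation <- function(mesh, adj, fa, fb, score_pair) {
  nf <- nrow(mesh$faces)
  used <- rep(FALSE, nf)
  frontier <- data.frame(a = fa, b = fb, score = score_pair(fa, fb))
  rhombi <- list(); scores <- numeric(0)
  seen <- character(0)
  while (nrow(frontier) > 0) {
    top <- which.max(frontier$score)
    cand <- frontier[top, ]
    frontier <- frontier[-top, , drop = FALSE]
    if (used[cand$a] || used[cand$b]) next
    used[c(cand$a, cand$b)] <- TRUE
    rhombi[[length(rhombi) + 1]] <- c(cand$a, cand$b)
    scores <- c(scores, cand$score)
    # push the neighbouring rhombi across the four outer edges
    for (f in c(cand$a, cand$b)) for (g in adj[[f]]) {
      if (used[g]) next
      for (h in adj[[g]]) {
        if (used[h] || h == g) next
        key <- mesh_edge_key(g, h)
        if (key %in% seen) next
        seen <- c(seen, key)
        frontier <- rbind(frontier,
                          data.frame(a = g, b = h, score = score_pair(g, h)))
      }
    }
  }
  # the algorithm stops only when no rhombus can be placed at all: sweep
  # any remaining free adjacent pairs (disjoint frontier pockets) until
  # the pairing is maximal
  repeat {
    free <- which(!used)
    cand <- NULL
    for (g in free) for (h in adj[[g]])
      if (h > g && !used[h]) {
        sc <- score_pair(g, h)
        if (is.null(cand) || sc > cand$score)
          cand <- data.frame(a = g, b = h, score = sc)
      }
    if (is.null(cand)) break
    used[c(cand$a, cand$b)] <- TRUE
    rhombi[[length(rhombi) + 1]] <- c(cand$a, cand$b)
    scores <- c(scores, cand$score)
  }
  # refinement: the stop condition is "no rhombus can be placed", so
  # orphan triangles that could still be paired by relocating existing
  # rhombi are resolved with alternating-path augmentation over the
  # face-pairing graph (starting from the greedy pairing)
  match <- integer(nf)
  for (r in rhombi) { match[r[1]] <- r[2]; match[r[2]] <- r[1] }
  match <- augment_matching(adj, match)
  paired <- which(match > seq_len(nf))
  rh <- cbind(match[paired], paired)
  sc <- if (nrow(rh)) vapply(seq_len(nrow(rh)), function(r)
    score_pair(rh[r, 1], rh[r, 2]), 0) else numeric(0)
  ord <- order(-sc)
  list(rhombi = rh[ord, , drop = FALSE], holes = which(match == 0),
       scores = sc[ord], total_score = sum(sc))
}

# Alternating-path augmentation (blossoms are not contracted; instead the
# search is retried with reversed neighbour order, which resolves the
# rare odd-cycle blocks seen on triangle-mesh duals).
augment_matching <- function(adj, match) {
  match <- augment_pass(adj, match)
  # odd-cycle (blossom) blocks are rare on mesh duals; escape them by
  # locally unmatching around a stuck free vertex and re-augmenting,
  # keeping the best matching found
  best <- match
  for (try in 1:8) {
    free <- which(best == 0)
    if (length(free) <= 1) break
    f <- free[1 + (try - 1) %% length(free)]
    hood <- f
    for (ring in seq_len(2 + try))  # widen the perturbation each attempt
      hood <- unique(c(hood, unlist(adj[hood])))
    cand <- best
    for (v in hood) if (cand[v] != 0) {
      w <- cand[v]; cand[v] <- 0L; cand[w] <- 0L
    }
    cand <- augment_pass(adj, cand)
    if (sum(cand == 0) < length(free)) best <- cand
  }
  best
}

augment_pass <- function(adj, match) {
  n <- length(adj)
  repeat {
    improved <- FALSE
    for (f in seq_len(n)) {
      if (match[f] != 0) next
      parent <- integer(n); state <- integer(n)
      state[f] <- 1; queue <- f
      found <- FALSE
      while (length(queue) && !found) {
        u <- queue[1]; queue <- queue[-1]
        for (v in adj[[u]]) {
          if (v == match[u] || state[v] != 0 || v == f) next
          if (match[v] == 0) {
            # augment: flip the alternating path ending at v
            y <- v; uu <- u
            repeat {
              x <- match[uu]
              match[uu] <- y; match[y] <- uu
              if (uu == f) break
              y <- x; uu <- parent[uu]
            }
            found <- TRUE; improved <- TRUE
            break
          }
          w <- match[v]
          if (state[w] == 0) {
            state[v] <- 2; state[w] <- 1; parent[w] <- u
            queue <- c(queue, w)
          }
        }
      }
    }
    if (!improved) break
  }
  match
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d rhombi, %d triangular holes, total score %.3f\n",
              nrow(x$rhombi), length(x$holes), x$total_score))
  invisible(x)
}

#' Place membrane blocks on a tessellation
#'
#' Orders the accepted rhombi by score, shuffles the top 90% with a
#' seeded Fisher-Yates permutation (so protein placements spread
#' uniformly), then places the protein-carrying blocks consecutively,
#' skipping rhombi where the block's protein pet atoms would collide
#' with already-placed protein atoms (neighbour-grid broad phase with a
#' cell of twice the largest pet radius). Remaining rhombi and the
#' triangular holes are filled with empty blocks. Blocks are mapped onto
#' each mesh rhombus by a least-squares affine fit of the ideal rhombus
#' corners onto the mesh corners.
#'
#' @param mesh the tessellated `tri_mesh`.
#' @param tess a `tessellation` of `mesh`.
#' @param protein_blocks list of pet `pet_object`s whose `$block$polygon`
#'   describes their ideal rhombus footprint and whose `$protein_atoms`
#'   (optional integer vector) marks protein pet atoms for collision
#'   testing; recycled entries are placed once each.
#' @param empty_block pet `pet_object` used for leftover rhombi and (its
#'   triangular half) for holes; may be NULL to skip filling.
#' @param seed shuffle seed.
#' @return list with `placements` (data.frame: site id, kind
#'   rhombus/hole, block kind protein/empty, face indices), `unplaced`
#'   (indices of protein blocks that collided everywhere), and
#'   `transforms` (per placement, 3x4 affine matrix) plus `corners`.
#' @export
place_blocks <- function(mesh, tess, protein_blocks = list(),
                         empty_block = NULL, seed = 0) {
  nr <- nrow(tess$rhombi)
  ord <- order(-tess$scores)
  top <- ord[seq_len(floor(0.9 * nr))]
  rest <- setdiff(ord, top)
  shuffled <- with_seed(seed, c(top[sample.int(length(top))], rest))
  corners_of <- function(r) {
    idx <- rhombus_corners(mesh, tess$rhombi[r, 1], tess$rhombi[r, 2])
    mesh$vertices[idx, , drop = FALSE]
  }
  placements <- list(); transforms <- list(); corners <- list()
  placed_atoms <- NULL
  grid_cell <- 2.4  # 2 x largest pet radius
  collides <- function(xyz) {
    if (is.null(placed_atoms) || nrow(xyz) == 0) return(FALSE)
    key <- function(m) paste(floor(m[, 1] / grid_cell),
                             floor(m[, 2] / grid_cell),
                             floor(m[, 3] / grid_cell))
    k_new <- key(xyz)
    # compare against neighbouring cells of existing atoms
    for (i in seq_len(nrow(xyz))) {
      d2 <- rowSums(sweep(placed_atoms, 2, xyz[i, ])^2)
      if (any(d2 < grid_cell^2 / 4)) return(TRUE)
    }
    FALSE
  }
  used_sites <- logical(nr)
  unplaced <- integer(0)
  queue <- shuffled
  for (b in seq_along(protein_blocks)) {
    blk <- protein_blocks[[b]]
    ok <- FALSE
    for (qi in seq_along(queue)) {
      r <- queue[qi]
      if (used_sites[r]) next
      tr <- block_to_rhombus(blk, corners_of(r))
      patoms <- blk$protein_atoms
      pxyz <- if (!is.null(patoms))
        affine_apply(atom_xyz(blk$atoms)[patoms, , drop = FALSE], tr)
      else affine_apply(atom_xyz(blk$atoms), tr)
      if (collides(pxyz)) next
      used_sites[r] <- TRUE
      placed_atoms <- rbind(placed_atoms, pxyz)
      placements[[length(placements) + 1]] <-
        data.frame(site = r, site_kind = "rhombus", block = "protein",
                   block_index = b)
      transforms[[length(transforms) + 1]] <- tr
      corners[[length(corners) + 1]] <- corners_of(r)
      ok <- TRUE
      break
    }
    if (!ok) unplaced <- c(unplaced, b)
  }
  # leftovers: empty blocks on unused rhombi and on triangular holes
  if (!is.null(empty_block)) {
    for (r in which(!used_sites)) {
      placements[[length(placements) + 1]] <-
        data.frame(site = r, site_kind = "rhombus", block = "empty",
                   block_index = NA_integer_)
      transforms[[length(transforms) + 1]] <-
        block_to_rhombus(empty_block, corners_of(r))
      corners[[length(corners) + 1]] <- corners_of(r)
    }
    for (h in tess$holes) {
      v <- mesh$vertices[mesh$faces[h, ], , drop = FALSE]
      placements[[length(placements) + 1]] <-
        data.frame(site = h, site_kind = "hole", block = "empty",
                   block_index = NA_integer_)
      transforms[[length(transforms) + 1]] <- NA
      corners[[length(corners) + 1]] <- v
    }
  }
  list(placements = if (length(placements)) do.call(rbind, placements)
       else data.frame(site = integer(0), site_kind = character(0),
                       block = character(0), block_index = integer(0)),
       transforms = transforms, corners = corners, unplaced = unplaced,
       order = shuffled)
}

# Least-squares affine fit of the block's ideal rhombus corners (2D
# polygon lifted to z = 0) onto the 3D mesh rhombus corners; returns a
# 3x4 matrix [A | t].
block_to_rhombus <- function(block, target_corners) {
  poly <- block$block$polygon
  if (is.null(poly)) stop("block lacks $block$polygon footprint")
  # mesh corners arrive as (apex 60, shared 120, apex 60, shared 120),
  # matching the ideal polygon's corner-angle order directly
  # least-squares 2D -> 3D affine on the footprint corners; the block's
  # out-of-plane axis maps to the target plane normal (unit scale)
  X <- cbind(poly, 1)
  coef <- qr.solve(X, target_corners[seq_len(nrow(poly)), , drop = FALSE])
  A2 <- t(coef[1:2, , drop = FALSE])   # 3 x 2
  t <- coef[3, ]
  nrm <- cross3(A2[, 1], A2[, 2])
  nrm <- nrm / max(vec_norm(nrm), 1e-12)
  cbind(A2, nrm, t)  # 3 x 4
}

affine_apply <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr[, 1:3]), 2, tr[, 4], "+")
}
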