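# Reduced level-of-detail meshes: molecules (balls or secondary-structure
# splines) are rasterised into a byte density grid, optionally averaged
# down over 8-cell blocks, and triangulated at iso level 128.
#
# Density mapping: the signed surface distance d is clamped to [-L, L]
# (L = one grid cube length) and mapped linearly to a byte, 255 one cube
# inside the surface, 128 on the surface, 0 one cube outside.

#' Signed distance to byte density
#'
#' @param d signed distance(s) from the representation surface, negative
#'   inside, in Angstrom.
#' @param L length of one grid cube (the grid spacing), Angstrom.
#' @return integer byte densities in [0, 255]; d = -L gives 255, d = 0
#'   gives 128 (the isosurface extraction level), d = +L gives 0.
#' @export
density_byte <- function(d, L) {
  v <- floor(255 * (L - d) / (2 * L) + 0.5)
  as.integer(pmax(0, pmin(255, v)))
}

new_lod_grid <- function(origin, dims, spacing) {
  structure(list(origin = origin, dims = dims, spacing = spacing,
                 density = array(0L, dims), color = array(0L, dims),
                 segment = array(0L, dims)),
            class = "lod_grid")
}

grid_point_xyz <- function(grid, ijk) {
  sweep((ijk - 1) * grid$spacing, 2, grid$origin, "+")
}

#' Fill a LOD density grid from a molecule
#'
#' "balls" style adds spherical densities per atom. Spline styles
#' ("tube", "ribbon", "cartoon") build a Catmull-Rom spline through the
#' C-alpha atoms of each ungapped residue stretch, subdivide it into
#' four segments between residues, and rasterise each segment by flood
#' fill using the cut-plane surface-distance estimator
#' ([estimate_surface_distance()]). Overlaps keep the highest density and
#' its surface colour; an auxiliary grid records the owning segment.
#'
#' @param obj a `pet_object`; spline styles need a `residues` table with
#'   secondary structure.
#' @param style "balls", "tube", "ribbon" or "cartoon".
#' @param spacing grid spacing (cube length L) in Angstrom.
#' @param color_by per-atom (balls) or per-residue (splines) integer
#'   colour indices; defaults to 1 + (index %% 6).
#' @return a `lod_grid`.
#' @export
fill_density_grid <- function(obj, style = c("balls", "tube", "ribbon",
                                             "cartoon"),
                              spacing = 1.5, color_by = NULL) {
  style <- match.arg(style)
  if (nrow(obj$atoms) == 0) stop("empty molecule")
  xyz <- atom_xyz(obj$atoms)
  L <- spacing
  pad <- max(obj$atoms$radius) + 3 * L + 3
  lo <- apply(xyz, 2, min) - pad
  dims <- as.integer(ceiling((apply(xyz, 2, max) + pad - lo) / L)) + 1L
  dims <- dims + dims %% 2L  # even dims: 8-cell averaging stays exact
  grid <- new_lod_grid(lo, dims, L)
  if (style == "balls") {
    if (is.null(color_by)) color_by <- 1 + (seq_len(nrow(xyz)) - 1) %% 6
    for (a in seq_len(nrow(xyz))) {
      r <- obj$atoms$radius[a]
      ctr <- (xyz[a, ] - lo) / L + 1
      span <- ceiling((r + L) / L)
      ix <- max(1, floor(ctr[1] - span)):min(dims[1], ceiling(ctr[1] + span))
      iy <- max(1, floor(ctr[2] - span)):min(dims[2], ceiling(ctr[2] + span))
      iz <- max(1, floor(ctr[3] - span)):min(dims[3], ceiling(ctr[3] + span))
      dd <- sqrt(outer(outer((ix - ctr[1])^2, (iy - ctr[2])^2, "+"),
                       (iz - ctr[3])^2, "+")) * L - r
      dens <- array(density_byte(dd, L), dim(dd))
      sub <- grid$density[ix, iy, iz, drop = FALSE]
      upd <- dens > sub
      sub[upd] <- dens[upd]
      grid$density[ix, iy, iz] <- sub
      colsub <- grid$color[ix, iy, iz, drop = FALSE]
      colsub[upd] <- color_by[a]
      grid$color[ix, iy, iz] <- colsub
      segsub <- grid$segment[ix, iy, iz, drop = FALSE]
      segsub[upd] <- a
      grid$segment[ix, iy, iz] <- segsub
    }
    return(grid)
  }
  segs <- spline_segments(obj, style)
  if (is.null(color_by)) color_by <- 1 + (seq_along(segs) - 1) %% 6
  for (s in seq_along(segs))
    grid <- rasterize_segment(grid, segs[[s]], s,
                              color_by[1 + (s - 1) %% length(color_by)])
  grid
}

# Catmull-Rom interpolation between p1 and p2 (t in [0,1]).
catmull_rom <- function(p0, p1, p2, p3, t) {
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

catmull_rom_tangent <- function(p0, p1, p2, p3, t) {
  0.5 * ((-p0 + p2) + 2 * (2 * p0 - 5 * p1 + 4 * p2 - p3) * t +
           3 * (-p0 + 3 * p1 - 3 * p2 + p3) * t^2)
}

# Build the spline segments for an object: one Catmull-Rom spline per
# ungapped residue stretch through the C-alpha atoms (strands and helix
# cylinders use positions smoothed over a 4-residue window), subdivided
# into four segments between consecutive residues. Cross sections:
# circles for tube (r = 0.75) and cartoon helix cylinders (r = 2.3),
# p4-symmetric octagons (width 1.5, thickness 0.4) for ribbons and
# strand arrows, tapering to a point over the final strand residue.
spline_segments <- function(obj, style) {
  res <- obj$residues
  if (is.null(res)) stop("spline styles need a residue table")
  ca <- vapply(seq_len(nrow(res)), function(i) {
    span <- res$start[i]:res$end[i]
    j <- span[obj$atoms$elety[span] == "CA"]
    if (length(j)) j[1] else span[1]
  }, 1L)
  P <- atom_xyz(obj$atoms)[ca, , drop = FALSE]
  n <- nrow(P)
  if (n < 2) stop("need at least two residues for a spline")
  smooth <- P
  if (style %in% c("ribbon", "cartoon")) {
    for (i in seq_len(n)) {
      w <- max(1, i - 1):min(n, i + 2)  # 4-residue window
      if (res$ss[i] %in% c("E")) smooth[i, ] <- colMeans(P[w, , drop = FALSE])
    }
  }
  cross_of <- function(i) {
    if (style == "tube") return(list(kind = "circle", r = 0.75))
    ss <- res$ss[i]
    if (style == "cartoon" && ss == "H") return(list(kind = "circle", r = 2.3))
    if (ss == "E") return(list(kind = "octagon", w = 1.5, th = 0.4))
    if (style == "ribbon") return(list(kind = "octagon", w = 1.5, th = 0.4))
    list(kind = "circle", r = 0.75)
  }
  segs <- list()
  # parallel-transported normal frame along the spline
  ref <- NULL
  for (i in seq_len(n - 1)) {
    p0 <- smooth[max(1, i - 1), ]; p1 <- smooth[i, ]
    p2 <- smooth[i + 1, ]; p3 <- smooth[min(n, i + 2), ]
    for (k in 0:3) {  # four segments between two residues
      t0 <- k / 4; t1 <- (k + 1) / 4
      a <- catmull_rom(p0, p1, p2, p3, t0)
      b <- catmull_rom(p0, p1, p2, p3, t1)
      ta <- catmull_rom_tangent(p0, p1, p2, p3, t0)
      tb <- catmull_rom_tangent(p0, p1, p2, p3, t1)
      if (vec_norm(ta) < 1e-9) ta <- b - a
      if (vec_norm(tb) < 1e-9) tb <- b - a
      ta <- unit(ta); tb <- unit(tb)
      if (is.null(ref)) {
        ref <- if (abs(ta[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        ref <- unit(ref - sum(ref * ta) * ta)
      }
      ua <- unit(ref - sum(ref * ta) * ta)
      ub <- unit(ua - sum(ua * tb) * tb)
      ref <- ub
      frac <- (i - 1 + t0) / (n - 1)
      cr <- cross_of(i)
      cr1 <- cr
      # strand arrow head: taper over the final residue of a strand run
      if (cr$kind == "octagon" && i == n - 1) {
        cr1$w <- cr$w * (1 - t1); cr1$th <- cr$th * (1 - t1) + 0.01
        cr$w <- cr$w * (1 - t0) + 0.01; cr$th <- cr$th * (1 - t0) + 0.01
      }
      segs[[length(segs) + 1]] <-
        list(p0 = a, p1 = b, t0 = ta, t1 = tb, u0 = ua, u1 = ub,
             cross0 = cr, cross1 = cr1)
    }
  }
  segs
}

# Piercing point of the ray through 2D point N (in-plane coordinates)
# normal to the nearest edge of the cross section; returns the 2D point.
cross_section_pierce <- function(N, cr) {
  if (cr$kind == "circle") {
    nr <- sqrt(sum(N^2))
    if (nr < 1e-12) return(c(cr$r, 0))
    return(N / nr * cr$r)
  }
  # p4-symmetric octagon = symmetrically chamfered rectangle with half
  # width w/2, half thickness th/2 and 45-degree corner cuts
  hw <- cr$w / 2; ht <- cr$th / 2
  ch <- min(hw, ht) * 0.5
  x <- abs(N[1]); y <- abs(N[2])
  # nearest side among: vertical (x = hw), horizontal (y = ht), chamfer
  d_v <- abs(x - hw); d_h <- abs(y - ht)
  d_c <- abs((x - (hw - ch)) + (y - (ht - ch))) / sqrt(2)
  side <- which.min(c(d_v, d_h, d_c))
  q <- if (side == 1) c(hw, min(y, ht - ch))
  else if (side == 2) c(min(x, hw - ch), ht)
  else {
    # 45-degree chamfer line x + y = hw + ht - ch; foot of normal from N
    s <- (x + y - (hw + ht - ch)) / 2
    c(x - s, y - s)
  }
  q * sign(N + 1e-15)
}

#' Estimate the signed distance from a point to a spline-segment surface
#'
#' Implements the cut-plane construction: the point is projected onto the
#' segment's two cut planes; in each plane, the ray through the projected
#' point normal to the nearest cross-section edge gives a piercing point;
#' the (signed) distance from the point to the line joining the two
#' piercing points estimates the distance to the surface, negative
#' inside. Exact for untapered circular segments.
#'
#' @param p length-3 point.
#' @param seg a spline segment from the internal segment builder (fields
#'   p0, p1, t0, t1, u0, u1, cross0, cross1).
#' @return signed distance in Angstrom.
#' @export
estimate_surface_distance <- function(p, seg) {
  pierce_in_plane <- function(c0, tan0, u0, cr) {
    v0 <- cross3(tan0, u0)
    rel <- p - sum((p - c0) * tan0) * tan0 - c0
    N <- c(sum(rel * u0), sum(rel * v0))
    q <- cross_section_pierce(N, cr)
    c0 + q[1] * u0 + q[2] * v0
  }
  Q0 <- pierce_in_plane(seg$p0, seg$t0, seg$u0, seg$cross0)
  Q1 <- pierce_in_plane(seg$p1, seg$t1, seg$u1, seg$cross1)
  dQ <- Q1 - Q0
  if (vec_norm(dQ) < 1e-12) {
    G <- Q0
  } else {
    s <- sum((p - Q0) * dQ) / sum(dQ * dQ)
    G <- Q0 + s * dQ
  }
  dist <- vec_norm(p - G)
  # sign: inside when the point is radially closer to the axis than the
  # interpolated boundary at the same axial fraction
  axis <- seg$p1 - seg$p0
  s_ax <- if (vec_norm(axis) < 1e-12) 0.5 else
    max(0, min(1, sum((p - seg$p0) * axis) / sum(axis * axis)))
  A <- seg$p0 + s_ax * (seg$p1 - seg$p0)
  B <- Q0 + s_ax * (Q1 - Q0)
  if (vec_norm(p - A) < vec_norm(B - A)) -dist else dist
}

# Flood-fill rasterisation of one segment: seeded at the grid point
# nearest the segment start, neighbours are visited while the local
# density is positive. Highest density (and its colour) wins overlaps.
rasterize_segment <- function(grid, seg, seg_id, color) {
  L <- grid$spacing
  seed_idx <- pmax(1, pmin(grid$dims,
                           round((seg$p0 - grid$origin) / L) + 1))
  key <- function(ijk) (ijk[1] - 1) + grid$dims[1] *
    ((ijk[2] - 1) + grid$dims[2] * (ijk[3] - 1)) + 1
  queue <- list(seed_idx)
  visited <- new.env(hash = TRUE)
  # slab bounds (inflated by L) to keep the fill local
  `%||%` <- function(a, b) if (is.null(a)) b else a
  mid <- (seg$p0 + seg$p1) / 2
  reach <- vec_norm(seg$p1 - seg$p0) / 2 +
    max(seg$cross0$r %||% seg$cross0$w, seg$cross1$r %||% seg$cross1$w) + 2 * L
  while (length(queue)) {
    ijk <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    kk <- as.character(key(ijk))
    if (!is.null(visited[[kk]])) next
    visited[[kk]] <- TRUE
    p <- grid$origin + (ijk - 1) * L
    if (vec_norm(p - mid) > reach) next
    d <- estimate_surface_distance(p, seg)
    dens <- density_byte(d, L)
    if (dens > grid$density[ijk[1], ijk[2], ijk[3]]) {
      grid$density[ijk[1], ijk[2], ijk[3]] <- dens
      grid$color[ijk[1], ijk[2], ijk[3]] <- color
      grid$segment[ijk[1], ijk[2], ijk[3]] <- seg_id
    }
    if (dens > 0) {
      for (dlt in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        nb <- ijk + dlt
        if (all(nb >= 1) && all(nb <= grid$dims) &&
            is.null(visited[[as.character(key(nb))]]))
          queue[[length(queue) + 1]] <- nb
      }
    }
  }
  grid
}

#' Downsample a LOD grid to half resolution
#'
#' Each coarse cell averages the densities of its eight children (odd
#' dimensions are zero-padded); the colour is the majority vote of the
#' eight child colours.
#'
#' @param grid a `lod_grid`.
#' @return a `lod_grid` with halved dimensions and doubled spacing.
#' @export
downsample_grid <- function(grid) {
  dims <- grid$dims
  pdims <- dims + dims %% 2L
  dens <- array(0L, pdims); col <- array(0L, pdims)
  dens[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- grid$density
  col[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- grid$color
  nd <- pdims %/% 2L
  newd <- array(0L, nd); newc <- array(0L, nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    chd <- dens[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    chc <- col[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    newd[i, j, k] <- as.integer(round(mean(chd)))
    tab <- table(chc)
    newc[i, j, k] <- as.integer(names(tab)[which.max(tab)])
  }
  out <- new_lod_grid(grid$origin, nd, grid$spacing * 2)
  out$density <- newd; out$color <- newc
  out
}

#' Extract an isosurface mesh from a LOD grid
#'
#' Marching-cubes extraction with tetrahedral cell decomposition (each
#' grid cube is split into six tetrahedra, avoiding the ambiguous cube
#' cases), at iso level 128. Vertices lie on grid edges at the linear
#' interpolation of the crossing; shared edge vertices are welded, so a
#' closed density blob gives a watertight mesh. Each vertex inherits the
#' colour of the denser edge endpoint.
#'
#' @param grid a `lod_grid`.
#' @param iso iso level (default 128, the surface distance 0 level).
#' @return a `tri_mesh` with `vertices`, `faces`, `vertex_colors`.
#' @export
extract_isosurface <- function(grid, iso = 128) {
  dens <- grid$density
  dims <- grid$dims
  if (all(dens < iso))
    return(structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3),
                          vertex_colors = integer(0)), class = "tri_mesh"))
  # six tetrahedra per cube over cube corner offsets (binary order)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  tets <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 5, 6, 8),
                c(1, 3, 4, 8), c(1, 3, 7, 8), c(1, 5, 7, 8))
  verts <- new.env(hash = TRUE)
  vlist <- list(); vcol <- integer(0)
  faces <- list()
  edge_vertex <- function(ijk_a, ijk_b) {
    ka <- paste(ijk_a, collapse = ","); kb <- paste(ijk_b, collapse = ",")
    key <- if (ka < kb) paste(ka, kb) else paste(kb, ka)
    got <- verts[[key]]
    if (!is.null(got)) return(got)
    da <- dens[ijk_a[1], ijk_a[2], ijk_a[3]]
    db <- dens[ijk_b[1], ijk_b[2], ijk_b[3]]
    t <- if (db == da) 0.5 else (iso - da) / (db - da)
    pa <- grid$origin + (ijk_a - 1) * grid$spacing
    pb <- grid$origin + (ijk_b - 1) * grid$spacing
    vlist[[length(vlist) + 1]] <<- pa + t * (pb - pa)
    vcol[length(vlist)] <<- if (da >= db)
      grid$color[ijk_a[1], ijk_a[2], ijk_a[3]]
    else grid$color[ijk_b[1], ijk_b[2], ijk_b[3]]
    verts[[key]] <- length(vlist)
    length(vlist)
  }
  # only march over cubes that touch the surface
  active <- which(dens >= iso, arr.ind = TRUE)
  if (nrow(active) == 0)
    return(structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3),
                          vertex_colors = integer(0)), class = "tri_mesh"))
  cubes <- new.env(hash = TRUE)
  for (r in seq_len(nrow(active))) {
    base <- active[r, ]
    for (dx in -1:0) for (dy in -1:0) for (dz in -1:0) {
      cb <- base + c(dx, dy, dz)
      if (any(cb < 1) || any(cb + 1 > dims)) next
      cubes[[paste(cb, collapse = ",")]] <- cb
    }
  }
  for (nm in ls(cubes)) {
    cb <- cubes[[nm]]
    cidx <- sweep(corner, 2, cb, "+")
    cval <- dens[cidx]
    for (tt in seq_len(nrow(tets))) {
      tv <- tets[tt, ]
      inside <- cval[tv] >= iso
      ni <- sum(inside)
      if (ni == 0 || ni == 4) next
      ins <- tv[inside]; outs <- tv[!inside]
      ev <- function(a, b) edge_vertex(cidx[a, ], cidx[b, ])
      if (ni == 1) {
        faces[[length(faces) + 1]] <- c(ev(ins[1], outs[1]),
                                        ev(ins[1], outs[2]),
                                        ev(ins[1], outs[3]))
      } else if (ni == 3) {
        faces[[length(faces) + 1]] <- c(ev(ins[1], outs[1]),
                                        ev(ins[2], outs[1]),
                                        ev(ins[3], outs[1]))
      } else {
        a <- ev(ins[1], outs[1]); b <- ev(ins[1], outs[2])
        cc <- ev(ins[2], outs[2]); dd <- ev(ins[2], outs[1])
        faces[[length(faces) + 1]] <- c(a, b, cc)
        faces[[length(faces) + 1]] <- c(a, cc, dd)
      }
    }
  }
  structure(list(vertices = do.call(rbind, vlist),
                 faces = do.call(rbind, faces),
                 vertex_colors = vcol), class = "tri_mesh")
}

# V - E + F of a triangle mesh (edges counted once).
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

# Connected components of mesh faces via shared vertices.
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  bonds <- unique(rbind(mesh$faces[, 1:2], mesh$faces[, 2:3],
                        mesh$faces[, c(3, 1)]))
  comp <- bond_components(n, bonds)
  length(unique(comp[unique(as.vector(mesh$faces))]))
}
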