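# Transmembrane-element detection, membrane orientation, and construction
# of pet membrane blocks (two systematic layers of 1.2 A pet atoms in
# rectangle / rhombus / triangle footprints).

.lipid_residues <- c("POPC", "POPE", "POPS", "DOPC", "DOPE", "DOPS",
                     "DPPC", "DPPE", "DMPC", "PC", "PE", "PS", "CHL",
                     "CHL1", "CLR", "CHOL")

#' Transmembrane detection criteria
#'
#' Hydrophobic and strongly polar residue sets, the exposure threshold
#' (side-chain surface > 20% of maximum), and the length / exposed-count
#' windows: strands 7-14 residues with more than 3 exposed hydrophobics,
#' helices 12-29 residues with more than 4; a helix "side" is a 120-degree
#' sector of its circumference.
#'
#' @return list of criteria constants.
#' @export
tm_criteria <- function() {
  list(hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TYR", "TRP"),
       strongly_polar = c("ASN", "GLN", "LYS", "ARG", "ASP", "GLU"),
       exposure_fraction = 0.20,
       strand_len = c(7, 14), strand_min_exposed = 3,
       helix_len = c(12, 29), helix_min_exposed = 4,
       helix_sector_deg = 120)
}

# Maximum side-chain solvent accessibility (A^2) in an extended Gly-X-Gly
# context; theoretical values of Tien et al. (2013).
.max_sidechain_sasa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193,
                         CYS = 167, GLN = 225, GLU = 223, GLY = 104,
                         HIS = 224, ILE = 197, LEU = 201, LYS = 236,
                         MET = 224, PHE = 240, PRO = 159, SER = 155,
                         THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA with a rolling probe: each atom's sphere (vdW + probe
#' radius) is sampled with quasi-uniform points and the accessible
#' fraction scaled to the sphere area.
#'
#' @param atoms atom table.
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points sample points per atom sphere.
#' @return per-atom SASA in square Angstrom.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 96) {
  xyz <- atom_xyz(atoms)
  r <- atoms$radius + probe
  n <- nrow(xyz)
  # Fibonacci sphere points
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sp <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  out <- numeric(n)
  # neighbour lists via cutoff on centre distance
  d <- as.matrix(stats::dist(xyz))
  for (a in seq_len(n)) {
    nb <- which(d[a, ] < r[a] + r & seq_len(n) != a)
    pts <- sweep(sp * r[a], 2, xyz[a, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (b in nb) {
        dd <- sweep(pts, 2, xyz[b, ])
        acc <- acc & rowSums(dd^2) > r[b]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[a] <- frac * 4 * pi * r[a]^2
  }
  out
}

# Per-residue side-chain exposure fraction (side-chain SASA / maximum).
residue_exposure <- function(obj) {
  res <- obj$residues
  if (is.null(res)) stop("object has no residue table")
  sasa <- shrake_rupley_sasa(obj$atoms)
  vapply(seq_len(nrow(res)), function(i) {
    span <- res$start[i]:res$end[i]
    side <- span[!obj$atoms$elety[span] %in% c("N", "CA", "C", "O")]
    if (length(side) == 0) return(0)
    mx <- .max_sidechain_sasa[res$name[i]]
    if (is.na(mx)) mx <- 200
    sum(sasa[side]) / mx
  }, 0)
}

# Regression line (principal axis) through a point set; direction points
# from the first to the last point.
regression_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  dir <- svd(sweep(xyz, 2, ctr))$v[, 1]
  if (sum(dir * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) dir <- -dir
  list(point = ctr, direction = unit(dir))
}

# Smallest arc (degrees) containing a set of angles (radians).
min_enclosing_arc <- function(ang) {
  if (length(ang) <= 1) return(0)
  a <- sort(ang %% (2 * pi))
  gaps <- diff(c(a, a[1] + 2 * pi))
  rad2deg(2 * pi - max(gaps))
}

#' Detect transmembrane secondary-structure elements
#'
#' Scans maximal helix/strand stretches for candidates whose exposed
#' residues (side-chain surface over 20% of the residue maximum) include
#' enough hydrophobics on one side while no strongly polar residue is
#' exposed on that side. For helices the "side" is a 120-degree sector
#' around the helix axis; for strands it is one of the two alternating
#' faces. A regression line through the C-alpha atoms of each accepted
#' element gives its axis.
#'
#' @param obj protein `pet_object` with a `residues` table (needs `ss`).
#' @param exposure optional per-residue side-chain exposure fractions;
#'   computed with [shrake_rupley_sasa()] when omitted.
#' @return list of segments: each has `range` (residue indices), `kind`
#'   ("helix"/"strand"), `axis` (list point/direction).
#' @export
detect_tm_elements <- function(obj, exposure = NULL) {
  crit <- tm_criteria()
  res <- obj$residues
  if (is.null(res)) stop("object has no residue/secondary-structure table")
  if (is.null(exposure)) exposure <- residue_exposure(obj)
  ca_idx <- vapply(seq_len(nrow(res)), function(i) {
    span <- res$start[i]:res$end[i]
    j <- span[obj$atoms$elety[span] == "CA"]
    if (length(j) == 0) NA_integer_ else j[1]
  }, 1L)
  sc_idx <- vapply(seq_len(nrow(res)), function(i) {
    span <- res$start[i]:res$end[i]
    j <- span[!obj$atoms$elety[span] %in% c("N", "CA", "C", "O")]
    if (length(j) == 0) NA_integer_ else j[1]
  }, 1L)
  xyz <- atom_xyz(obj$atoms)
  res_chain <- obj$atoms$chain[res$start]
  runs <- rle(paste(res$ss, res_chain))
  runs$values <- sub(" .*$", "", runs$values)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  segs <- list()
  for (k in seq_along(runs$values)) {
    ss <- runs$values[k]
    if (!ss %in% c("H", "E")) next
    rng <- starts[k]:ends[k]
    if (any(is.na(ca_idx[rng]))) {
      warning("residues without C-alpha skipped in segment ", k)
      rng <- rng[!is.na(ca_idx[rng])]
    }
    len <- length(rng)
    bounds <- if (ss == "H") crit$helix_len else crit$strand_len
    if (len < bounds[1] || len > bounds[2]) next
    exposed <- exposure[rng] > crit$exposure_fraction
    hyd <- res$name[rng] %in% crit$hydrophobic
    pol <- res$name[rng] %in% crit$strongly_polar
    min_exp <- if (ss == "H") crit$helix_min_exposed else crit$strand_min_exposed
    if (any(pol)) next          # segment shows a strongly polar residue
    if (sum(exposed & hyd) <= min_exp) next
    axis <- regression_axis(xyz[ca_idx[rng], , drop = FALSE])
    if (ss == "H") {
      # one-sidedness: some 120-degree sector around the axis in which
      # every exposed side chain is hydrophobic
      e1 <- unit(cross3(axis$direction,
                        if (abs(axis$direction[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
      e2 <- cross3(axis$direction, e1)
      ang_of <- function(i) {
        v <- xyz[sc_idx[i], ] - (axis$point +
          sum((xyz[sc_idx[i], ] - axis$point) * axis$direction) * axis$direction)
        atan2(sum(v * e2), sum(v * e1))
      }
      exp_i <- rng[exposed & !is.na(sc_idx[rng])]
      if (length(exp_i)) {
        a_e <- vapply(exp_i, ang_of, 0)
        e_hyd <- hyd[match(exp_i, rng)]
        half <- deg2rad(crit$helix_sector_deg / 2)
        ok_side <- FALSE
        for (ctr in seq(0, 2 * pi, by = deg2rad(5))) {
          dif <- (a_e - ctr + pi) %% (2 * pi) - pi
          in_sec <- abs(dif) <= half
          if (any(in_sec) && all(e_hyd[in_sec])) { ok_side <- TRUE; break }
        }
        if (!ok_side) next
      }
    } else {
      # strand faces alternate with residue parity
      face <- rng %% 2
      ok_face <- FALSE
      for (f in 0:1) {
        on <- face == f
        if (sum(exposed & hyd & on) > 0 && all(hyd[exposed & on])) {
          ok_face <- TRUE; break
        }
      }
      if (!ok_face) next
    }
    segs[[length(segs) + 1]] <- list(range = rng,
                                     kind = if (ss == "H") "helix" else "strand",
                                     axis = axis)
  }
  segs
}

#' Orient a protein for membrane embedding
#'
#' Sign-corrects the transmembrane segment axes (each flipped to agree
#' with the first), sums them, and returns the rotation that takes the
#' resulting direction onto +Z — so the membrane normal is the summed
#' axis direction. The rotated protein is then scanned along Z with a
#' sliding slab to find the band with the largest weighted count of
#' exposed hydrophobic residues, TM-segment residues counting five times.
#'
#' @param obj protein `pet_object` with residues.
#' @param segments output of [detect_tm_elements()].
#' @param exposure optional per-residue exposure fractions.
#' @param slab_thickness scan slab thickness in Angstrom (default 30).
#' @param step scan step in Angstrom (default 1).
#' @return list with `rotation` (3x3), `z_band` (c(lo, hi) after
#'   rotation), `normal` (the membrane normal before rotation).
#' @export
orient_for_membrane <- function(obj, segments, exposure = NULL,
                                slab_thickness = 30, step = 1) {
  if (length(segments) == 0) stop("at least one transmembrane segment needed")
  dirs <- lapply(segments, function(s) s$axis$direction)
  ref <- dirs[[1]]
  total <- c(0, 0, 0)
  for (d in dirs) total <- total + if (sum(d * ref) < 0) -d else d
  if (vec_norm(total) < 1e-9) {
    warning("segment axes cancel; falling back to the first segment axis")
    total <- ref
  }
  normal <- unit(total)
  R <- rotation_between(normal, c(0, 0, 1))
  res <- obj$residues
  if (is.null(exposure)) exposure <- residue_exposure(obj)
  crit <- tm_criteria()
  xyz <- atom_xyz(obj$atoms) %*% t(R)
  res_z <- vapply(seq_len(nrow(res)), function(i)
    mean(xyz[res$start[i]:res$end[i], 3]), 0)
  in_tm <- seq_len(nrow(res)) %in% unlist(lapply(segments, `[[`, "range"))
  wt <- ifelse(res$name %in% crit$hydrophobic &
                 exposure > crit$exposure_fraction,
               ifelse(in_tm, 5, 1), 0)
  zs <- seq(min(res_z), max(max(res_z) - slab_thickness, min(res_z)), by = step)
  score <- vapply(zs, function(z0)
    sum(wt[res_z >= z0 & res_z <= z0 + slab_thickness]), 0)
  best <- zs[which.max(score)]
  list(rotation = R, z_band = c(best, best + slab_thickness), normal = normal)
}

#' Build a pet membrane block
#'
#' Places 1.2 A pet atoms systematically in two planar hexagonal layers
#' filling a rectangle, 60/120-degree rhombus, or equilateral triangle
#' (half rhombus) footprint. Lattice spacing is 2.4 A (pet scale) so that
#' neighbouring atoms touch; bonds connect touching neighbours within a
#' layer and nearest partners across the two layers.
#'
#' @param shape "rectangle", "rhombus" or "triangle".
#' @param size rectangle: c(width, height); rhombus/triangle: side length
#'   (pet Angstrom).
#' @param layer_gap distance between the two layer planes (pet Angstrom).
#' @param spacing in-layer lattice spacing (default 2.4 = two pet radii).
#' @return a pet-kind `pet_object` with shape metadata in `$block`.
#' @export
build_pet_membrane_block <- function(shape = c("rectangle", "rhombus",
                                               "triangle"),
                                     size = 10, layer_gap = 4,
                                     spacing = 2.4) {
  shape <- match.arg(shape)
  if (min(size) <= 0) stop("size must be positive")
  w <- size[1]; h <- if (length(size) > 1) size[2] else size[1]
  poly <- switch(shape,
    rectangle = rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
    rhombus = rbind(c(0, 0), c(w, 0), c(w + w * cos(pi / 3), w * sin(pi / 3)),
                    c(w * cos(pi / 3), w * sin(pi / 3))),
    triangle = rbind(c(0, 0), c(w, 0), c(w * cos(pi / 3), w * sin(pi / 3))))
  # hexagonal lattice covering the polygon bounding box
  ry <- spacing * sin(pi / 3)
  bb_lo <- apply(poly, 2, min); bb_hi <- apply(poly, 2, max)
  if (bb_hi[1] - bb_lo[1] < spacing || bb_hi[2] - bb_lo[2] < ry)
    stop("block size smaller than one lattice cell")
  pts <- list()
  row <- 0
  for (y in seq(bb_lo[2] + ry / 2, bb_hi[2], by = ry)) {
    xoff <- if (row %% 2 == 1) spacing / 2 else 0
    for (x in seq(bb_lo[1] + spacing / 2 + xoff, bb_hi[1], by = spacing))
      pts[[length(pts) + 1]] <- c(x, y)
    row <- row + 1
  }
  pts <- do.call(rbind, pts)
  keep <- point_in_polygon(pts, poly)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) stop("block size smaller than one lattice cell")
  xyz <- rbind(cbind(pts, -layer_gap / 2), cbind(pts, layer_gap / 2))
  atoms <- atom_table(element = "OC", xyz = xyz, bfactor = 0, resid = "PMB")
  # in-layer touching neighbours + nearest inter-layer partner
  d <- as.matrix(stats::dist(xyz))
  bonds <- which(d < spacing * 1.05 & upper.tri(d), arr.ind = TRUE)
  n1 <- nrow(pts)
  inter <- cbind(seq_len(n1), n1 + seq_len(n1))
  bonds <- unique(rbind(unname(bonds), inter))
  obj <- molecular_object("membrane_block", atoms, bonds, kind = "pet")
  obj$block <- list(shape = shape, size = size, layer_gap = layer_gap,
                    polygon = poly, spacing = spacing)
  obj
}

# Even-odd point-in-polygon test with a small boundary tolerance (points
# on the edge count as inside, so the lattice stays flush with the
# boundary without double-counting between adjacent blocks).
point_in_polygon <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, 1]; y <- pts[p, 2]
    cnt <- FALSE; on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
      # edge hit test
      ex <- xj - xi; ey <- yj - yi
      t <- ((x - xi) * ex + (y - yi) * ey) / (ex^2 + ey^2)
      if (t >= 0 && t <= 1) {
        dd <- (x - (xi + t * ex))^2 + (y - (yi + t * ey))^2
        if (dd < tol) on_edge <- TRUE
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) cnt <- !cnt
      j <- i
    }
    inside[p] <- cnt || on_edge
  }
  inside
}

#' Classify an all-atom lipid object as a membrane block
#'
#' Requires a considerable phospholipid content (at least 25% of atoms in
#' whitelisted lipid residues). The lipid atoms are split into two
#' leaflets along the membrane normal (the smallest principal axis); the
#' in-plane convex hull is compared against rectangle, rhombus and
#' triangle footprints by its bounding-box fill fraction.
#'
#' @param obj all-atom `pet_object`.
#' @return list with `shape`, `size` (real-scale Angstrom), `layer_z`
#'   (per-leaflet mean z).
#' @export
classify_membrane_block <- function(obj) {
  lipid <- obj$atoms$resid %in% .lipid_residues
  if (mean(lipid) < 0.25)
    stop("object does not contain a considerable amount of phospholipids")
  classify_membrane_block_atoms(obj$atoms[lipid, , drop = FALSE])
}

classify_membrane_block_atoms <- function(atoms) {
  xyz <- atom_xyz(atoms)
  ctr <- colMeans(xyz)
  pc <- svd(sweep(xyz, 2, ctr))$v
  # membrane normal: the principal axis along which the headgroup atoms
  # split into two separated leaflets (largest empty mid-gap)
  heads <- atoms$elety == "P" | atoms$element == "P"
  hx <- if (sum(heads) >= 4) xyz[heads, , drop = FALSE] else xyz
  midgap <- vapply(1:3, function(a) {
    p <- sort(as.vector(sweep(hx, 2, ctr) %*% pc[, a]))
    q <- p[p >= stats::quantile(p, 0.25) & p <= stats::quantile(p, 0.75)]
    if (length(q) < 2) 0 else max(diff(q))
  }, 0)
  ni <- which.max(midgap)
  # a bilayer shows two well-separated headgroup planes along the normal;
  # in-plane lattice gaps are on the order of one lipid spacing, leaflet
  # separations tens of Angstrom
  if (midgap[ni] < 12) stop("monolayer: only one leaflet found")
  normal <- pc[, ni]
  pc <- cbind(pc[, setdiff(1:3, ni), drop = FALSE], normal)
  z <- as.vector(sweep(xyz, 2, ctr) %*% normal)
  upper <- z > 0
  if (!any(upper) || all(upper)) stop("monolayer: only one leaflet found")
  layer_z <- c(mean(z[!upper]), mean(z[upper])) + sum(ctr * normal)
  uv <- sweep(xyz, 2, ctr) %*% pc[, 1:2]
  hull <- grDevices::chull(uv)
  hp <- uv[hull, , drop = FALSE]
  area <- polygon_area(hp)
  # minimum-area enclosing rectangle: one side is flush with a hull edge
  edges <- diff(rbind(hp, hp[1, , drop = FALSE]))
  best <- NULL
  for (r in seq_len(nrow(edges))) {
    e <- edges[r, ]
    if (sum(e^2) < 1e-12) next
    th <- -atan2(e[2], e[1])
    Rz <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    hr <- hp %*% Rz
    wh_r <- apply(hr, 2, function(c0) diff(range(c0)))
    if (is.null(best) || prod(wh_r) < best$area)
      best <- list(area = prod(wh_r), wh = wh_r, th = th)
  }
  wh <- sort(best$wh, decreasing = TRUE)
  fill <- area / best$area
  # account for the half-cell inset of the lipid lattice: in-plane
  # nearest-neighbour spacing of one leaflet's headgroups
  lip_idx <- which(if (any(heads)) heads & z > 0 else z > 0)
  lip_idx <- lip_idx[seq_len(min(150, length(lip_idx)))]
  duv <- as.matrix(stats::dist(uv[lip_idx, , drop = FALSE]))
  nn <- stats::median(apply(duv, 1, function(r) min(r[r > 1e-6])))
  shape <- if (fill > 0.85) "rectangle" else if (fill > 0.55) "rhombus"
  else "triangle"
  size <- switch(shape,
    rectangle = wh + nn,
    rhombus = (wh[2] + nn) / sin(pi / 3),
    triangle = wh[1] + nn)
  list(shape = shape, size = size, layer_z = layer_z, fill = fill)
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
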