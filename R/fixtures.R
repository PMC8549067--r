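# Deterministic generators of synthetic test inputs: globular atom clouds,
# ideal helix bundles, pseudo-lipid bilayers, icosphere meshes and random
# sequences. Every generator takes a seed and restores the caller's RNG
# state, so identical calls are bitwise reproducible.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic globular atom cloud
#'
#' Packs `n_atoms` atoms into a sphere at protein-like density
#' (0.09 atoms per cubic Angstrom) with element identities drawn at
#' H/C/N/O proportions and Bondi vdW radii. Atoms sit on a jittered cubic
#' lattice, which enforces a minimum separation while matching the target
#' density; the innermost `n_atoms` lattice sites are used so the cloud is
#' approximately a uniform ball.
#'
#' @param n_atoms number of atoms (>= 10).
#' @param seed RNG seed.
#' @param density target number density in atoms per cubic Angstrom.
#' @return a `pet_object` of kind "protein".
#' @export
make_globular_cloud <- function(n_atoms, seed = 0, density = 0.09) {
  if (n_atoms < 10) stop("n_atoms must be >= 10")
  a <- density^(-1 / 3)  # lattice constant giving the target density
  with_seed(seed, {
    half <- ceiling((n_atoms * 3 / (4 * pi))^(1 / 3)) + 2
    g <- expand.grid(x = -half:half, y = -half:half, z = -half:half)
    pts <- as.matrix(g) * a
    d2 <- rowSums(pts^2)
    keep <- order(d2)[seq_len(n_atoms)]
    pts <- pts[keep, , drop = FALSE]
    # jitter inside each cell, keeping lattice separation positive
    pts <- pts + matrix(runif(3 * n_atoms, -0.25, 0.25) * a, ncol = 3)
    el <- sample(c("H", "C", "N", "O"), n_atoms, replace = TRUE,
                 prob = c(0.50, 0.32, 0.085, 0.095))
    atoms <- atom_table(element = el, xyz = pts,
                        charge = round(runif(n_atoms, -0.4, 0.4), 3),
                        resid = "GLB", resno = rep(seq_len(ceiling(n_atoms / 8)),
                                                   each = 8)[seq_len(n_atoms)])
    molecular_object("globular_cloud", atoms, kind = "protein")
  })
}

#' Ideal alpha-helix bundle with pseudo side chains
#'
#' Builds `n_helices` ideal alpha helices (rise 1.5 A per residue, 100
#' degrees per residue, C-alpha radius 2.3 A) arranged on a circle, each
#' tilted by +/- `tilt` degrees from the z axis. Every residue carries a
#' C-alpha atom plus one pseudo side-chain centroid atom pointing radially
#' outward; residue identities follow `sequence_pattern` (three-letter
#' codes, recycled). All residues are labelled helix ("H").
#'
#' @param n_helices number of helices.
#' @param length residues per helix (5-50).
#' @param tilt tilt magnitude in degrees, alternating sign per helix.
#' @param sequence_pattern character vector of three-letter residue names.
#' @param seed RNG seed (used only for reproducible lateral dither).
#' @return a `pet_object` of kind "protein" with a `residues` table.
#' @export
make_helix_bundle <- function(n_helices = 1, length = 20, tilt = 0,
                              sequence_pattern = "LEU", seed = 0) {
  if (length < 5 || length > 50) stop("helix length must be in 5..50")
  with_seed(seed, {
    resnames <- rep_len(sequence_pattern, length)
    rows <- list(); resdf <- list(); resno <- 0L
    ring_r <- if (n_helices > 1) 8 else 0
    for (h in seq_len(n_helices)) {
      phi <- 2 * pi * (h - 1) / max(1, n_helices)
      center <- c(ring_r * cos(phi), ring_r * sin(phi), 0)
      sgn <- if (h %% 2 == 0) -1 else 1
      Rtilt <- rotation_about_axis(c(cos(phi + pi / 2), sin(phi + pi / 2), 0),
                                   deg2rad(sgn * tilt))
      for (i in seq_len(length)) {
        ang <- deg2rad(100 * (i - 1))
        ca_local <- c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1) - 1.5 * length / 2)
        sc_local <- c(4.2 * cos(ang), 4.2 * sin(ang), ca_local[3])
        ca <- as.vector(Rtilt %*% ca_local) + center
        sc <- as.vector(Rtilt %*% sc_local) + center
        resno <- resno + 1L
        rows[[2 * resno - 1]] <- c(ca, resno)
        rows[[2 * resno]] <- c(sc, resno)
        resdf[[resno]] <- resnames[i]
      }
    }
    m <- do.call(rbind, rows)
    n <- nrow(m)
    atoms <- atom_table(element = rep(c("C", "C"), n / 2), xyz = m[, 1:3],
                        elety = rep(c("CA", "CB"), n / 2),
                        resid = rep(unlist(resdf), each = 2),
                        resno = m[, 4],
                        chain = rep(LETTERS[rep(seq_len(n_helices),
                                                each = length)], each = 2))
    residues <- data.frame(name = unlist(resdf),
                           start = seq(1, n, by = 2), end = seq(2, n, by = 2),
                           ss = "H", stringsAsFactors = FALSE)
    molecular_object("helix_bundle", atoms, kind = "protein",
                     residues = residues)
  })
}

#' Icosphere triangle mesh
#'
#' Subdivides an icosahedron `subdivisions` times and projects vertices to
#' the unit sphere, giving 20 * 4^s near-equilateral faces.
#'
#' @param subdivisions integer 0-5.
#' @param radius sphere radius in Angstrom.
#' @return a `tri_mesh`: list with `vertices` (n x 3) and `faces` (m x 3).
#' @export
make_icosphere <- function(subdivisions = 0, radius = 1) {
  if (subdivisions < 0 || subdivisions > 5) stop("subdivisions must be 0..5")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env()
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- unit((vlist[[a]] + vlist[[b]]) / 2)
      vlist[[length(vlist) + 1]] <<- m
      midcache[[key]] <- length(vlist)
      length(vlist)
    }
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- c(nf, list(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                       c(ab, bc, ca)))
    }
    v <- do.call(rbind, vlist)
    f <- do.call(rbind, nf)
  }
  structure(list(vertices = v * radius, faces = f), class = "tri_mesh")
}

#' Pseudo-lipid bilayer slab
#'
#' Two leaflets of pseudo-lipid residues (each a phosphorus headgroup atom
#' plus two tail carbons) with headgroup z near +/-20 Angstrom, on an
#' in-plane lattice covering the requested footprint. Residues are named
#' "POPC" so the lipid whitelist recognises them.
#'
#' @param footprint for "rectangle": c(width, height) in Angstrom (a single
#'   number is used for both); for "rhombus"/"triangle": side length.
#' @param shape "rectangle", "rhombus" or "triangle".
#' @param seed RNG seed for in-plane dither.
#' @param spacing in-plane lipid lattice spacing in Angstrom.
#' @return a `pet_object` of kind "membrane_block".
#' @export
make_bilayer <- function(footprint = 60, shape = c("rectangle", "rhombus",
                                                   "triangle"),
                         seed = 0, spacing = 8) {
  shape <- match.arg(shape)
  if (min(footprint) < 20) stop("footprint must be >= 20 Angstrom")
  w <- footprint[1]; h <- if (length(footprint) > 1) footprint[2] else w
  with_seed(seed, {
    g <- expand.grid(u = seq(spacing / 2, w - spacing / 2, by = spacing),
                     v = seq(spacing / 2, h - spacing / 2, by = spacing))
    # map lattice coords into the footprint shape
    if (shape == "rectangle") {
      xy <- cbind(g$u, g$v)
    } else {
      # shear the square lattice to a 60/120-degree rhombus
      xy <- cbind(g$u + g$v * cos(pi / 3), g$v * sin(pi / 3))
      if (shape == "triangle") {
        keep <- g$u + g$v <= w  # lower-left half of the rhombus
        xy <- xy[keep, , drop = FALSE]
      }
    }
    n_lip <- nrow(xy)
    rows <- list(); k <- 0
    for (leaf in c(1, -1)) for (i in seq_len(n_lip)) {
      k <- k + 1
      jit <- runif(2, -0.5, 0.5)
      x <- xy[i, 1] + jit[1]; y <- xy[i, 2] + jit[2]
      rows[[k]] <- rbind(c(x, y, leaf * 20), c(x, y, leaf * 12),
                         c(x, y, leaf * 5))
    }
    m <- do.call(rbind, rows)
    nres <- 2 * n_lip
    atoms <- atom_table(element = rep(c("P", "C", "C"), nres), xyz = m,
                        elety = rep(c("P", "C2", "C3"), nres),
                        resid = "POPC", resno = rep(seq_len(nres), each = 3))
    molecular_object("bilayer", atoms, kind = "membrane_block")
  })
}

#' Random nucleotide sequence
#'
#' @param n sequence length.
#' @param alphabet "dna" or "rna".
#' @param seed RNG seed.
#' @return single character string.
#' @export
make_random_sequence <- function(n, alphabet = c("dna", "rna"), seed = 0) {
  alphabet <- match.arg(alphabet)
  letters <- if (alphabet == "dna") c("A", "C", "G", "T") else
    c("A", "C", "G", "U")
  with_seed(seed, paste(sample(letters, n, replace = TRUE), collapse = ""))
}
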