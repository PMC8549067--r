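# Shared helpers for the test suite: small deterministic inputs and
# independent (brute-force) oracles kept separate from the implementation
# paths they check.

xyz_of <- function(obj) as.matrix(obj$atoms[, c("x", "y", "z")])

# Independent recount of the probe counts at one grid position: loops
# over every grid point and classifies it against the probe sphere and
# its two-point shell. Used as the oracle for sweep_scores.
brute_counts <- function(grid, centre, radius) {
  dims <- dim(grid$inside)
  ic <- dc <- oc <- 0L
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      d <- sqrt(sum((c(x, y, z) - centre)^2)) * grid$spacing
      if (d <= radius) {
        if (grid$inside[x, y, z]) ic <- ic + 1L
        if (grid$covered[x, y, z]) dc <- dc + 1L
      } else if (d <= radius + 2 * grid$spacing) {
        if (grid$inside[x, y, z]) oc <- oc + 1L
      }
    }
  c(ic = ic, dc = dc, oc = oc)
}

# Small random density grid (16^3 or smaller) with given fractions of
# inside and covered flags.
random_test_grid <- function(dims = c(12, 12, 12), seed = 1,
                             p_inside = 0.4, p_covered = 0.1,
                             spacing = 0.65536) {
  set.seed(seed)
  structure(list(spacing = spacing, origin = c(0, 0, 0), dims = dims,
                 inside = array(runif(prod(dims)) < p_inside, dims),
                 covered = array(runif(prod(dims)) < p_covered, dims)),
            class = "density_grid")
}

# Naive term-by-term energy evaluation, written independently of
# energy_and_forces (plain loops, explicit formulas).
naive_energy <- function(atoms, terms, cutoff = 3) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  vlen <- function(v) sqrt(sum(v^2))
  e <- 0
  b <- terms$bonds
  for (r in seq_len(nrow(b)))
    e <- e + b$k[r] * (vlen(xyz[b$i[r], ] - xyz[b$j[r], ]) - b$r0[r])^2
  a <- terms$angles
  for (r in seq_len(nrow(a))) {
    v1 <- xyz[a$i[r], ] - xyz[a$j[r], ]; v2 <- xyz[a$k[r], ] - xyz[a$j[r], ]
    th <- acos(max(-1, min(1, sum(v1 * v2) / (vlen(v1) * vlen(v2)))))
    e <- e + a$k_force[r] * (th - a$theta0[r])^2
  }
  d <- terms$dihedrals
  for (r in seq_len(nrow(d))) {
    p <- xyz[c(d$i[r], d$j[r], d$k[r], d$l[r]), ]
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    phi <- atan2(sum(cr(n1, n2) * b2) / vlen(b2), sum(n1 * n2))
    e <- e + d$pk[r] / d$idiv[r] * (1 + cos(d$pn[r] * phi - d$phase[r]))
  }
  ex <- terms$excluded_pairs
  exset <- if (nrow(ex)) paste(ex[, 1], ex[, 2]) else character(0)
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% exset) next
    rij <- vlen(xyz[i, ] - xyz[j, ])
    if (rij > cutoff) next
    rmin <- atoms$radius[i] + atoms$radius[j]
    e <- e + terms$ff$vdw_eps * ((rmin / rij)^12 - 2 * (rmin / rij)^6)
    e <- e + 332.0636 * atoms$charge[i] * atoms$charge[j] / rij
  }
  e
}

# A straight poly-residue "chain" object with CA atoms on the x axis,
# for spline/tube rasterisation tests.
straight_chain <- function(n = 10, step = 3.8) {
  xyz <- cbind(seq(0, by = step, length.out = n), 0, 0)
  atoms <- atom_table(element = "C", xyz = xyz, elety = "CA",
                      resid = "GLY", resno = seq_len(n))
  residues <- data.frame(name = "GLY", start = seq_len(n), end = seq_len(n),
                         ss = "C", stringsAsFactors = FALSE)
  molecular_object("chain", atoms, kind = "protein", residues = residues)
}
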