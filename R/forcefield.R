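# AMBER-functional-form parameter assignment for pet molecules, energy
# evaluation and desk-scale minimization / multiple-time-step dynamics.
#
# Functional forms: E_bond = k (r - r0)^2 with k = 575 kcal/(mol A^2);
# E_angle = k (theta - theta0)^2 with k = 300 kcal/(mol rad^2);
# E_dihedral = (pk/idiv) (1 + cos(pn phi - phase)) with pk = 5 kcal/mol,
# pn = 1, idiv = 1 and phase = equilibrium dihedral + pi (so the term
# vanishes at the equilibrium). Nonbonded: 12-6 vdW with rmin = ri + rj
# and a single well depth, truncated Coulomb; 1-2 and 1-3 pairs excluded.

#' Force-field defaults for pet atoms
#'
#' @return list of default constants: atom `types` (12 rows), `bond_k`
#'   (kcal/(mol A^2)), `angle_k` (kcal/(mol rad^2)), `dihedral_pk`
#'   (kcal/mol), `pn`, `idiv`, `mass` (u, same for all pet atoms),
#'   `cutoff` (A), `vdw_eps` (kcal/mol), `dt_bonded`/`dt_nonbonded` (fs),
#'   `charge_scale` (pet charge = summed source charges x 0.1).
#' @export
ff_defaults <- function() {
  list(types = pet_elements(), bond_k = 575, angle_k = 300,
       dihedral_pk = 5, pn = 1, idiv = 1, mass = 8, cutoff = 3,
       vdw_eps = 0.05, dt_bonded = 0.5, dt_nonbonded = 1,
       charge_scale = 0.1, angle_window_deg = c(20, 160))
}

#' Assign force-field terms to a bonded pet molecule
#'
#' Equilibria come from the construction coordinates for pet atoms with
#' B-factor 0 (shrunk from known structures); any term touching a
#' sequence-built atom (B-factor > 0) takes its equilibrium from the
#' nucleic-acid geometry table instead (distances scaled by 0.1 to the
#' pet scale). Angle terms are skipped inside 3-rings, reduced to two
#' neighbouring terms inside 4-rings, and excluded when the equilibrium
#' is below 20 or above 160 degrees (force singularities at 0/180). A
#' dihedral A-B-C-D is added only when A has fewer than four bonds and B
#' exactly two, with phase = current dihedral + pi; dihedrals over
#' excluded angle triplets are dropped. For the double-strand axis model
#' the 180-degree main-main-main angle is replaced by two 90-degree
#' main-main-helper angles and the helper-main-main-helper dihedral is
#' set to three times the helical twist.
#'
#' @param pet bonded pet `pet_object`.
#' @param geom nucleic geometry ([na_geometry()]) used for sequence-built
#'   atoms; taken from `pet$na$form` when present.
#' @param ff defaults from [ff_defaults()].
#' @return a `term_set`: list with `bonds`, `angles`, `dihedrals`
#'   data.frames and `excluded_pairs`.
#' @export
assign_parameters <- function(pet, geom = NULL, ff = ff_defaults()) {
  atoms <- pet$atoms
  n <- nrow(atoms)
  bonds <- pet$bonds
  if (n > 1 && (is.null(bonds) || nrow(bonds) == 0 ||
                length(unique(c(bonds))) < n))
    stop("unbonded atom present: run bonding before parameter assignment")
  adj <- bond_adjacency(n, bonds)
  deg <- lengths(adj)
  xyz <- atom_xyz(atoms)
  seq_built <- atoms$bfactor > 0
  if (is.null(geom))
    geom <- na_geometry(if (!is.null(pet[["na"]])) pet[["na"]]$form else "bdna")
  nakind <- na_atom_kind(pet)

  # ---- bonds ----
  r0 <- numeric(nrow(bonds))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    if (seq_built[i] || seq_built[j])
      r0[b] <- na_bond_equilibrium(i, j, nakind, geom, xyz)
    else r0[b] <- vec_norm(xyz[i, ] - xyz[j, ])
  }
  bond_df <- data.frame(i = bonds[, 1], j = bonds[, 2], r0 = r0,
                        k = ff$bond_k)

  bonded <- matrix(FALSE, n, n)
  if (nrow(bonds)) bonded[rbind(bonds, bonds[, 2:1, drop = FALSE])] <- TRUE

  # ---- angles ----
  ang <- list(); excluded_triplets <- list()
  win <- deg2rad(ff$angle_window_deg)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_along(nb)[-length(nb)]) for (b in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[b]
      if (bonded[i, k]) next  # 3-ring: the three bonds fix the geometry
      if (vec_norm(xyz[i, ] - xyz[j, ]) < 1e-9 ||
          vec_norm(xyz[k, ] - xyz[j, ]) < 1e-9) {
        excluded_triplets[[length(excluded_triplets) + 1]] <- c(i, j, k)
        next  # degenerate arm: angle undefined
      }
      th0 <- if (any(seq_built[c(i, j, k)]))
        na_angle_equilibrium(i, j, k, nakind, geom, xyz)
      else bend_angle(xyz[i, ], xyz[j, ], xyz[k, ])
      if (th0 < win[1] || th0 > win[2]) {
        excluded_triplets[[length(excluded_triplets) + 1]] <- c(i, j, k)
        next
      }
      ang[[length(ang) + 1]] <- c(i, j, k, th0)
    }
  }
  ang_df <- if (length(ang)) {
    m <- do.call(rbind, ang)
    data.frame(i = m[, 1], j = m[, 2], k = m[, 3], theta0 = m[, 4],
               k_force = ff$angle_k)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    theta0 = numeric(0), k_force = numeric(0))
  # (the two 90-degree main-main-helper angles per ds junction arise in
  # the generic loop through na_angle_equilibrium; the 180-degree
  # main-main-main angle is excluded by the window, as intended)
  ang_df <- prune_four_rings(ang_df, bonded)

  # ---- dihedrals ----
  tri_excl <- excluded_triplets
  is_excluded_triplet <- function(i, j, k) {
    for (t in tri_excl)
      if (t[2] == j && ((t[1] == i && t[3] == k) || (t[1] == k && t[3] == i)))
        return(TRUE)
    FALSE
  }
  dih <- list()
  seen <- character(0)
  for (b in seq_len(nrow(bonds))) for (dir in 1:2) {
    B <- bonds[b, dir]; C <- bonds[b, 3 - dir]
    if (deg[B] != 2) next
    for (A in adj[[B]]) {
      if (A == C || deg[A] >= 4) next
      for (D in adj[[C]]) {
        if (D == B || D == A) next
        # ds axis quads are handled explicitly (3 x twist) below
        if (all(nakind[c(A, B, C, D)] %in% c("main", "helper")) &&
            any(nakind[c(A, B, C, D)] == "main")) next
        key <- paste(sort(c(paste(A, B), paste(D, C))), collapse = "|")
        if (key %in% seen) next
        if (is_excluded_triplet(A, B, C) || is_excluded_triplet(B, C, D))
          next
        if (min(vec_norm(xyz[A, ] - xyz[B, ]), vec_norm(xyz[B, ] - xyz[C, ]),
                vec_norm(xyz[C, ] - xyz[D, ])) < 1e-9) next
        phi0 <- if (any(seq_built[c(A, B, C, D)]))
          na_dihedral_equilibrium(A, B, C, D, nakind, geom, xyz)
        else dihedral_angle(xyz[A, ], xyz[B, ], xyz[C, ], xyz[D, ])
        seen <- c(seen, key)
        dih[[length(dih) + 1]] <- c(A, B, C, D, phi0 + pi)
      }
    }
  }
  # ds axis: helper-main-main-helper dihedral = 3 x twist
  dsd <- ds_axis_dihedrals(pet, nakind, adj, geom)
  for (d in dsd) dih[[length(dih) + 1]] <- d
  dih_df <- if (length(dih)) {
    m <- do.call(rbind, dih)
    data.frame(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4],
               phase = m[, 5], pk = ff$dihedral_pk, pn = ff$pn,
               idiv = ff$idiv)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    l = integer(0), phase = numeric(0), pk = numeric(0),
                    pn = numeric(0), idiv = numeric(0))

  structure(list(bonds = bond_df, angles = ang_df, dihedrals = dih_df,
                 excluded_pairs = nonbonded_exclusions(n, bonds, adj),
                 ff = ff),
            class = "term_set")
}

# Role of each atom in a pet nucleic acid: "nt" (ss nucleotide atom),
# "main"/"helper" (ds axis atoms) or "" for everything else.
na_atom_kind <- function(pet) {
  a <- pet$atoms
  kind <- rep("", nrow(a))
  kind[a$element == "O5" & a$bfactor > 0] <- "nt"
  kind[a$element == "OC" & a$bfactor > 0] <- "main"
  kind[a$element == "O1" & a$bfactor > 0] <- "helper"
  kind
}

na_bond_equilibrium <- function(i, j, kind, geom, xyz) {
  ki <- kind[i]; kj <- kind[j]
  if (ki == "nt" && kj == "nt") {
    if (abs(i - j) == 1) return(geom$c1_sequential_distance * 0.1)
    return(geom$c1_paired_distance * 0.1)   # pairing bond
  }
  if (any(c(ki, kj) == "main") && any(c(ki, kj) == "helper"))
    return(1.2)                              # helper offset, pet scale
  if (ki == "main" && kj == "main")
    return(3 * geom$rise_per_bp * 0.1)
  vec_norm(xyz[i, ] - xyz[j, ])              # junction fallback
}

na_angle_equilibrium <- function(i, j, k, kind, geom, xyz) {
  if (all(kind[c(i, j, k)] == "nt")) {
    if (abs(i - j) == 1 && abs(j - k) == 1)
      return(deg2rad(geom$angle_c1_c1_c1))
    # pairing geometry: i bonded to its paired j, k a strand neighbour of j
    if (abs(j - k) == 1) {
      if (k == j + 1) return(deg2rad(geom$angle_c1_paired_3prime))
      return(deg2rad(geom$angle_c1_paired_5prime))
    }
    if (abs(i - j) == 1) {
      if (i == j + 1) return(deg2rad(geom$angle_c1_paired_3prime))
      return(deg2rad(geom$angle_c1_paired_5prime))
    }
  }
  if (all(kind[c(i, j, k)] == "main")) return(pi)  # excluded by the window
  if (kind[j] == "main" && any(kind[c(i, k)] == "helper") &&
      any(kind[c(i, k)] == "main"))
    return(pi / 2)
  bend_angle(xyz[i, ], xyz[j, ], xyz[k, ])
}

na_dihedral_equilibrium <- function(A, B, C, D, kind, geom, xyz) {
  if (all(kind[c(A, B, C, D)] == "nt") &&
      all(diff(sort(c(A, B, C, D))) == 1))
    return(deg2rad(geom$dihedral_c1x4))
  dihedral_angle(xyz[A, ], xyz[B, ], xyz[C, ], xyz[D, ])
}

ds_axis_dihedrals <- function(pet, kind, adj, geom) {
  out <- list()
  mains <- which(kind == "main")
  for (j in mains) for (k in adj[[j]]) {
    if (kind[k] != "main" || k <= j) next
    hj <- adj[[j]][kind[adj[[j]]] == "helper"]
    hk <- adj[[k]][kind[adj[[k]]] == "helper"]
    for (a in hj) for (d in hk)
      out[[length(out) + 1]] <-
        c(a, j, k, d, deg2rad(3 * geom$twist_per_bp) + pi)
  }
  out
}

# Inside each 4-ring keep only the two angle terms whose central atoms are
# the lowest-index ring atom and its lowest-index ring neighbour.
prune_four_rings <- function(ang_df, bonded) {
  if (nrow(ang_df) == 0) return(ang_df)
  n <- nrow(bonded)
  drop <- rep(FALSE, nrow(ang_df))
  key <- paste(pmin(ang_df$i, ang_df$k), ang_df$j, pmax(ang_df$i, ang_df$k))
  # find 4-rings: non-bonded pair (p, q) with >= 2 common neighbours
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    if (bonded[p, q]) next
    common <- which(bonded[p, ] & bonded[q, ])
    if (length(common) < 2) next
    for (a in seq_along(common)[-length(common)])
      for (b in (a + 1):length(common)) {
        ring <- c(p, common[a], q, common[b])  # cycle order
        centres_keep <- integer(2)
        lo <- ring[which.min(ring)]
        pos <- which(ring == lo)
        nb <- ring[c((pos %% 4) + 1, ((pos - 2) %% 4) + 1)]
        centres_keep <- c(lo, min(nb))
        for (ci in seq_len(4)) {
          ctr <- ring[ci]
          ends <- ring[c((ci %% 4) + 1, ((ci - 2) %% 4) + 1)]
          if (ctr %in% centres_keep) next
          kk <- paste(min(ends), ctr, max(ends))
          drop[key == kk] <- TRUE
        }
      }
  }
  ang_df[!drop, , drop = FALSE]
}

# 1-2 and 1-3 pairs excluded from nonbonded interactions.
nonbonded_exclusions <- function(n, bonds, adj) {
  ex <- list()
  if (nrow(bonds)) for (r in seq_len(nrow(bonds)))
    ex[[length(ex) + 1]] <- sort(bonds[r, ])
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_along(nb)[-length(nb)]) for (b in (a + 1):length(nb))
      ex[[length(ex) + 1]] <- sort(c(nb[a], nb[b]))
  }
  if (!length(ex)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, ex))
}

#' Evaluate the pet-world energy
#'
#' @param pet pet `pet_object` (coordinates are taken from its atoms
#'   unless `xyz` is given).
#' @param terms `term_set` from [assign_parameters()].
#' @param xyz optional coordinate matrix overriding the object's.
#' @param cutoff nonbonded cutoff in Angstrom (default from the term set).
#' @return list of components `bond`, `angle`, `dihedral`, `vdw`,
#'   `coulomb`, and `total` (kcal/mol).
#' @export
evaluate_energy <- function(pet, terms, xyz = NULL, cutoff = NULL) {
  if (is.null(xyz)) xyz <- atom_xyz(pet$atoms)
  if (is.null(cutoff)) cutoff <- terms$ff$cutoff
  e <- energy_and_forces(pet, terms, xyz, cutoff, forces = FALSE)
  e$energy
}

energy_and_forces <- function(pet, terms, xyz, cutoff, forces = TRUE) {
  n <- nrow(xyz)
  F <- if (forces) matrix(0, n, 3) else NULL
  eb <- ea <- ed <- ev <- ec <- 0
  b <- terms$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- xyz[i, ] - xyz[j, ]; rij <- vec_norm(d)
    dr <- rij - b$r0[r]
    eb <- eb + b$k[r] * dr^2
    if (forces && rij > 1e-12) {
      f <- -2 * b$k[r] * dr * d / rij
      F[i, ] <- F[i, ] + f; F[j, ] <- F[j, ] - f
    }
  }
  a <- terms$angles
  for (r in seq_len(nrow(a))) {
    i <- a$i[r]; j <- a$j[r]; k <- a$k[r]
    rij <- xyz[i, ] - xyz[j, ]; rkj <- xyz[k, ] - xyz[j, ]
    nij <- vec_norm(rij); nkj <- vec_norm(rkj)
    cs <- max(-1, min(1, sum(rij * rkj) / (nij * nkj)))
    th <- acos(cs)
    dth <- th - a$theta0[r]
    ea <- ea + a$k_force[r] * dth^2
    if (forces) {
      sn <- sqrt(max(1e-12, 1 - cs^2))
      dEdth <- 2 * a$k_force[r] * dth
      fi <- dEdth / (nij * sn) * (rkj / nkj - cs * rij / nij)
      fk <- dEdth / (nkj * sn) * (rij / nij - cs * rkj / nkj)
      F[i, ] <- F[i, ] + fi; F[k, ] <- F[k, ] + fk
      F[j, ] <- F[j, ] - fi - fk
    }
  }
  d <- terms$dihedrals
  for (r in seq_len(nrow(d))) {
    i <- d$i[r]; j <- d$j[r]; k <- d$k[r]; l <- d$l[r]
    out <- dihedral_and_grad(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ],
                             grad = forces)
    phi <- out$phi
    arg <- d$pn[r] * phi - d$phase[r]
    ed <- ed + d$pk[r] / d$idiv[r] * (1 + cos(arg))
    if (forces) {
      dEdphi <- -d$pk[r] / d$idiv[r] * d$pn[r] * sin(arg)
      F[i, ] <- F[i, ] - dEdphi * out$gi
      F[j, ] <- F[j, ] - dEdphi * out$gj
      F[k, ] <- F[k, ] - dEdphi * out$gk
      F[l, ] <- F[l, ] - dEdphi * out$gl
    }
  }
  nb <- nonbonded_pairs(pet, terms, xyz, cutoff)
  ff <- terms$ff
  for (r in seq_len(nrow(nb))) {
    i <- nb[r, 1]; j <- nb[r, 2]
    dv <- xyz[i, ] - xyz[j, ]; rij <- vec_norm(dv)
    rmin <- pet$atoms$radius[i] + pet$atoms$radius[j]
    sr <- (rmin / rij)
    ev_t <- ff$vdw_eps * (sr^12 - 2 * sr^6)
    ev <- ev + ev_t
    qq <- 332.0636 * pet$atoms$charge[i] * pet$atoms$charge[j]
    ec <- ec + qq / rij
    if (forces) {
      dEdr <- ff$vdw_eps * (-12 * sr^12 + 12 * sr^6) / rij - qq / rij^2
      f <- -dEdr * dv / rij
      F[i, ] <- F[i, ] + f; F[j, ] <- F[j, ] - f
    }
  }
  list(energy = list(bond = eb, angle = ea, dihedral = ed, vdw = ev,
                     coulomb = ec, total = eb + ea + ed + ev + ec),
       forces = F)
}

nonbonded_pairs <- function(pet, terms, xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(xyz))
  within <- d <= cutoff & upper.tri(d)
  ex <- terms$excluded_pairs
  if (nrow(ex)) within[ex] <- FALSE
  which(within, arr.ind = TRUE)
}

# Dihedral angle with analytic gradients (standard formulation).
dihedral_and_grad <- function(p1, p2, p3, p4, grad = TRUE) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- vec_norm(b2)
  phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  if (!grad) return(list(phi = phi))
  sq1 <- sum(n1 * n1); sq2 <- sum(n2 * n2)
  gi <- -nb2 / max(sq1, 1e-12) * n1
  gl <- nb2 / max(sq2, 1e-12) * n2
  s <- sum(b1 * b2) / nb2^2
  t <- sum(b3 * b2) / nb2^2
  gj <- -(1 + s) * gi + t * gl
  gk <- s * gi - (1 + t) * gl
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

#' Minimize or integrate a pet molecule
#'
#' Minimization uses steepest descent with a backtracking line search,
#' so the energy is non-increasing at every accepted step. Dynamics uses
#' velocity-Verlet with the multiple time step scheme of the pet world:
#' bonded forces integrate at 0.5 fs and nonbonded forces kick at 1 fs
#' (impulse splitting), with every pet atom carrying the same 8 u mass.
#' Initial velocities are seeded Maxwell-Boltzmann.
#'
#' @param pet pet `pet_object`.
#' @param terms `term_set`.
#' @param mode "minimize" or "md".
#' @param steps minimization steps or outer MD steps (1 fs each).
#' @param seed velocity seed (md).
#' @param temperature initial temperature in K (md).
#' @param force_limit abort threshold on |F| (kcal/(mol A)).
#' @return list with final `xyz`, `energies` (per step totals), and for
#'   md `kinetic` and `velocities`.
#' @export
minimize_or_integrate <- function(pet, terms, mode = c("minimize", "md"),
                                  steps = 100, seed = 0, temperature = 298,
                                  force_limit = 1e5) {
  mode <- match.arg(mode)
  xyz <- atom_xyz(pet$atoms)
  ff <- terms$ff
  cutoff <- ff$cutoff
  if (mode == "minimize") {
    ef <- energy_and_forces(pet, terms, xyz, cutoff)
    energies <- ef$energy$total
    step_size <- 1e-3
    for (s in seq_len(steps)) {
      fmax <- max(abs(ef$forces))
      if (fmax > force_limit) stop("exploding forces: |F| = ", fmax)
      if (fmax < 1e-8) break
      repeat {
        trial <- xyz + step_size * ef$forces / max(1, fmax)
        et <- energy_and_forces(pet, terms, trial, cutoff, forces = FALSE)
        if (et$energy$total <= energies[length(energies)] || step_size < 1e-12)
          break
        step_size <- step_size / 2
      }
      if (et$energy$total > energies[length(energies)]) break
      xyz <- trial
      ef <- energy_and_forces(pet, terms, xyz, cutoff)
      energies <- c(energies, ef$energy$total)
      step_size <- min(step_size * 1.5, 0.1)
    }
    return(list(xyz = xyz, energies = energies))
  }
  # --- md: impulse multiple time step velocity-Verlet ---
  n <- nrow(xyz)
  m <- ff$mass
  fconv <- 4.184e-4  # kcal/mol -> u A^2/fs^2
  kB <- 1.987204e-3  # kcal/(mol K)
  vel <- with_seed(seed, matrix(stats::rnorm(3 * n, sd = sqrt(kB * temperature *
                                                                fconv / m)),
                                n, 3))
  dt_out <- ff$dt_nonbonded; dt_in <- ff$dt_bonded
  n_inner <- round(dt_out / dt_in)
  split_forces <- function(xy) {
    full <- energy_and_forces(pet, terms, xy, cutoff)
    bonded_only <- energy_and_forces(pet, list(bonds = terms$bonds,
                                               angles = terms$angles,
                                               dihedrals = terms$dihedrals,
                                               excluded_pairs = matrix(0, 0, 2),
                                               ff = ff),
                                     xy, cutoff = 0)
    list(total = full, bonded = bonded_only$forces,
         nonbonded = full$forces - bonded_only$forces)
  }
  sf <- split_forces(xyz)
  energies <- numeric(steps); kinetic <- numeric(steps)
  for (s in seq_len(steps)) {
    if (max(abs(sf$total$forces)) > force_limit)
      stop("exploding forces at step ", s)
    vel <- vel + 0.5 * dt_out * sf$nonbonded * fconv / m
    for (ii in seq_len(n_inner)) {
      fb <- if (ii == 1) sf$bonded else
        energy_and_forces(pet, terms, xyz, 0)$forces
      vel <- vel + 0.5 * dt_in * fb * fconv / m
      xyz <- xyz + dt_in * vel
      fb2 <- energy_and_forces(pet, terms, xyz, 0)$forces
      vel <- vel + 0.5 * dt_in * fb2 * fconv / m
    }
    sf <- split_forces(xyz)
    vel <- vel + 0.5 * dt_out * sf$nonbonded * fconv / m
    kinetic[s] <- 0.5 * m * sum(vel^2) / fconv
    energies[s] <- sf$total$energy$total + kinetic[s]
  }
  list(xyz = xyz, energies = energies, kinetic = kinetic, velocities = vel)
}
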