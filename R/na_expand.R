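# Expansion of pet nucleic acids to all-atom coordinates: per-nucleotide
# local frames, three-point superposition of template nucleotides on
# C1*/N3/C6, and cyclic-coordinate-descent closure of backbone gaps.

#' Minimal nucleotide coordinate templates
#'
#' Synthetic ideal-geometry nucleotide templates built in code: a shared
#' ribose/backbone (P, O5*, C5*, C4*, O4*, C3*, O3*, C2*, C1*) plus a
#' planar base ring carrying the N3 and C6 anchors that exist in every
#' base. Coordinates are in a local frame with C1* at the origin and the
#' base in the xy plane. These are deliberately simple stand-ins for
#' crystallographic template nucleotides; they have standard bond lengths
#' but idealised ring geometry.
#'
#' @return named list (A, C, G, T, U) of data.frames with `name`, `x`,
#'   `y`, `z`, `element`.
#' @export
na_templates <- function() {
  # local frame: +x points toward the base (away from the chain), +y
  # runs along the chain toward the next (3') nucleotide, so O3* sits at
  # positive y and P (which bonds the previous residue's O3*) at
  # negative y
  backbone <- rbind(
    c("C1*",  0.00,  0.00,  0.00, "C"),
    c("O4*", -0.62,  0.83, -0.52, "O"),
    c("C4*", -1.90,  0.80,  0.50, "C"),
    c("C3*", -1.35,  1.95,  0.10, "C"),
    c("C2*", -0.70,  1.20, -0.60, "C"),
    c("O3*", -0.20,  1.675, 0.00, "O"),
    c("C5*", -2.00, -0.70,  0.50, "C"),
    c("O5*", -1.30, -2.00,  0.60, "O"),
    c("P",   -0.20, -3.20,  0.20, "P"))
  purine <- rbind(
    c("N9", 1.48,  0.00, 0, "N"), c("C8", 1.95, -1.25, 0, "C"),
    c("N7", 3.28, -1.18, 0, "N"), c("C5", 3.65,  0.12, 0, "C"),
    c("C4", 2.56,  0.88, 0, "C"), c("N3", 2.62,  2.23, 0, "N"),
    c("C2", 3.84,  2.80, 0, "C"), c("N1", 4.96,  2.11, 0, "N"),
    c("C6", 4.95,  0.76, 0, "C"))
  pyrimidine <- rbind(
    c("N1", 1.50,  0.00, 0, "N"), c("C2", 2.18,  1.17, 0, "C"),
    c("N3", 3.53,  1.17, 0, "N"), c("C4", 4.20,  0.00, 0, "C"),
    c("C5", 3.53, -1.17, 0, "C"), c("C6", 2.18, -1.17, 0, "C"))
  as_df <- function(m) data.frame(name = m[, 1], x = as.numeric(m[, 2]),
                                  y = as.numeric(m[, 3]),
                                  z = as.numeric(m[, 4]), element = m[, 5],
                                  stringsAsFactors = FALSE)
  pur <- as_df(rbind(backbone, purine))
  pyr <- as_df(rbind(backbone, pyrimidine))
  list(A = pur, G = pur, C = pyr, T = pyr, U = pyr)
}

# Local frame at an interior chain position: X is the sum of the unit
# vectors to the next and previous C1*, Z = X x v_next, Y = Z x X. At
# chain termini the single neighbour vector stands in for the sum.
c1_local_frame <- function(c1, i) {
  n <- nrow(c1)
  v_next <- if (i < n) c1[i + 1, ] - c1[i, ] else c1[i, ] - c1[i - 1, ]
  v_prev <- if (i > 1) c1[i - 1, ] - c1[i, ] else -v_next
  x <- v_next + v_prev
  if (vec_norm(x) < 1e-9) x <- cross3(v_next, c(0, 0, 1))
  if (vec_norm(x) < 1e-9) x <- cross3(v_next, c(0, 1, 0))
  x <- unit(x)
  z <- cross3(x, v_next)
  if (vec_norm(z) < 1e-9) z <- cross3(x, if (abs(x[3]) < 0.9) c(0, 0, 1)
                                      else c(1, 0, 0))
  z <- unit(z)
  y <- cross3(z, x)
  cbind(x, y, z)  # columns are the frame axes
}

#' Expand a single-stranded pet nucleic acid to all-atom coordinates
#'
#' Each 0.5 A pet atom (one per nucleotide, at the future C1* position,
#' scaled up tenfold) is replaced by a template nucleotide: a local frame
#' is built from the neighbouring C1* positions, the base's N3 and C6
#' target positions are computed from their template coordinates in that
#' frame, and the template is rigidly superposed onto C1*/N3/C6. Backbone
#' O3*(i-1)-P(i) gaps larger than the target bond length are closed with
#' [ccd_close_gap()] over the three rotatable backbone torsions.
#'
#' @param pet pet nucleic object from [build_pet_ss()].
#' @param templates template set (default [na_templates()]).
#' @param close_gaps logical; run CCD gap closure (default TRUE).
#' @return all-atom `pet_object` of kind "nucleic" (real scale).
#' @export
expand_ss <- function(pet, templates = na_templates(), close_gaps = TRUE) {
  if (is.null(pet[["na"]]) || pet[["na"]]$strandedness != "ss")
    stop("expand_ss needs a single-stranded pet nucleic acid")
  nt <- strsplit(pet[["na"]]$sequence, "")[[1]]
  c1 <- atom_xyz(pet$atoms) * 10  # pet -> real scale
  # paired stretches: idealise the local C1* triplet with a fitted
  # standard three-base-pair fragment before frame construction
  pairing <- pet[["na"]]$pairing
  if (!is.null(pairing) && any(!is.na(pairing))) {
    geom <- na_geometry(pet[["na"]]$form)
    for (i in seq_along(nt)) {
      j <- pairing[i]
      if (is.na(j) || i == 1 || i == length(nt)) next
      if (is.na(pairing[i - 1]) || is.na(pairing[i + 1])) next
      if (pairing[i - 1] != j + 1 || pairing[i + 1] != j - 1) next
      frag <- ideal_ds_c1(geom, 3)
      src <- rbind(frag$strand1, frag$strand2[3:1, , drop = FALSE])
      dst <- rbind(c1[(i - 1):(i + 1), , drop = FALSE],
                   c1[c(j + 1, j, j - 1), , drop = FALSE])
      fit <- kabsch_fit(src, dst)
      c1[i, ] <- apply_transform(frag$strand1[2, , drop = FALSE], fit)
    }
  }
  placed <- place_nucleotides(c1, nt, templates, close_gaps)
  molecular_object("expanded_ss_na", placed$atoms, kind = "nucleic",
                   residues = placed$residues)
}

# Place one template nucleotide per C1* target using the local-frame
# rule, then optionally close backbone gaps with CCD. Returns the atom
# table and residue spans.
place_nucleotides <- function(c1, nt, templates = na_templates(),
                              close_gaps = TRUE, chain = "A") {
  n <- length(nt)
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- templates[[nt[i]]]
    F <- c1_local_frame(c1, i)
    loc <- function(name) as.numeric(tpl[tpl$name == name, c("x", "y", "z")])
    t_n3 <- c1[i, ] + as.vector(F %*% loc("N3"))
    t_c6 <- c1[i, ] + as.vector(F %*% loc("C6"))
    src <- rbind(loc("C1*"), loc("N3"), loc("C6"))
    dst <- rbind(c1[i, ], t_n3, t_c6)
    fit <- kabsch_fit(src, dst)
    xyz <- apply_transform(as.matrix(tpl[, c("x", "y", "z")]), fit)
    placed[[i]] <- data.frame(name = tpl$name, x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3], element = tpl$element,
                              resno = i, resid = nt[i],
                              stringsAsFactors = FALSE)
  }
  if (close_gaps && n > 1) {
    target <- 1.6  # O3*-P bond length
    for (i in 2:n) {
      o3_prev <- as.numeric(placed[[i - 1]][placed[[i - 1]]$name == "O3*",
                                            c("x", "y", "z")])
      res <- placed[[i]]
      xyz <- as.matrix(res[, c("x", "y", "z")])
      at <- function(nm) which(res$name == nm)
      torsions <- list(
        list(axis = c(at("C4*"), at("C5*")), moving = c(at("O5*"), at("P"))),
        list(axis = c(at("C5*"), at("O5*")), moving = at("P")))
      out <- ccd_close_gap(xyz, torsions, moving_point = at("P"),
                           target_point = o3_prev, target_dist = target)
      placed[[i]][, c("x", "y", "z")] <- out$points
    }
  }
  all <- do.call(rbind, placed)
  atoms <- atom_table(element = all$element,
                      xyz = as.matrix(all[, c("x", "y", "z")]),
                      elety = all$name, resid = all$resid, resno = all$resno,
                      bfactor = 1, chain = chain)
  starts <- cumsum(c(1, vapply(placed[-n], nrow, 1L)))
  residues <- data.frame(name = nt, start = starts,
                         end = starts + vapply(placed, nrow, 1L) - 1,
                         ss = "C", stringsAsFactors = FALSE)
  list(atoms = atoms, residues = residues)
}

#' Close a positional gap by cyclic coordinate descent
#'
#' Adjusts the listed torsions one at a time: for each torsion the moving
#' point travels on a circle around the bond axis, and the rotation angle
#' is solved in closed form to bring its distance to the target point as
#' close as possible to `target_dist`. The gap (|distance - target_dist|)
#' is non-increasing at every sweep; iteration stops at `tol` or after
#' `max_sweeps`. Torsions whose axis is degenerate (coincident atoms, or
#' moving point on the axis) are skipped for that sweep.
#'
#' @param points n x 3 coordinate matrix of the chain.
#' @param torsions list; each element has `axis` (indices c(i, j) of the
#'   bond) and `moving` (indices rotated by this torsion).
#' @param moving_point index of the point whose distance is driven.
#' @param target_point length-3 target position.
#' @param target_dist desired distance between moving point and target.
#' @param tol stop when the gap is below this (Angstrom, default 0.05).
#' @param max_sweeps maximum CCD sweeps (default 50).
#' @return list: `points` (adjusted), `gap` (final), `gaps` (per sweep,
#'   starting with the initial gap), `sweeps`.
#' @export
ccd_close_gap <- function(points, torsions, moving_point, target_point,
                          target_dist = 0, tol = 0.05, max_sweeps = 50) {
  points <- as.matrix(points)
  gap_of <- function(p) abs(vec_norm(p[moving_point, ] - target_point) -
                              target_dist)
  gaps <- gap_of(points)
  sweeps <- 0
  while (gaps[length(gaps)] > tol && sweeps < max_sweeps) {
    sweeps <- sweeps + 1
    for (tor in torsions) {
      a <- points[tor$axis[1], ]; b <- points[tor$axis[2], ]
      axis <- b - a
      if (vec_norm(axis) < 1e-9) next
      axis <- unit(axis)
      m <- points[moving_point, ]
      # decompose the moving point about the axis circle
      r0 <- m - b
      r_par <- sum(r0 * axis) * axis
      r_perp <- r0 - r_par
      if (vec_norm(r_perp) < 1e-9) next  # moving point on the axis
      e1 <- r_perp; e2 <- cross3(axis, e1)
      centre <- b + r_par
      tvec <- target_point - centre
      # |m(theta) - target|^2 = k0 - 2 (t.e1 cos + t.e2 sin)
      c1 <- sum(tvec * e1); c2 <- sum(tvec * e2)
      amp <- sqrt(c1^2 + c2^2)
      k0 <- sum(tvec * tvec) + sum(e1 * e1) - 2 * sum(tvec * axis) * 0
      k0 <- sum(tvec * tvec) + sum(e1 * e1)
      theta_min <- atan2(c2, c1)  # minimises the distance
      d2_at <- function(th) k0 - 2 * (c1 * cos(th) + c2 * sin(th))
      d_min <- sqrt(max(0, d2_at(theta_min)))
      d_max <- sqrt(k0 + 2 * amp)
      theta <- if (target_dist <= d_min) theta_min
      else if (target_dist >= d_max) theta_min + pi
      else {  # solve d2(theta) = target^2 exactly
        ct <- (k0 - target_dist^2) / (2 * amp)
        theta_min + acos(max(-1, min(1, ct)))
      }
      # only rotate if it does not worsen the gap (monotonicity guard)
      cur_gap <- gap_of(points)
      R <- rotation_about_axis(axis, theta)
      mv <- tor$moving
      newpts <- points
      newpts[mv, ] <- sweep(sweep(points[mv, , drop = FALSE], 2, b) %*% t(R),
                            2, b, "+")
      if (gap_of(newpts) <= cur_gap + 1e-12) points <- newpts
    }
    gaps <- c(gaps, gap_of(points))
    if (length(gaps) > 2 &&
        abs(gaps[length(gaps)] - gaps[length(gaps) - 1]) < 1e-12) break
  }
  list(points = points, gap = gaps[length(gaps)], gaps = gaps,
       sweeps = sweeps)
}
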