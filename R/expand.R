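# Expansion of pet scenes back to instanced all-atom representation, and
# the inverse in-place shrink, so scenes round-trip repeatedly.

#' Expand a pet scene to all-atom
#'
#' Every pet object either carries an all-atom backup (stored by
#' [shrink_molecule()]), which is restored verbatim, or is a sequence-built
#' pet nucleic acid, which is expanded with [expand_ss()] /
#' [expand_ds_genome()]. One instance is created per pet copy and the
#' translations between instances are enlarged tenfold, so relative
#' positions are retained at the new scale. The pet object is stored back
#' on the result (`pet_backup`) so the scene can be shrunk and expanded
#' again in place.
#'
#' @param pet_scene a `pet_scene` at pet scale.
#' @return all-atom `pet_scene` at real scale.
#' @export
expand_scene <- function(pet_scene) {
  if (pet_scene$scale != "pet") stop("scene is not at pet scale")
  objects <- list(); instances <- list()
  for (k in seq_along(pet_scene$objects)) {
    obj <- pet_scene$objects[[k]]
    full <- if (!is.null(obj$allatom_backup)) obj$allatom_backup
    else if (!is.null(obj[["na"]]) && obj[["na"]]$strandedness == "ss") expand_ss(obj)
    else if (!is.null(obj[["na"]]) && obj[["na"]]$strandedness == "ds")
      expand_ds_genome(obj)
    else stop("object '", obj$name, "' has no all-atom backup and is not ",
              "a sequence-built pet nucleic acid")
    full$pet_backup <- obj
    objects[[k]] <- full
    instances[[k]] <- lapply(pet_scene$instances[[k]], function(tr)
      instance_transform(tr$R, tr$t * 10))
  }
  scene_model(objects, instances, scale = "real")
}

#' Shrink a scene (inverse of expansion)
#'
#' Objects carrying a `pet_backup` (set by [expand_scene()]) are restored
#' instantly; any other object is shrunk with [shrink_molecule()].
#' Instance translations contract tenfold.
#'
#' @param scene all-atom `pet_scene`.
#' @param ... passed to [shrink_molecule()] for objects without a backup.
#' @return pet-scale `pet_scene`.
#' @export
shrink_scene <- function(scene, ...) {
  if (scene$scale != "real") stop("scene is not at real scale")
  objects <- lapply(scene$objects, function(obj) {
    if (!is.null(obj$pet_backup)) obj$pet_backup else shrink_molecule(obj, ...)
  })
  instances <- lapply(scene$instances, function(trs)
    lapply(trs, function(tr) instance_transform(tr$R, tr$t * 0.1)))
  scene_model(objects, instances, scale = "pet")
}

# Ideal C1* helix positions of a double strand built from the geometry
# table: strand 1 row-wise then strand 2 (paired order), real scale.
ideal_ds_c1 <- function(geom, n_bp) {
  r <- geom$c1_axis_distance
  rise <- geom$rise_per_bp
  tw <- deg2rad(geom$twist_per_bp)
  shift <- geom$strand_shift
  chord2 <- geom$c1_paired_distance^2 - shift^2
  pair_phase <- 2 * asin(max(-1, min(1, sqrt(max(0, chord2)) / (2 * r))))
  k <- seq_len(n_bp) - 1
  s1 <- cbind(r * cos(k * tw), r * sin(k * tw), k * rise)
  s2 <- cbind(r * cos(k * tw + pair_phase), r * sin(k * tw + pair_phase),
              k * rise + shift)
  list(strand1 = s1, strand2 = s2, pair_phase = pair_phase)
}

#' Expand a double-stranded pet genome to all-atom
#'
#' Builds a linear double helix from the geometry table, bends it to
#' follow the trace of the 1.2 A main pet atoms (enlarged tenfold), and
#' twists it so the backbone phase stays in sync with the direction
#' indicated by the 0.1 A helper atoms. Each main atom anchors the middle
#' base pair of its three-base-pair segment; axis points between anchors
#' are interpolated linearly and the helical phase advances by the twist
#' per base pair from the nearest helper anchor.
#'
#' @param pet_ds pet object from [build_pet_ds()] (or an equivalent
#'   main/helper chain).
#' @param templates nucleotide templates.
#' @return all-atom `pet_object` of kind "nucleic" (real scale) holding
#'   both strands.
#' @export
expand_ds_genome <- function(pet_ds, templates = na_templates()) {
  if (is.null(pet_ds[["na"]]) || pet_ds[["na"]]$strandedness != "ds")
    stop("expand_ds_genome needs a double-stranded pet nucleic acid")
  a <- pet_ds$atoms
  mains <- which(a$element == "OC")
  helpers <- which(a$element == "O1")
  if (length(helpers) < length(mains))
    stop("missing helper atom: each main axis atom needs one")
  geom <- na_geometry(pet_ds[["na"]]$form)
  nt <- strsplit(pet_ds[["na"]]$sequence, "")[[1]]
  n_bp <- length(nt)
  M <- atom_xyz(a)[mains, , drop = FALSE] * 10
  H <- atom_xyz(a)[helpers, , drop = FALSE] * 10
  n_main <- nrow(M)
  tangent_at <- function(k) {
    if (n_main == 1) return(c(0, 0, 1))
    if (k == 1) unit(M[2, ] - M[1, ])
    else if (k == n_main) unit(M[n_main, ] - M[n_main - 1, ])
    else unit(M[k + 1, ] - M[k - 1, ])
  }
  tw <- deg2rad(geom$twist_per_bp)
  rise <- geom$rise_per_bp
  r_ax <- geom$c1_axis_distance
  shift <- geom$strand_shift
  chord2 <- geom$c1_paired_distance^2 - shift^2
  pair_phase <- 2 * asin(max(-1, min(1, sqrt(max(0, chord2)) / (2 * r_ax))))
  c1_1 <- matrix(0, n_bp, 3); c1_2 <- matrix(0, n_bp, 3)
  axis_pts <- matrix(0, n_bp, 3)
  for (m in seq_len(n_bp)) {
    tpos <- (m - 2) / 3 + 1          # main-index coordinate; mains sit at
    k <- max(1, min(n_main, round(tpos)))  # the middle bp of each triplet
    k0 <- max(1, min(n_main - 1, floor(tpos)))
    if (n_main == 1) { axis_pt <- M[1, ] + (m - 2) * rise * tangent_at(1) }
    else {
      frac <- tpos - k0
      axis_pt <- M[k0, ] + max(min(frac, 1.5), -0.5) * (M[k0 + 1, ] - M[k0, ])
    }
    T <- tangent_at(k)
    u <- H[k, ] - M[k, ]
    u <- u - sum(u * T) * T
    u <- unit(u)
    v <- cross3(T, u)
    mid_bp <- 3 * (k - 1) + 2
    theta <- (m - mid_bp) * tw       # phase anchored at the helper
    axis_pts[m, ] <- axis_pt
    c1_1[m, ] <- axis_pt + r_ax * (cos(theta) * u + sin(theta) * v)
    c1_2[m, ] <- axis_pt + r_ax * (cos(theta + pair_phase) * u +
                                     sin(theta + pair_phase) * v) + shift * T
  }
  comp <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
  if (pet_ds[["na"]]$form == "arna") comp["A"] <- "U"
  s1 <- place_nucleotides(c1_1, nt, templates, close_gaps = TRUE)
  s2 <- place_nucleotides(c1_2[rev(seq_len(n_bp)), , drop = FALSE],
                          unname(comp[nt[rev(seq_len(n_bp))]]),
                          templates, close_gaps = TRUE, chain = "B")
  atoms <- rbind(s1$atoms, s2$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  res2 <- s2$residues
  res2$start <- res2$start + nrow(s1$atoms)
  res2$end <- res2$end + nrow(s1$atoms)
  obj <- molecular_object("expanded_ds_na", atoms, kind = "nucleic",
                          residues = rbind(s1$residues, res2))
  obj$axis <- list(c1_strand1 = c1_1, c1_strand2 = c1_2, points = axis_pts)
  obj
}
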