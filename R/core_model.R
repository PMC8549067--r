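# Core domain types: atom tables, molecular objects, instance transforms
# and scenes. Atoms are stored as a data.frame (one row per atom); bonds as
# a two-column integer matrix of atom row indices.

ATOM_COLS <- c("eleno", "elety", "resid", "chain", "resno",
               "x", "y", "z", "element", "radius", "charge", "bfactor")

#' Create an atom table
#'
#' @param element character vector of element symbols (standard or pet).
#' @param xyz n x 3 matrix of coordinates in Angstrom.
#' @param charge per-atom partial charges (elementary charges).
#' @param bfactor B-factor; by convention 0 marks a pet atom whose
#'   coordinates come from a known structure and values > 0 mark atoms
#'   built from sequence.
#' @param elety atom names; defaults to the element symbol.
#' @param resid,resno,chain residue name/number/chain per atom.
#' @param radius vdW radius override; defaults to [vdw_radius()].
#' @return data.frame with the package's standard atom columns.
#' @export
atom_table <- function(element, xyz, charge = 0, bfactor = 0,
                       elety = element, resid = "UNK", resno = 1L,
                       chain = "A", radius = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (n == 0) stop("atom table must contain at least one atom")
  if (is.null(radius)) radius <- vdw_radius(element)
  data.frame(eleno = seq_len(n), elety = rep_len(elety, n),
             resid = rep_len(resid, n), chain = rep_len(chain, n),
             resno = as.integer(rep_len(resno, n)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = rep_len(element, n),
             radius = rep_len(radius, n),
             charge = rep_len(charge, n),
             bfactor = rep_len(bfactor, n),
             stringsAsFactors = FALSE)
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

`atom_xyz<-` <- function(atoms, value) {
  atoms[, c("x", "y", "z")] <- value
  atoms
}

#' Create a molecular object
#'
#' A molecular object bundles an atom table, a bond list, residue
#' annotations and a kind tag. Pet objects may carry a backup of the
#' pre-shrink all-atom structure so that expansion can restore it.
#'
#' @param name object name.
#' @param atoms atom table from [atom_table()].
#' @param bonds two-column integer matrix of atom indices (may have 0 rows).
#' @param kind one of "protein", "nucleic", "membrane_block", "pet", "mixed".
#' @param residues optional data.frame with columns `name`, `start`, `end`,
#'   `ss` (secondary structure H/E/C); spans must partition the atom list.
#' @param allatom_backup optional molecular object holding the original
#'   all-atom structure (stored by the shrinking step).
#' @return object of class `pet_object`.
#' @export
molecular_object <- function(name, atoms, bonds = NULL,
                             kind = c("protein", "nucleic", "membrane_block",
                                      "pet", "mixed"),
                             residues = NULL, allatom_backup = NULL) {
  kind <- match.arg(kind)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && any(bonds[, 1] == bonds[, 2]))
    stop("bond relation must be irreflexive")
  if (nrow(bonds) && (max(bonds) > nrow(atoms) || min(bonds) < 1))
    stop("bond indices out of range")
  # canonical order: i < j, unique
  if (nrow(bonds)) {
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  if (kind == "pet" && !all(is_pet_element(atoms$element)))
    stop("a pet-kind object may contain only pet elements")
  if (!is.null(residues)) {
    spans <- unlist(mapply(seq, residues$start, residues$end,
                           SIMPLIFY = FALSE))
    if (length(spans) != nrow(atoms) || anyDuplicated(spans))
      stop("residue spans must partition the atom list")
  }
  structure(list(name = name, atoms = atoms, bonds = bonds, kind = kind,
                 residues = residues, allatom_backup = allatom_backup,
                 pet_backup = NULL),
            class = "pet_object")
}

#' @export
print.pet_object <- function(x, ...) {
  cat(sprintf("<pet_object '%s'> kind=%s atoms=%d bonds=%d\n",
              x$name, x$kind, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Create an instance transform
#'
#' A rigid-body transform (rotation + translation) that places one copy of
#' an object in the scene. One transform per instance is the scene's
#' compression mechanism.
#'
#' @param R 3x3 rotation matrix with determinant +1.
#' @param t length-3 translation vector in Angstrom.
#' @return object of class `pet_transform`.
#' @export
instance_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation determinant must be +1 (got ", format(det(R)), ")")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation matrix must be orthonormal")
  structure(list(R = R, t = as.numeric(t)), class = "pet_transform")
}

#' Create a scene
#'
#' A scene is a set of named molecular objects, each with one or more
#' instance transforms, plus a scale flag ("pet" = one-tenth linear size,
#' "real" = all-atom scale).
#'
#' @param objects list of `pet_object`s.
#' @param instances list (parallel to `objects`) of lists of
#'   `pet_transform`s; defaults to one identity instance per object.
#' @param scale "pet" or "real".
#' @return object of class `pet_scene`.
#' @export
scene_model <- function(objects, instances = NULL,
                        scale = c("real", "pet")) {
  scale <- match.arg(scale)
  if (length(objects) == 0) stop("a scene must contain at least one object")
  if (inherits(objects, "pet_object")) objects <- list(objects)
  if (is.null(instances))
    instances <- lapply(objects, function(o) list(instance_transform()))
  stopifnot(length(instances) == length(objects))
  if (any(vapply(instances, length, 1L) < 1))
    stop("every object must have at least one instance")
  structure(list(objects = objects, instances = instances, scale = scale),
            class = "pet_scene")
}

#' @export
print.pet_scene <- function(x, ...) {
  st <- scene_stats(x)
  cat(sprintf("<pet_scene> %d object(s), %d instance(s), scale=%s\n",
              length(x$objects), st$total_instances, x$scale))
  cat(sprintf("  unique atoms=%d  total drawn atoms=%d (compression %.1fx)\n",
              st$unique_atoms, st$total_atoms,
              st$total_atoms / st$unique_atoms))
  invisible(x)
}

#' Instancing statistics of a scene
#'
#' @param scene a `pet_scene`.
#' @return list with `unique_atoms` (stored once), `total_atoms`
#'   (drawn = sum over objects of atoms x instances), `total_instances`.
#' @export
scene_stats <- function(scene) {
  na <- vapply(scene$objects, function(o) nrow(o$atoms), 1L)
  ni <- vapply(scene$instances, length, 1L)
  list(unique_atoms = sum(na), total_atoms = sum(na * ni),
       total_instances = sum(ni))
}

# Connected components of a bond graph over n atoms; returns integer
# component labels.
bond_components <- function(n, bonds) {
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    a <- find(bonds[r, 1]); b <- find(bonds[r, 2])
    if (a != b) comp[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

# Adjacency list from a bond matrix.
bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}
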