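# Structure I/O. PDB files go through bio3d; mmCIF reading/writing is done
# in-package because the scene format relies on instancing extension items
# (_pdbx_model.name, _pdbx_model.instances,
# _pdbx_struct_assembly_gen.PDB_model_num, _pdbx_struct_oper_list) that no
# general-purpose writer emits. Coordinates are written with 3 decimals,
# operators with 6.

#' Read a structure file into a scene
#'
#' Reads a PDB or mmCIF file. Objects are keyed by their model number
#' (`atom_site.pdbx_PDB_model_num` / PDB MODEL records). For mmCIF files
#' carrying the instancing extension, a model whose `_pdbx_model.instances`
#' entry exceeds 1 has its instances materialized immediately from the
#' `_pdbx_struct_assembly_gen` / `_pdbx_struct_oper_list` data; otherwise a
#' single identity instance is used.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif"; guessed from the extension by default.
#' @return a `pet_scene`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("malformed PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- gsub("[0-9*']", "", substr(a$elety, 1, 2))
  el <- toupper(trimws(el))
  # normalise pet symbols that lose case in PDB columns
  charge <- suppressWarnings(as.numeric(a$charge))
  charge[is.na(charge)] <- 0
  nmodel <- max(1L, nrow(pdb$xyz))
  objects <- list()
  for (m in seq_len(nmodel)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- atom_table(element = el, xyz = xyz, charge = charge,
                        bfactor = ifelse(is.na(a$b), 0, a$b),
                        elety = a$elety, resid = a$resid,
                        resno = a$resno, chain = ifelse(is.na(a$chain), "A",
                                                        a$chain))
    kind <- guess_object_kind(atoms)
    objects[[m]] <- molecular_object(sprintf("model_%d", m), atoms,
                                     kind = kind)
  }
  scale <- if (all(is_pet_element(el))) "pet" else "real"
  scene_model(objects, scale = scale)
}

guess_object_kind <- function(atoms) {
  if (all(is_pet_element(atoms$element))) return("pet")
  na_res <- c("DA", "DC", "DG", "DT", "A", "C", "G", "U", "DU")
  if (all(atoms$resid %in% na_res)) return("nucleic")
  if (any(atoms$resid %in% .lipid_residues)) return("membrane_block")
  "protein"
}

# ---- minimal mmCIF tokenizer / category reader ------------------------------

# Split one mmCIF data line into tokens, honouring single/double quotes.
cif_tokens <- function(line) {
  out <- character(0)
  i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && !(substr(line, j, j) == ch &&
                         (j == n || substr(line, j + 1, j + 1) %in% c(" ", "\t"))))
        j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      out <- c(out, substr(line, i, j - 1))
      i <- j
    }
  }
  out
}

# Parse an mmCIF file into a list of category data.frames (loops) and a
# list of single key/value items.
cif_parse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loops <- list(); items <- list()
  i <- 1; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#") || startsWith(line, "data_")) {
      i <- i + 1; next
    }
    if (line == "loop_") {
      tags <- character(0); i <- i + 1
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1
      }
      vals <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (l2 == "" || startsWith(l2, "#") || l2 == "loop_" ||
            startsWith(l2, "_") || startsWith(l2, "data_")) break
        vals <- c(vals, cif_tokens(lines[i])); i <- i + 1
      }
      if (length(vals) %% length(tags) != 0)
        stop("malformed mmCIF loop near line ", i, " of '", path,
             "': token count not a multiple of the tag count")
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags
      cat0 <- sub("\\..*$", "", tags[1])
      loops[[cat0]] <- if (is.null(loops[[cat0]])) df else
        rbind(loops[[cat0]], df)
    } else if (startsWith(line, "_")) {
      tok <- cif_tokens(line)
      if (length(tok) >= 2) items[[tok[1]]] <- paste(tok[-1], collapse = " ")
      i <- i + 1
    } else i <- i + 1
  }
  list(loops = loops, items = items)
}

read_structure_mmcif <- function(path) {
  p <- cif_parse(path)
  as_ <- p$loops[["_atom_site"]]
  if (is.null(as_)) stop("malformed mmCIF file '", path,
                         "': no _atom_site loop found")
  g <- function(tag, default = NA) {
    col <- paste0("_atom_site.", tag)
    if (col %in% names(as_)) as_[[col]] else rep(default, nrow(as_))
  }
  model_num <- as.integer(g("pdbx_PDB_model_num", 1))
  model_num[is.na(model_num)] <- 1L
  el <- toupper(g("type_symbol"))
  if (anyNA(el)) stop("mmCIF file lacks _atom_site.type_symbol")
  xyz <- cbind(as.numeric(g("Cartn_x")), as.numeric(g("Cartn_y")),
               as.numeric(g("Cartn_z")))
  bfac <- suppressWarnings(as.numeric(g("B_iso_or_equiv", 0)))
  bfac[is.na(bfac)] <- 0
  resno <- suppressWarnings(as.integer(g("label_seq_id", 1)))
  resno[is.na(resno)] <- 1L
  vdw_radius(unique(el))  # errors early on unknown symbols, naming them

  # extension items: model names and instance counts
  pm <- p$loops[["_pdbx_model"]]
  if (is.null(pm) && "_pdbx_model.name" %in% names(p$items))
    pm <- data.frame("_pdbx_model.name" = p$items[["_pdbx_model.name"]],
                     "_pdbx_model.instances" = p$items[["_pdbx_model.instances"]],
                     check.names = FALSE, stringsAsFactors = FALSE)
  opers <- cif_oper_list(p$loops[["_pdbx_struct_oper_list"]])
  agen <- p$loops[["_pdbx_struct_assembly_gen"]]

  umodels <- sort(unique(model_num))
  objects <- list(); instances <- list()
  for (k in seq_along(umodels)) {
    m <- umodels[k]
    sel <- model_num == m
    atoms <- atom_table(element = el[sel], xyz = xyz[sel, , drop = FALSE],
                        bfactor = bfac[sel],
                        elety = g("label_atom_id", el)[sel],
                        resid = g("label_comp_id", "UNK")[sel],
                        resno = resno[sel],
                        chain = g("label_asym_id", "A")[sel])
    name <- sprintf("model_%d", m)
    ninst <- 1L
    if (!is.null(pm) && k <= nrow(pm)) {
      name <- pm[["_pdbx_model.name"]][k]
      ninst <- as.integer(pm[["_pdbx_model.instances"]][k])
    }
    tr <- list(instance_transform())
    if (ninst > 1 && !is.null(agen) && length(opers)) {
      row <- agen[as.integer(agen[["_pdbx_struct_assembly_gen.PDB_model_num"]]) == m, ,
                  drop = FALSE]
      if (nrow(row)) {
        ids <- trimws(strsplit(row[["_pdbx_struct_assembly_gen.oper_expression"]][1],
                               ",")[[1]])
        ids <- gsub("[()]", "", ids)
        tr <- opers[ids]
        if (any(vapply(tr, is.null, TRUE)))
          stop("mmCIF assembly references unknown operator id")
      }
    }
    objects[[k]] <- molecular_object(name, atoms,
                                     kind = guess_object_kind(atoms))
    instances[[k]] <- tr
  }
  scale <- if (all(is_pet_element(el))) "pet" else "real"
  scene_model(objects, instances, scale = scale)
}

cif_oper_list <- function(df) {
  if (is.null(df)) return(list())
  out <- list()
  for (r in seq_len(nrow(df))) {
    R <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      R[i, j] <- as.numeric(df[[sprintf("_pdbx_struct_oper_list.matrix[%d][%d]", i, j)]][r])
    t <- vapply(1:3, function(i)
      as.numeric(df[[sprintf("_pdbx_struct_oper_list.vector[%d]", i)]][r]), 0)
    # written operators carry 6 decimals: snap to the nearest rotation
    s <- svd(R)
    R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    out[[df[["_pdbx_struct_oper_list.id"]][r]]] <- instance_transform(R, t)
  }
  out
}

# ---- writing ----------------------------------------------------------------

#' Write a scene to mmCIF
#'
#' In "pet" mode every object must be pet-kind; atoms are written out one
#' by one (one model per object, pet element symbols O1-O9/OA/OB/OC) without
#' instance compression. In "expanded" mode each object is written once as
#' one model and its copies are stored as biological-assembly operators:
#' one `_pdbx_struct_oper_list` row per instance, with
#' `_pdbx_struct_assembly_gen.PDB_model_num` linking each assembly to its
#' model and `_pdbx_model.name`/`.instances` naming the objects.
#'
#' @param scene a `pet_scene`.
#' @param path output file path.
#' @param mode "pet" or "expanded".
#' @return the path, invisibly.
#' @export
write_mmcif <- function(scene, path, mode = c("expanded", "pet")) {
  mode <- match.arg(mode)
  if (length(scene$objects) == 0) stop("cannot write a scene with no objects")
  if (mode == "pet" &&
      !all(vapply(scene$objects, function(o) o$kind == "pet", TRUE)))
    stop("pet mode requires all objects to be pet-kind")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_petworld")
  w("#")
  w("_petworld.scale %s", scene$scale)
  w("#")
  w("loop_")
  w("_pdbx_model.name")
  w("_pdbx_model.instances")
  for (k in seq_along(scene$objects)) {
    ninst <- if (mode == "pet") 1L else length(scene$instances[[k]])
    w("'%s' %d", scene$objects[[k]]$name, ninst)
  }
  w("#")
  if (mode == "expanded") {
    w("loop_")
    w("_pdbx_struct_assembly_gen.assembly_id")
    w("_pdbx_struct_assembly_gen.oper_expression")
    w("_pdbx_struct_assembly_gen.PDB_model_num")
    oid <- 0L
    for (k in seq_along(scene$objects)) {
      ids <- oid + seq_along(scene$instances[[k]])
      w("%d '%s' %d", k, paste(ids, collapse = ","), k)
      oid <- oid + length(ids)
    }
    w("#")
    w("loop_")
    w("_pdbx_struct_oper_list.id")
    w("_pdbx_struct_oper_list.type")
    for (i in 1:3) for (j in 1:3)
      w("_pdbx_struct_oper_list.matrix[%d][%d]", i, j)
    for (i in 1:3) w("_pdbx_struct_oper_list.vector[%d]", i)
    oid <- 0L
    for (k in seq_along(scene$objects)) {
      for (tr in scene$instances[[k]]) {
        oid <- oid + 1L
        vals <- c(t(tr$R))  # row-major matrix[i][j]
        w("%d 'point symmetry operation' %s %s", oid,
          paste(sprintf("%.6f", vals), collapse = " "),
          paste(sprintf("%.6f", tr$t), collapse = " "))
      }
    }
    w("#")
  }
  w("loop_")
  w("_atom_site.group_PDB")
  w("_atom_site.id")
  w("_atom_site.type_symbol")
  w("_atom_site.label_atom_id")
  w("_atom_site.label_comp_id")
  w("_atom_site.label_asym_id")
  w("_atom_site.label_seq_id")
  w("_atom_site.Cartn_x")
  w("_atom_site.Cartn_y")
  w("_atom_site.Cartn_z")
  w("_atom_site.occupancy")
  w("_atom_site.B_iso_or_equiv")
  w("_atom_site.pdbx_PDB_model_num")
  id <- 0L
  for (k in seq_along(scene$objects)) {
    a <- scene$objects[[k]]$atoms
    hetatm <- is_pet_element(a$element)
    for (r in seq_len(nrow(a))) {
      id <- id + 1L
      w("%s %d %s %s %s %s %d %.3f %.3f %.3f 1.00 %.2f %d",
        if (hetatm[r]) "HETATM" else "ATOM", id, a$element[r],
        gsub(" ", "_", a$elety[r]), a$resid[r], a$chain[r], a$resno[r],
        a$x[r], a$y[r], a$z[r], a$bfactor[r], k)
    }
  }
  w("#")
  invisible(path)
}

#' Write a scene (or object) to PDB
#'
#' Thin wrapper over [bio3d::write.pdb()]. Each object becomes one MODEL;
#' pet element symbols are written to the element columns. Instances are
#' not compressed in PDB output; only the first instance of each object is
#' written.
#'
#' @param scene a `pet_scene` or `pet_object`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb_scene <- function(scene, path) {
  if (inherits(scene, "pet_object")) scene <- scene_model(list(scene))
  a <- do.call(rbind, lapply(scene$objects, function(o) o$atoms))
  xyz <- as.vector(t(atom_xyz(a)))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, b = a$bfactor,
                   elesy = a$element, o = rep(1, nrow(a)))
  invisible(path)
}
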