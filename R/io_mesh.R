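# Triangle-mesh I/O: Wavefront OBJ and ASCII PLY, with optional per-vertex
# colours (OBJ: extra RGB floats after the coordinates; PLY: uchar
# red/green/blue properties).

#' Read a triangle mesh (OBJ or PLY)
#'
#' @param path file path; format guessed from the extension.
#' @return a `tri_mesh`: list with `vertices` (n x 3) and `faces`
#'   (m x 3, 1-based), plus `vertex_colors` when present.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path)
  else read_obj(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- lines[startsWith(lines, "v ")]
  fs <- lines[startsWith(lines, "f ")]
  if (!length(vs) || !length(fs)) stop("malformed OBJ file: ", path)
  vm <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                              as.numeric))
  fm <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                              function(tok) as.integer(sub("/.*$", "", tok))))
  out <- list(vertices = vm[, 1:3, drop = FALSE], faces = fm[, 1:3, drop = FALSE])
  if (ncol(vm) >= 6) out$vertex_colors <- vm[, 4:6, drop = FALSE]
  structure(out, class = "tri_mesh")
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply" || !any(grepl("ascii", lines[1:5])))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub(".*vertex ", "", lines[grepl("element vertex", lines)]))
  nf <- as.integer(sub(".*face ", "", lines[grepl("element face", lines)]))
  hdr_end <- which(lines == "end_header")
  vrows <- lines[hdr_end + seq_len(nv)]
  frows <- lines[hdr_end + nv + seq_len(nf)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vrows), "\\s+"), as.numeric))
  fm <- do.call(rbind, lapply(strsplit(trimws(frows), "\\s+"), function(tok)
    as.integer(tok[2:4]) + 1L))
  out <- list(vertices = vm[, 1:3, drop = FALSE], faces = fm)
  if (ncol(vm) >= 6) out$vertex_colors <- vm[, 4:6, drop = FALSE]
  structure(out, class = "tri_mesh")
}

#' Write a triangle mesh (OBJ or PLY)
#'
#' @param mesh a `tri_mesh` (optionally with `vertex_colors`).
#' @param path output path; ".ply" selects ASCII PLY, anything else OBJ.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  cols <- mesh$vertex_colors
  if (!is.null(cols) && is.null(dim(cols))) {
    # colour indices -> a small RGB palette
    pal <- grDevices::col2rgb(grDevices::palette.colors(9)[1 + (0:8)]) / 255
    cols <- t(pal)[1 + (as.integer(cols) - 1) %% 9, , drop = FALSE]
  }
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 if (!is.null(cols)) c("property uchar red",
                                       "property uchar green",
                                       "property uchar blue"),
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    for (i in seq_len(nrow(v)))
      writeLines(paste(c(sprintf("%.6f", v[i, ]),
                         if (!is.null(cols)) as.integer(round(255 * cols[i, ]))),
                       collapse = " "), con)
    for (i in seq_len(nrow(f)))
      writeLines(paste(c(3, f[i, ] - 1L), collapse = " "), con)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(v)))
      writeLines(paste(c("v", sprintf("%.6f", v[i, ]),
                         if (!is.null(cols)) sprintf("%.4f", cols[i, ])),
                       collapse = " "), con)
    for (i in seq_len(nrow(f)))
      writeLines(paste(c("f", f[i, ]), collapse = " "), con)
  }
  invisible(path)
}
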