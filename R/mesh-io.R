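# File I/O for meshes and nodal displacement fields.
#
# Supported mesh dialects: Gmsh .msh (ASCII v2.2 and v4.1, tet4 volume
# elements; lower-dimensional boundary entities are ignored), legacy ASCII
# VTK unstructured grids (cell type 10), and a minimal FEBio .feb XML
# dialect (<Nodes> + <Elements type="tet4">, under <Mesh> or <Geometry>).
# Displacement fields: CSV with header node,ux,uy,uz (assumed mm, the MRI
# convention, unless `units = "m"`), and VTK point-data VECTORS (assumed
# metres, the package's own writer convention).
#
# All dialects are converted to the internal convention at the boundary:
# 1-based connectivity, SI units.

#' Read a tetrahedral mesh
#'
#' @param path path to a `.msh` (Gmsh), `.vtk` (legacy ASCII) or `.feb`
#'   (minimal FEBio XML) file.
#' @param format_hint one of `"auto"`, `"gmsh"`, `"vtk"`, `"febio"`.
#' @param density tissue density attached to the mesh (kg m^-3).
#' @param units coordinate units in the file; `"m"` (default) or `"mm"`.
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format_hint = c("auto", "gmsh", "vtk", "febio"),
                      density = 1040, units = c("m", "mm")) {
  format_hint <- match.arg(format_hint)
  units <- match.arg(units)
  if (!file.exists(path)) config_error("mesh file not found: %s", path)
  if (format_hint == "auto") {
    format_hint <- switch(tolower(tools::file_ext(path)),
                          msh = "gmsh", vtk = "vtk", feb = "febio",
                          config_error("cannot infer mesh format from extension of %s", path))
  }
  m <- switch(format_hint,
              gmsh  = read_gmsh(path),
              vtk   = read_vtk_mesh(path),
              febio = read_febio(path))
  if (units == "mm") m$nodes <- m$nodes / 1000
  tet_mesh(m$nodes, m$elements, density = density)
}

#' @noRd
read_gmsh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) config_error("Gmsh file lacks $%s section", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  ver <- as.numeric(fmt[1])
  if (fmt[2] != "0") config_error("binary Gmsh files are not supported")
  if (ver < 3) read_gmsh_v2(sect) else read_gmsh_v4(sect)
}

#' @noRd
read_gmsh_v2 <- function(sect) {
  nl <- sect("Nodes")
  nn <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[2:(nn + 1L)], quiet = TRUE), ncol = 4L, byrow = TRUE)
  ids <- as.integer(ntab[, 1]); coords <- ntab[, 2:4, drop = FALSE]
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)

  el <- sect("Elements")
  ne <- as.integer(el[1])
  rows <- strsplit(trimws(el[2:(ne + 1L)]), "\\s+")
  conn <- list(); bad <- integer(0)
  for (r in rows) {
    v <- as.integer(r)
    type <- v[2]; ntags <- v[3]
    nodes <- v[(4L + ntags):length(v)]
    if (type == 4L) conn[[length(conn) + 1L]] <- nodes
    else if (!type %in% c(1L, 2L, 15L)) bad <- c(bad, type)  # keep tet4; skip pts/lines/tris
  }
  if (length(bad)) config_error("unsupported (non-tet4) volume element types in Gmsh file: %s",
                                paste(unique(bad), collapse = ", "))
  if (!length(conn)) config_error("no tet4 elements in Gmsh file")
  elements <- matrix(remap[do.call(rbind, conn)], ncol = 4L)
  list(nodes = coords, elements = elements)
}

#' @noRd
read_gmsh_v4 <- function(sect) {
  nl <- sect("Nodes")
  hdr <- as.numeric(strsplit(trimws(nl[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  pos <- 2L; ids <- integer(0); coords <- NULL
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(trimws(nl[pos]), "\\s+")[[1]])
    nb <- bh[4]; pos <- pos + 1L
    if (nb > 0) {
      tag <- as.integer(nl[pos:(pos + nb - 1L)]); pos <- pos + nb
      xyz <- matrix(scan(text = nl[pos:(pos + nb - 1L)], quiet = TRUE),
                    ncol = 3L, byrow = TRUE)
      pos <- pos + nb
      ids <- c(ids, tag); coords <- rbind(coords, xyz)
    }
  }
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)

  el <- sect("Elements")
  pos <- 2L; conn <- NULL
  eh <- as.numeric(strsplit(trimws(el[1]), "\\s+")[[1]])
  for (b in seq_len(eh[1])) {
    bh <- as.numeric(strsplit(trimws(el[pos]), "\\s+")[[1]])
    dim <- bh[1]; type <- bh[3]; nb <- bh[4]; pos <- pos + 1L
    if (nb == 0) next
    rows <- matrix(scan(text = el[pos:(pos + nb - 1L)], quiet = TRUE),
                   nrow = nb, byrow = TRUE)
    pos <- pos + nb
    if (type == 4) conn <- rbind(conn, rows[, 2:5, drop = FALSE])
    else if (dim == 3) config_error("unsupported (non-tet4) volume element type %d in Gmsh file", type)
  }
  if (is.null(conn)) config_error("no tet4 elements in Gmsh file")
  list(nodes = coords, elements = matrix(remap[as.integer(conn)], ncol = 4L))
}

#' @noRd
read_vtk_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("UNSTRUCTURED_GRID", lines)))
    config_error("VTK file is not an unstructured grid")
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  vals <- scan(text = lines[-seq_len(ip)], n = 3L * np, quiet = TRUE)
  nodes <- matrix(vals, ncol = 3L, byrow = TRUE)

  ic <- grep("^CELLS", lines)[1]
  hdr <- strsplit(trimws(lines[ic]), "\\s+")[[1]]
  nc <- as.integer(hdr[2]); ntot <- as.integer(hdr[3])
  cvals <- scan(text = lines[-seq_len(ic)], n = ntot, quiet = TRUE)
  it <- grep("^CELL_TYPES", lines)[1]
  types <- scan(text = lines[-seq_len(it)], n = nc, quiet = TRUE)
  if (any(types != 10)) config_error("non-tet4 cells (VTK type != 10) present")
  cm <- matrix(cvals, ncol = 5L, byrow = TRUE)
  if (any(cm[, 1] != 4)) config_error("malformed tet4 cell record in VTK file")
  list(nodes = nodes, elements = cm[, 2:5, drop = FALSE] + 1L)  # VTK is 0-based
}

#' @noRd
read_febio <- function(path) {
  doc <- xml2::read_xml(path)
  geo <- xml2::xml_find_first(doc, ".//Mesh | .//Geometry")
  if (inherits(geo, "xml_missing")) config_error(".feb file lacks a <Mesh>/<Geometry> section")
  node_els <- xml2::xml_find_all(geo, ".//Nodes/node")
  if (!length(node_els)) config_error(".feb file has no <node> entries")
  ids <- as.integer(xml2::xml_attr(node_els, "id"))
  coords <- do.call(rbind, lapply(strsplit(xml2::xml_text(node_els), ","), as.numeric))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)

  elem_blocks <- xml2::xml_find_all(geo, ".//Elements")
  conn <- NULL
  for (blk in elem_blocks) {
    type <- xml2::xml_attr(blk, "type")
    if (!identical(type, "tet4"))
      config_error("unsupported element type '%s' in .feb file (tet4 only)", type)
    rows <- lapply(strsplit(xml2::xml_text(xml2::xml_find_all(blk, "elem")), ","),
                   as.integer)
    conn <- rbind(conn, do.call(rbind, rows))
  }
  if (is.null(conn)) config_error("no tet4 elements in .feb file")
  list(nodes = coords, elements = matrix(remap[conn], ncol = 4L))
}

#' Write a mesh (optionally with nodal vector fields) as legacy ASCII VTK
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @param point_data named list of N x 3 matrices written as VECTORS
#'   point data (metres).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes)
  con <- file(path, "w"); on.exit(close(con))
  num <- function(M) apply(M, 1L, function(r) paste(sprintf("%.17g", r),
                                                    collapse = " "))
  writeLines(c("# vtk DataFile Version 3.0", "gravfm mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(num(mesh$nodes), con)
  m <- nrow(mesh$elements)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  write(t(cbind(4L, mesh$elements - 1L)), con, ncolumns = 5L)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(10L, m), con, ncolumns = 10L)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(num(point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a per-node displacement field
#'
#' @param path a `.csv` file (header `node,ux,uy,uz`), a `.vtk` file with
#'   point-data VECTORS, or the deposited `.mat` layout (unsupported
#'   offline; errors with an explanatory message).
#' @param mesh the [tet_mesh()] the field belongs to (node-count check and
#'   ordering alignment).
#' @param units displacement units in the file. Default `"mm"` for CSV
#'   (the MRI convention) and `"m"` for VTK (this package's writer
#'   convention); converted to metres internally.
#' @param field for VTK input, the VECTORS array name (default: first).
#' @return an N x 3 numeric matrix of displacements in metres, aligned
#'   with the mesh node ordering.
#' @export
read_displacement_field <- function(path, mesh, units = NULL, field = NULL) {
  if (!file.exists(path)) config_error("displacement file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  u <- switch(ext,
    csv = {
      units <- if (is.null(units)) "mm" else match.arg(units, c("mm", "m"))
      df <- read.csv(path)
      need <- c("node", "ux", "uy", "uz")
      if (!all(need %in% names(df)))
        config_error("displacement CSV must have columns %s", paste(need, collapse = ","))
      if (nrow(df) != nrow(mesh$nodes))
        config_error("displacement record count (%d) != mesh node count (%d)",
                     nrow(df), nrow(mesh$nodes))
      u <- matrix(0, nrow(mesh$nodes), 3L)
      u[df$node, ] <- as.matrix(df[, c("ux", "uy", "uz")])
      if (units == "mm") u / 1000 else u
    },
    vtk = {
      units <- if (is.null(units)) "m" else match.arg(units, c("mm", "m"))
      u <- read_vtk_point_vectors(path, field = field)
      if (nrow(u) != nrow(mesh$nodes))
        config_error("VTK point-data count (%d) != mesh node count (%d)",
                     nrow(u), nrow(mesh$nodes))
      if (units == "mm") u / 1000 else u
    },
    mat = config_error(paste0(
      "MAT-file displacement input (deposited avgT_uw_mesh.mat layout) is not ",
      "supported: the layout is undocumented and no MAT parser is available ",
      "offline; convert to CSV (node,ux,uy,uz, mm) or VTK point data")),
    config_error("unsupported displacement format: .%s", ext))
  if (any(!is.finite(u))) config_error("NaN/Inf displacement components in %s", path)
  u
}

#' @noRd
read_vtk_point_vectors <- function(path, field = NULL) {
  lines <- readLines(path, warn = FALSE)
  ipd <- grep("^POINT_DATA", lines)[1]
  if (is.na(ipd)) config_error("VTK file has no POINT_DATA section")
  np <- as.integer(strsplit(trimws(lines[ipd]), "\\s+")[[1]][2])
  vecs <- grep("^VECTORS", lines)
  vecs <- vecs[vecs > ipd]
  if (!length(vecs)) config_error("VTK file has no VECTORS point data")
  if (!is.null(field)) {
    names_v <- vapply(strsplit(trimws(lines[vecs]), "\\s+"), `[`, "", 2L)
    sel <- vecs[match(field, names_v)]
    if (is.na(sel)) config_error("VECTORS array '%s' not found in %s", field, path)
  } else sel <- vecs[1]
  vals <- scan(text = lines[-seq_len(sel)], n = 3L * np, quiet = TRUE)
  matrix(vals, ncol = 3L, byrow = TRUE)
}

#' Write a displacement field as CSV (header `node,ux,uy,uz`)
#'
#' @param u N x 3 displacement matrix in metres.
#' @param path output path.
#' @param units output units, `"mm"` (imaging convention, default) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(u, path, units = c("mm", "m")) {
  units <- match.arg(units)
  fac <- if (units == "mm") 1000 else 1
  df <- data.frame(node = seq_len(nrow(u)), ux = u[, 1] * fac,
                   uy = u[, 2] * fac, uz = u[, 3] * fac)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
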