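# Mesh readers and writers for the formats the package exchanges with
# standard meshing and visualization tools. Region labels travel as volume
# physical groups (MSH) or integer cell data (VTK); named node sets travel
# as point elements with physical tags (MSH) or 0/1 point-data arrays
# (VTK). ASCII only.

region_table <- c(muscle = 1L, bone = 2L, tendon = 3L)
SET_TAG_BASE <- 100L

#' Read a tetrahedral mesh
#'
#' Supported formats: Gmsh MSH v2.2 and v4.1 (`"msh"`, auto-detected),
#' legacy VTK unstructured grids (`"vtk"`) and XML VTK unstructured grids
#' (`"vtu"`). Region labels are taken from volume physical groups (MSH) or
#' the `region` cell-data array (VTK); node sets from point-element
#' physical groups (MSH) or `set_<name>` point-data arrays (VTK). A file
#' without region labels is rejected, never defaulted.
#'
#' @param path File to read.
#' @param format `"msh"`, `"vtk"`, `"vtu"`, or `NULL` to infer from the
#'   file extension.
#' @return A [fem_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("mesh file '%s' does not exist", path))
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         msh = read_msh(path),
         vtk = read_vtk(path),
         vtu = read_vtu(path),
         stop(sprintf("unknown mesh format '%s'", format)))
}

#' Write a tetrahedral mesh
#'
#' Writes `mesh` in the requested format; [read_mesh()] of the result
#' restores coordinates to 1e-12, connectivity exactly, and region labels
#' and node sets exactly. MSH files use 1-based node tags (restored to the
#' internal 1-based indexing on read).
#'
#' @param mesh A [fem_mesh()].
#' @param path Output file.
#' @param format `"msh22"`, `"msh41"`, `"vtk"`, `"vtu"`, or `NULL` to infer
#'   (`.msh` writes v2.2).
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               msh = "msh22", vtk = "vtk", vtu = "vtu",
                               stop("cannot infer mesh format from path"))
  switch(format,
         msh22 = write_msh22(mesh, path),
         msh41 = write_msh41(mesh, path),
         vtk = write_vtk(mesh, path),
         vtu = write_vtu(mesh, path),
         stop(sprintf("unknown mesh format '%s'", format)))
  invisible(path)
}

num <- function(x) formatC(x, format = "g", digits = 17)

## ---------------------------------------------------------------- MSH 2.2

write_msh22 <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  sets <- mesh$sets
  w("$PhysicalNames", length(region_table) + length(sets))
  for (r in names(region_table))
    w(sprintf("3 %d \"%s\"", region_table[[r]], r))
  for (i in seq_along(sets))
    w(sprintf("0 %d \"%s\"", SET_TAG_BASE + i - 1L, names(sets)[i]))
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes", n)
  w(paste(seq_len(n), num(mesh$nodes[, 1]), num(mesh$nodes[, 2]),
          num(mesh$nodes[, 3])))
  w("$EndNodes")
  m <- nrow(mesh$elems)
  npts <- sum(vapply(sets, length, 1L))
  w("$Elements", m + npts)
  eid <- 0L
  for (i in seq_along(sets)) {
    tag <- SET_TAG_BASE + i - 1L
    for (nd in sets[[i]]) {
      eid <- eid + 1L
      w(sprintf("%d 15 2 %d %d %d", eid, tag, tag, nd))
    }
  }
  rg <- region_table[mesh$region]
  w(paste(eid + seq_len(m), 4, 2, rg, rg,
          mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
          mesh$elems[, 4]))
  w("$EndElements")
}

msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  i1 <- which(lines == paste0("$End", name))
  if (!length(i0) || !length(i1))
    stop(sprintf("malformed MSH file: missing $%s section", name))
  lines[(i0 + 1):(i1 - 1)]
}

read_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fmt <- strsplit(msh_section(lines, "MeshFormat")[1], "\\s+")[[1]][1]
  if (startsWith(fmt, "4")) read_msh41(lines)
  else if (startsWith(fmt, "2")) read_msh22(lines)
  else stop(sprintf("unsupported MSH version '%s'", fmt))
}

parse_physical_names <- function(lines) {
  pn <- msh_section(lines, "PhysicalNames")
  out <- list(regions = integer(0), sets = integer(0))
  for (ln in pn[-1]) {
    p <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(p) < 3) next
    nm <- gsub('"', "", paste(p[-(1:2)], collapse = " "))
    tag <- as.integer(p[2])
    if (p[1] == "3") out$regions[nm] <- tag
    else if (p[1] == "0") out$sets[nm] <- tag
  }
  out
}

read_msh22 <- function(lines) {
  phys <- parse_physical_names(lines)
  nl <- msh_section(lines, "Nodes")
  n <- as.integer(nl[1])
  nd <- utils::read.table(text = nl[-1], col.names = c("id", "x", "y", "z"))
  ord <- order(nd$id)
  nodes <- as.matrix(nd[ord, c("x", "y", "z")])
  id_map <- integer(max(nd$id))
  id_map[nd$id[ord]] <- seq_len(n)
  el <- msh_section(lines, "Elements")
  conn <- list(); region <- character(0)
  sets <- stats::setNames(vector("list", length(phys$sets)),
                          names(phys$sets))
  for (ln in el[-1]) {
    p <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    type <- p[2]; ntags <- p[3]
    tags <- p[3 + seq_len(ntags)]
    rest <- p[-(1:(3 + ntags))]
    if (type == 4) {
      rname <- names(phys$regions)[match(tags[1], phys$regions)]
      if (is.na(rname))
        stop("MSH tetrahedron without a known region physical group")
      conn[[length(conn) + 1]] <- id_map[rest]
      region <- c(region, rname)
    } else if (type == 15) {
      sname <- names(phys$sets)[match(tags[1], phys$sets)]
      if (!is.na(sname)) sets[[sname]] <- c(sets[[sname]], id_map[rest[1]])
    }
  }
  if (!length(conn)) stop("MSH file contains no tetrahedra")
  fem_mesh(nodes, do.call(rbind, conn), region, sets)
}

## ---------------------------------------------------------------- MSH 4.1

write_msh41 <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  sets <- mesh$sets
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", length(region_table) + length(sets))
  for (r in names(region_table))
    w(sprintf("3 %d \"%s\"", region_table[[r]], r))
  for (i in seq_along(sets))
    w(sprintf("0 %d \"%s\"", SET_TAG_BASE + i - 1L, names(sets)[i]))
  w("$EndPhysicalNames")
  # entities: one point entity per node set, one volume entity per region
  w("$Entities", paste(length(sets), 0, 0, length(region_table)))
  for (i in seq_along(sets))
    w(sprintf("%d 0 0 0 1 %d", i, SET_TAG_BASE + i - 1L))
  bb <- apply(mesh$nodes, 2, range)
  for (r in names(region_table))
    w(sprintf("%d %s %s 1 %d 0", region_table[[r]],
              paste(num(bb[1, ]), collapse = " "),
              paste(num(bb[2, ]), collapse = " "), region_table[[r]]))
  w("$EndEntities")
  n <- nrow(mesh$nodes)
  # all nodes in one block owned by the first region's volume entity
  w("$Nodes", paste(1, n, 1, n))
  w(paste(3, region_table[[1]], 0, n))
  w(paste(seq_len(n)))
  w(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  w("$EndNodes")
  m <- nrow(mesh$elems)
  npts <- sum(vapply(sets, length, 1L))
  regions_present <- intersect(names(region_table), unique(mesh$region))
  nblocks <- length(sets) + length(regions_present)
  w("$Elements", paste(nblocks, m + npts, 1, m + npts))
  eid <- 0L
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    w(paste(0, i, 15, length(s)))
    w(paste(eid + seq_along(s), s))
    eid <- eid + length(s)
  }
  # element tags encode the original element order so the round trip
  # restores it exactly even though blocks are grouped by region
  for (r in regions_present) {
    idx <- which(mesh$region == r)
    w(paste(3, region_table[[r]], 4, length(idx)))
    w(paste(npts + idx,
            mesh$elems[idx, 1], mesh$elems[idx, 2],
            mesh$elems[idx, 3], mesh$elems[idx, 4]))
  }
  w("$EndElements")
}

read_msh41 <- function(lines) {
  phys <- parse_physical_names(lines)
  # entity tag -> physical tag, per dimension
  ent <- msh_section(lines, "Entities")
  hdr <- as.integer(strsplit(trimws(ent[1]), "\\s+")[[1]])
  ent_phys0 <- integer(0); ent_phys3 <- integer(0)
  row <- 2
  for (i in seq_len(hdr[1])) {          # points: tag x y z nphys phys...
    p <- as.numeric(strsplit(trimws(ent[row]), "\\s+")[[1]])
    if (p[5] >= 1) ent_phys0[as.character(as.integer(p[1]))] <-
        as.integer(p[6])
    row <- row + 1
  }
  row <- row + hdr[2] + hdr[3]          # skip curves, surfaces
  for (i in seq_len(hdr[4])) {          # volumes: tag bbox(6) nphys phys...
    p <- as.numeric(strsplit(trimws(ent[row]), "\\s+")[[1]])
    if (p[8] >= 1) ent_phys3[as.character(as.integer(p[1]))] <-
        as.integer(p[9])
    row <- row + 1
  }
  nl <- msh_section(lines, "Nodes")
  hdr <- as.numeric(strsplit(trimws(nl[1]), "\\s+")[[1]])
  nblocks <- hdr[1]; ntotal <- hdr[2]
  ids <- integer(0); coords <- list()
  row <- 2
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(nl[row]), "\\s+")[[1]])
    nb <- bh[4]
    row <- row + 1
    if (nb > 0) {
      ids <- c(ids, as.integer(nl[row:(row + nb - 1)]))
      row <- row + nb
      coords[[b]] <- utils::read.table(text = nl[row:(row + nb - 1)],
                                       col.names = c("x", "y", "z"))
      row <- row + nb
    }
  }
  nodes_raw <- as.matrix(do.call(rbind, coords))
  ord <- order(ids)
  nodes <- nodes_raw[ord, , drop = FALSE]
  id_map <- integer(max(ids)); id_map[ids[ord]] <- seq_along(ids)
  el <- msh_section(lines, "Elements")
  ehdr <- as.numeric(strsplit(trimws(el[1]), "\\s+")[[1]])
  conn <- list(); region <- character(0); tags <- integer(0)
  sets <- list()
  row <- 2
  for (b in seq_len(ehdr[1])) {
    bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
    dim <- bh[1]; etag <- bh[2]; type <- bh[3]; nb <- bh[4]
    row <- row + 1
    if (nb == 0) next
    block <- el[row:(row + nb - 1)]
    row <- row + nb
    if (type == 4 && dim == 3) {
      ptag <- ent_phys3[[as.character(etag)]]
      rname <- names(phys$regions)[match(ptag, phys$regions)]
      if (is.na(rname))
        stop("MSH tetrahedron block without a known region physical group")
      tb <- utils::read.table(text = block)
      conn[[length(conn) + 1]] <-
        matrix(id_map[as.matrix(tb[, 2:5])], ncol = 4)
      region <- c(region, rep(rname, nb))
      tags <- c(tags, tb[, 1])
    } else if (type == 15 && dim == 0) {
      ptag <- ent_phys0[[as.character(etag)]]
      sname <- names(phys$sets)[match(ptag, phys$sets)]
      if (!is.na(sname)) {
        tb <- utils::read.table(text = block)
        sets[[sname]] <- c(sets[[sname]], id_map[tb[, 2]])
      }
    }
  }
  if (!length(conn)) stop("MSH file contains no tetrahedra")
  ord <- order(tags)
  fem_mesh(nodes, do.call(rbind, conn)[ord, , drop = FALSE],
           region[ord], sets)
}

## ------------------------------------------------------------- legacy VTK

write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  w("# vtk DataFile Version 3.0",
    paste("musclefem mesh; regions:",
          paste(sprintf("%d=%s", region_table, names(region_table)),
                collapse = " ")),
    "ASCII", "DATASET UNSTRUCTURED_GRID")
  w(paste("POINTS", n, "double"))
  w(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  w(paste("CELLS", m, 5 * m))
  w(paste(4, mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
          mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L))
  w(paste("CELL_TYPES", m))
  w(paste(rep(10L, m)))
  w(paste("CELL_DATA", m))
  w("SCALARS region int 1", "LOOKUP_TABLE default")
  w(paste(region_table[mesh$region]))
  if (length(mesh$sets)) {
    w(paste("POINT_DATA", n))
    for (s in names(mesh$sets)) {
      w(sprintf("SCALARS set_%s int 1", s), "LOOKUP_TABLE default")
      memb <- integer(n); memb[mesh$sets[[s]]] <- 1L
      w(paste(memb))
    }
  }
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("malformed VTK file: no POINTS section")
  n <- as.integer(toks(lines[ip])[2])
  pts <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = " "),
              n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(toks(lines[ic])[2])
  cells <- scan(text = paste(lines[(ic + 1):length(lines)], collapse = " "),
                n = 5 * m, quiet = TRUE)
  cells <- matrix(cells, ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) stop("VTK file contains non-tetrahedral cells")
  conn <- cells[, 2:5, drop = FALSE] + 1L
  ird <- grep("^SCALARS region", lines)[1]
  if (is.na(ird))
    stop("VTK file lacks the region cell-data array; refusing to default")
  rg <- scan(text = paste(lines[(ird + 2):length(lines)], collapse = " "),
             n = m, quiet = TRUE)
  region <- names(region_table)[match(rg, region_table)]
  if (anyNA(region)) stop("VTK region array contains unknown labels")
  sets <- list()
  for (is in grep("^SCALARS set_", lines)) {
    nm <- sub("^set_", "", toks(lines[is])[2])
    memb <- scan(text = paste(lines[(is + 2):length(lines)], collapse = " "),
                 n = n, quiet = TRUE)
    sets[[nm]] <- which(memb != 0)
  }
  fem_mesh(nodes, conn, region, sets)
}

## --------------------------------------------------------------- XML VTU

write_vtu <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  da <- function(name, type, ncomp, values)
    sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            type, name, ncomp, paste(values, collapse = " "))
  pd <- character(0)
  for (s in names(mesh$sets)) {
    memb <- integer(n); memb[mesh$sets[[s]]] <- 1L
    pd <- c(pd, da(paste0("set_", s), "Int32", 1, memb))
  }
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '<Points>',
    da("Points", "Float64", 3, num(as.vector(t(mesh$nodes)))),
    '</Points>',
    '<Cells>',
    da("connectivity", "Int32", 1, as.vector(t(mesh$elems - 1L))),
    da("offsets", "Int32", 1, seq_len(m) * 4L),
    da("types", "UInt8", 1, rep(10L, m)),
    '</Cells>',
    '<CellData>',
    da("region", "Int32", 1, region_table[mesh$region]),
    '</CellData>',
    if (length(pd)) c('<PointData>', pd, '</PointData>') else character(0),
    '</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  writeLines(xml, path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_da <- function(xpath) {
    node <- xml2::xml_find_first(piece, xpath)
    if (inherits(node, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- get_da(".//Points/DataArray[@Name='Points']")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- matrix(get_da(".//Cells/DataArray[@Name='connectivity']"),
                 ncol = 4, byrow = TRUE) + 1L
  types <- get_da(".//Cells/DataArray[@Name='types']")
  if (any(types != 10)) stop("VTU file contains non-tetrahedral cells")
  rg <- get_da(".//CellData/DataArray[@Name='region']")
  if (is.null(rg))
    stop("VTU file lacks the region cell-data array; refusing to default")
  region <- names(region_table)[match(rg, region_table)]
  if (anyNA(region)) stop("VTU region array contains unknown labels")
  sets <- list()
  for (node in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    if (startsWith(nm, "set_")) {
      memb <- scan(text = xml2::xml_text(node), quiet = TRUE)
      sets[[sub("^set_", "", nm)]] <- which(memb != 0)
    }
  }
  fem_mesh(nodes, conn, region, sets)
}

#' Write a deformed state for visualization
#'
#' Exports a legacy VTK unstructured grid with the displacement field as
#' point data and per-element `J`, fiber stretch, fiber nominal stress and
#' (where present) the incompressibility multiplier as cell data.
#'
#' @param model A [fem_model()].
#' @param state A [system_state()] (or the per-step state of a
#'   [time_march()] history).
#' @param path Output `.vtk` file.
#' @param dt Time increment used for the stretch-rate in the stress
#'   evaluation.
#' @export
write_vtk_state <- function(model, state, path, dt = 1) {
  asm <- assemble_system(model, state, dt = dt, want_tangent = FALSE)
  mesh <- model$mesh
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  w("# vtk DataFile Version 3.0", "musclefem state", "ASCII",
    "DATASET UNSTRUCTURED_GRID")
  w(paste("POINTS", n, "double"))
  w(paste(num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  w(paste("CELLS", m, 5 * m))
  w(paste(4, mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
          mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L))
  w(paste("CELL_TYPES", m))
  w(paste(rep(10L, m)))
  w(paste("CELL_DATA", m))
  w("SCALARS region int 1", "LOOKUP_TABLE default")
  w(paste(region_table[mesh$region]))
  cell_scalar <- function(name, v) {
    w(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default")
    w(paste(num(v)))
  }
  cell_scalar("jacobian", asm$J)
  cell_scalar("fiber_stretch", asm$lamf)
  cell_scalar("fiber_stress", asm$fiber_T)
  lam_full <- rep(0, m)
  has <- model$lam_id >= 0
  if (any(has)) lam_full[has] <- state$lam[model$lam_id[has] + 1L]
  cell_scalar("multiplier", lam_full)
  w(paste("POINT_DATA", n))
  w("VECTORS displacement double")
  U <- matrix(state$u, ncol = 3, byrow = TRUE)
  w(paste(num(U[, 1]), num(U[, 2]), num(U[, 3])))
}
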