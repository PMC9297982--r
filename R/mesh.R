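# surface extraction and mesh I/O

#' Boundary faces of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron, with outward-pointing normals.
#'
#' @param model a `tibia_model` (or any list with `nodes` and `tets`)
#' @param elements optional element subset (indices or logical) to restrict to
#' @return data.frame with node indices `n1,n2,n3`, owning element `elem`,
#'   area (mm^2), unit normal `nx,ny,nz` and face centroid `cx,cy,cz`
#' @export
boundary_faces <- function(model, elements = NULL) {
  tets <- model$tets
  eidx <- seq_len(nrow(tets))
  if (!is.null(elements)) {
    eidx <- if (is.logical(elements)) which(elements) else elements
    tets <- tets[eidx, , drop = FALSE]
  }
  # the 4 faces of each tet, opposite node order gives outward orientation
  fl <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
              tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  owner <- rep(eidx, 4)
  key <- apply_face_key(fl, nrow(model$nodes))
  once <- !(key %in% key[duplicated(key)])
  fl <- fl[once, , drop = FALSE]
  owner <- owner[once]
  p1 <- model$nodes[fl[, 1], , drop = FALSE]
  p2 <- model$nodes[fl[, 2], , drop = FALSE]
  p3 <- model$nodes[fl[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sqrt(rowSums(nrm^2)) / 2
  unit <- nrm / (2 * area)
  cen <- (p1 + p2 + p3) / 3
  data.frame(n1 = fl[, 1], n2 = fl[, 2], n3 = fl[, 3], elem = owner,
             area = area, nx = unit[, 1], ny = unit[, 2], nz = unit[, 3],
             cx = cen[, 1], cy = cen[, 2], cz = cen[, 3])
}

apply_face_key <- function(faces, n_nodes) {
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- as.double(faces[, 1]) + faces[, 2] + faces[, 3] - a - c3
  base <- as.double(n_nodes + 1)
  a * base * base + b * base + c3
}

#' Nodal tributary areas over a set of surface faces
#'
#' Each face assigns a third of its area to each of its nodes.
#'
#' @param faces data.frame from [boundary_faces()]
#' @param n_nodes total node count
#' @return numeric vector of tributary areas per node, mm^2
#' @export
tributary_areas <- function(faces, n_nodes) {
  out <- numeric(n_nodes)
  for (cc in c("n1", "n2", "n3")) {
    tab <- tapply(faces$area, faces[[cc]], sum)
    out[as.integer(names(tab))] <- out[as.integer(names(tab))] + tab / 3
  }
  out
}

#' Write a tetrahedral model as a legacy ASCII VTK unstructured grid
#'
#' Cell data carries the part label (int code) and density (float).
#'
#' @param model a `tibia_model`
#' @param path output file path
#' @param cell_data optional named list of extra per-element numeric vectors
#' @return `path`, invisibly
#' @export
write_vtk <- function(model, path, cell_data = list()) {
  n <- nrow(model$nodes); m <- nrow(model$tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("tkaremod %s tibia model", model$provenance %||% ""),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  write(t(model$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  write(t(cbind(4L, model$tets - 1L)), con, ncolumns = 5)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(10L, m), con, ncolumns = 20)
  writeLines(sprintf("CELL_DATA %d", m), con)
  part_code <- match(model$part, part_levels()) - 1L
  writeLines(c("SCALARS part_label int 1", "LOOKUP_TABLE default"), con)
  write(part_code, con, ncolumns = 20)
  writeLines(c("SCALARS density float 1", "LOOKUP_TABLE default"), con)
  dens <- model$density
  dens[is.na(dens)] <- -1
  write(dens, con, ncolumns = 10)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    write(cell_data[[nm]], con, ncolumns = 10)
  }
  invisible(path)
}

part_levels <- function() c("bone", "cement", "tray", "insert")

# largest face-connected component of a tet set: elements attached to the
# body only through a node or edge act as mechanisms in the FE system
face_connected_keep <- function(tets, n_nodes) {
  m <- nrow(tets)
  if (m <= 1) return(rep(TRUE, m))
  fl <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
              tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  owner <- rep(seq_len(m), 4)
  key <- apply_face_key(fl, n_nodes)
  o <- order(key)
  key <- key[o]; owner <- owner[o]
  same <- which(key[-1] == key[-length(key)])
  e1 <- owner[same]; e2 <- owner[same + 1]
  g <- igraph::graph_from_edgelist(cbind(e1, e2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  comp <- igraph::components(g)
  comp$membership == which.max(comp$csize)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk()]
#'
#' @param path VTK file path
#' @return a `tibia_model`-like list with nodes, tets, part, density
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  toks <- function(line) strsplit(trimws(line), "\\s+")[[1]]
  ip <- grep("^POINTS", txt)[1]
  n <- as.integer(toks(txt[ip])[2])
  num <- scan(text = txt[(ip + 1):length(txt)], what = double(), n = 3 * n,
              quiet = TRUE)
  nodes <- matrix(num, ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  ic <- grep("^CELLS", txt)[1]
  m <- as.integer(toks(txt[ic])[2])
  cint <- scan(text = txt[(ic + 1):length(txt)], what = integer(), n = 5 * m,
               quiet = TRUE)
  cells <- matrix(cint, ncol = 5, byrow = TRUE)
  stopifnot(all(cells[, 1] == 4L))
  tets <- cells[, 2:5, drop = FALSE] + 1L
  read_scalar <- function(name, what) {
    i <- grep(paste0("^SCALARS ", name, " "), txt)
    if (!length(i)) return(NULL)
    scan(text = txt[(i[1] + 2):length(txt)], what = what, n = m, quiet = TRUE)
  }
  part <- part_levels()[read_scalar("part_label", integer()) + 1L]
  dens <- read_scalar("density", double())
  if (!is.null(dens)) dens[dens < 0] <- NA_real_
  structure(list(nodes = nodes, tets = tets, part = part, density = dens,
                 provenance = "file"), class = "tibia_model")
}
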