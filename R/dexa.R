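# virtual DEXA: fine voxelization of the tet mesh, AP projection, ROIs

#' Voxelize a tetrahedral model into an element-id volume
#'
#' Each voxel stores the id of the element containing its center (0 when
#' empty).  Only the requested parts are mapped; by default only bone, so
#' projections emulate densitometry of the segmented tibia alone.
#'
#' @param model a `tibia_model`
#' @param voxel_edge cubic voxel edge length, mm (0.2 matches the reference
#'   projection resolution; coarser values for test meshes)
#' @param parts character vector of parts to map
#' @return a `voxel_volume` list: integer array `elem`, `spacing`, `origin`
#'   (mm coordinates of the first voxel center)
#' @export
voxelize <- function(model, voxel_edge = 0.2, parts = "bone") {
  stopifnot(voxel_edge > 0)
  sel <- which(model$part %in% parts)
  if (!length(sel)) {
    return(structure(list(elem = array(0L, c(0, 0, 0)),
                          spacing = voxel_edge, origin = c(0, 0, 0)),
                     class = "voxel_volume"))
  }
  tets <- model$tets[sel, , drop = FALSE]
  used <- unique(as.vector(tets))
  lo <- apply(model$nodes[used, , drop = FALSE], 2, min)
  hi <- apply(model$nodes[used, , drop = FALSE], 2, max)
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_edge - 1e-9)))
  # sub-voxel irrational offset avoids sampling points falling exactly on
  # element faces (ties would bias per-element voxel counts)
  origin <- lo + voxel_edge / 2 + voxel_edge * c(0.0342871, 0.0587306, 0.0213549)
  arr <- array(0L, dims)
  nx <- dims[1]; ny <- dims[2]

  p1 <- model$nodes[tets[, 1], , drop = FALSE]
  p2 <- model$nodes[tets[, 2], , drop = FALSE]
  p3 <- model$nodes[tets[, 3], , drop = FALSE]
  p4 <- model$nodes[tets[, 4], , drop = FALSE]
  tol <- 1e-9
  for (e in seq_along(sel)) {
    r1 <- p1[e, ]; A <- cbind(p2[e, ] - r1, p3[e, ] - r1, p4[e, ] - r1)
    G <- solve(A)
    bb_lo <- pmin(r1, p2[e, ], p3[e, ], p4[e, ])
    bb_hi <- pmax(r1, p2[e, ], p3[e, ], p4[e, ])
    i0 <- pmax(1L, as.integer(ceiling((bb_lo - origin) / voxel_edge + 1 - tol)))
    i1 <- pmin(dims, as.integer(floor((bb_hi - origin) / voxel_edge + 1 + tol)))
    if (any(i1 < i0)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    cx <- origin[1] + (ii - 1) * voxel_edge
    cy <- origin[2] + (jj - 1) * voxel_edge
    cz <- origin[3] + (kk - 1) * voxel_edge
    ncand <- length(ii) * length(jj) * length(kk)
    px <- rep(cx, times = length(jj) * length(kk)) - r1[1]
    py <- rep(rep(cy, each = length(ii)), times = length(kk)) - r1[2]
    pz <- rep(cz, each = length(ii) * length(jj)) - r1[3]
    l2 <- G[1, 1] * px + G[1, 2] * py + G[1, 3] * pz
    l3 <- G[2, 1] * px + G[2, 2] * py + G[2, 3] * pz
    l4 <- G[3, 1] * px + G[3, 2] * py + G[3, 3] * pz
    inside <- l2 >= -tol & l3 >= -tol & l4 >= -tol & (l2 + l3 + l4) <= 1 + tol
    if (!any(inside)) next
    li <- rep(ii, times = length(jj) * length(kk)) +
      (rep(rep(jj, each = length(ii)), times = length(kk)) - 1L) * nx +
      (rep(kk, each = length(ii) * length(jj)) - 1L) * nx * ny
    li <- li[inside]
    li <- li[arr[li] == 0L]
    arr[li] <- sel[e]
  }
  structure(list(elem = arr, spacing = voxel_edge, origin = origin),
            class = "voxel_volume")
}

#' Sparse AP projection operator of a voxelized model
#'
#' Maps per-element density (g/cm^3) to the areal-BMD image vector (g/cm^2)
#' by summing voxel columns along +y.  Build once per model; reuse across
#' remodeling snapshots.
#'
#' @param vox a `voxel_volume`
#' @param n_elem total element count of the source model
#' @return a `dexa_projector`: sparse matrix `P` (pixels x elements), image
#'   dims/origin/spacing
#' @export
projection_operator <- function(vox, n_elem) {
  dims <- dim(vox$elem)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  filled <- which(vox$elem > 0L)
  i0 <- (filled - 1L) %% nx + 1L
  k0 <- (filled - 1L) %/% (nx * ny) + 1L
  pix <- i0 + (k0 - 1L) * nx
  P <- Matrix::sparseMatrix(i = pix, j = vox$elem[filled],
                            x = vox$spacing / 10,  # mm of bone -> cm
                            dims = c(nx * nz, n_elem))
  structure(list(P = P, nx = nx, nz = nz, spacing = vox$spacing,
                 origin = vox$origin[c(1, 3)]), class = "dexa_projector")
}

#' Project element densities to a virtual AP DEXA image
#'
#' @param proj a `dexa_projector` (or a `voxel_volume`, in which case the
#'   operator is built on the fly)
#' @param densities per-element apparent densities, g/cm^3 (NA for non-bone
#'   elements is treated as 0)
#' @return a `dexa_image`: matrix `bmd` (ML x axial, g/cm^2), `spacing`,
#'   `origin` of the first pixel center in model (x, z) mm
#' @export
project_ap <- function(proj, densities) {
  if (inherits(proj, "voxel_volume")) proj <- projection_operator(proj, length(densities))
  rho <- densities
  rho[is.na(rho)] <- 0
  v <- as.numeric(proj$P %*% rho)
  structure(list(bmd = matrix(v, proj$nx, proj$nz), spacing = proj$spacing,
                 origin = proj$origin), class = "dexa_image")
}

#' Place the three periprosthetic ROIs relative to the tray
#'
#' Medial and lateral ROIs are 1 cm^2 squares whose top edges lie 1 cm distal
#' to the baseplate plane, outer edges on the projected cortical silhouette;
#' the distal ROI lies 4 cm distal to the tray, ML-centered on the keel.
#'
#' @param implant an `implant_spec`
#' @param geom tibia geometry
#' @param roi_size ROI edge length, mm
#' @return named list of ROI specs, each with `name`, `x = c(lo, hi)`,
#'   `z = c(lo, hi)` in model coordinates (mm)
#' @export
place_rois <- function(implant, geom, roi_size = 10) {
  z_base <- resection_plane_z(0, implant, geom) + implant$cement_thickness
  z_prox <- c(z_base - 10 - roi_size, z_base - 10)
  z_dist <- c(z_base - 40 - roi_size, z_base - 40)
  x_out <- tibia_section(mean(z_prox), geom)$a
  kx <- implant$keel_center[1]
  list(
    medial = list(name = "medial", x = c(x_out - roi_size, x_out), z = z_prox),
    lateral = list(name = "lateral", x = c(-x_out, -x_out + roi_size), z = z_prox),
    distal = list(name = "distal", x = kx + c(-roi_size / 2, roi_size / 2),
                  z = z_dist))
}

# per-axis overlap weights of pixel cells with an interval
axis_weights <- function(n, origin, spacing, lo, hi) {
  edges_lo <- origin - spacing / 2 + (seq_len(n) - 1) * spacing
  edges_hi <- edges_lo + spacing
  pmax(0, pmin(edges_hi, hi) - pmax(edges_lo, lo)) / spacing
}

#' Mean areal BMD over a rectangular ROI
#'
#' ROI BMC (sum of pixel BMD times pixel area, partial edge pixels
#' area-weighted) divided by the ROI area.
#'
#' @param image a `dexa_image`
#' @param roi an ROI spec from [place_rois()]
#' @return mean areal BMD in the ROI, g/cm^2
#' @export
roi_bmd <- function(image, roi) {
  d <- dim(image$bmd); sp <- image$spacing
  span_x <- c(image$origin[1] - sp / 2, image$origin[1] + (d[1] - 0.5) * sp)
  span_z <- c(image$origin[2] - sp / 2, image$origin[2] + (d[2] - 0.5) * sp)
  if (roi$x[1] < span_x[1] - 1e-9 || roi$x[2] > span_x[2] + 1e-9 ||
      roi$z[1] < span_z[1] - 1e-9 || roi$z[2] > span_z[2] + 1e-9)
    stop(sprintf("ROI '%s' extends outside the image bounds", roi$name))
  wx <- axis_weights(d[1], image$origin[1], sp, roi$x[1], roi$x[2])
  wz <- axis_weights(d[2], image$origin[2], sp, roi$z[1], roi$z[2])
  area_px <- sp^2
  roi_area <- (roi$x[2] - roi$x[1]) * (roi$z[2] - roi$z[1])
  as.numeric(wx %*% image$bmd %*% wz) * area_px / roi_area
}

#' Per-element ROI evaluation vectors
#'
#' Precomputes, for each ROI, the vector q with ROI BMD = q . density, so a
#' full remodeling trajectory of ROI values costs one dot product per
#' snapshot.
#'
#' @param proj a `dexa_projector`
#' @param rois list from [place_rois()]
#' @return list of numeric vectors, one per ROI
#' @export
roi_operators <- function(proj, rois) {
  lapply(rois, function(roi) {
    wx <- axis_weights(proj$nx, proj$origin[1], proj$spacing, roi$x[1], roi$x[2])
    wz <- axis_weights(proj$nz, proj$origin[2], proj$spacing, roi$z[1], roi$z[2])
    w <- as.numeric(outer(wx, wz)) * proj$spacing^2 /
      ((roi$x[2] - roi$x[1]) * (roi$z[2] - roi$z[1]))
    as.numeric(Matrix::crossprod(proj$P, w))
  })
}

#' Total bone mineral content of a DEXA image
#' @param image a `dexa_image`
#' @return BMC in g (pixel BMD times pixel area summed)
#' @export
image_bmc <- function(image) sum(image$bmd) * (image$spacing / 10)^2

#' Write a DEXA image as 32-bit float TIFF with a JSON sidecar
#'
#' @param image a `dexa_image`
#' @param path output TIFF path (sidecar written next to it)
#' @param rois optional ROI list recorded in the sidecar
#' @return `path`, invisibly
#' @export
write_dexa_tiff <- function(image, path, rois = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF images")
  img <- t(image$bmd)[rev(seq_len(ncol(image$bmd))), , drop = FALSE]
  tiff::writeTIFF(img / max(img, 1e-12), path, bits.per.sample = 32L)
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(spacing_mm = image$spacing,
                            origin_mm = image$origin,
                            max_bmd = max(img), rois = rois),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
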