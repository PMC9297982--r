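#' Default parametric tibia geometry
#'
#' The synthetic proximal tibia is a lofted solid of elliptical cross
#' sections: a wide condylar plateau tapering through a metaphyseal flare to
#' a diaphyseal shaft.  The model frame has +z proximal along the mechanical
#' axis (plateau apex at z = 0), +y anterior and +x medial (left tibiae are
#' mirrored so one load frame serves both sides).
#'
#' @param mesh_edge target in-plane element edge length in mm.  2 mm matches
#'   the reference meshing density; coarser values (5-8 mm) are intended for
#'   tests and cohort-scale runs.
#' @return list of geometry parameters
#' @export
default_geometry <- function(mesh_edge = 5) {
  list(
    mesh_edge = mesh_edge,
    plateau_a = 38,      # ML half-width at the plateau, mm
    plateau_b = 26,      # AP half-depth at the plateau, mm
    shaft_a = 13, shaft_b = 12,
    flare_length = 55,   # decay length of the metaphyseal flare, mm
    flare_power = 1.8,
    length = 158,        # modeled extent below the plateau apex, mm
    top_extent = 6,      # grid headroom above the plateau for the implant stack
    interface_band = c(-14.5, -6.5),  # fine z-band around the resection plane
    interface_step = 0.75,            # z-step inside the band (cement scale), mm
    # density field
    rho_cort = 1.5,      # apparent density of fully dense cortex, g/cm^3
    cortical_thickness_meta = 0.75,   # emulated shell thickness at the plateau, mm
    cortical_thickness_shaft = 2.35,  # emulated shell thickness in the shaft, mm
    rho_canc0 = 0.38,    # cancellous apparent density at the plateau, g/cm^3
    rho_marrow = 0.05,   # asymptotic diaphyseal marrow-space density
    canc_decay = 42,     # proximodistal decay length of cancellous density, mm
    canc_decay_power = 1.5,
    ml_gradient = c(varus = 0.55, neutral = 0.22, valgus = -0.25),
    density_noise_sd = 0.08,
    rho_min = 0.01, rho_max = 1.73
  )
}

#' Elliptical half-axes of the tibia solid at height z
#'
#' @param z heights in mm (0 at plateau apex, negative distal)
#' @param geom geometry list
#' @return list with components `a` (ML) and `b` (AP), mm
#' @export
tibia_section <- function(z, geom) {
  f <- exp(-(pmax(-z, 0) / geom$flare_length)^geom$flare_power)
  list(a = geom$shaft_a + (geom$plateau_a - geom$shaft_a) * f,
       b = geom$shaft_b + (geom$plateau_b - geom$shaft_b) * f)
}

# squared relative radius: <= 1 inside the solid cross-section
tibia_srel <- function(x, y, z, geom) {
  s <- tibia_section(z, geom)
  (x / s$a)^2 + (y / s$b)^2
}

tibia_inside <- function(x, y, z, geom) {
  z <= 0 & z >= -geom$length & tibia_srel(x, y, z, geom) <= 1
}

# --- structured tetrahedral grid ------------------------------------------

# Kuhn/Freudenthal 6-tet split of each hex cell; globally conforming.
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  out <- matrix(0L, 6, 4)
  corner_id <- function(v) 1L + v[1] + 2L * v[2] + 4L * v[3]
  for (p in seq_len(6)) {
    v <- c(0L, 0L, 0L)
    ids <- corner_id(v)
    for (ax in perms[p, ]) {
      v[ax] <- 1L
      ids <- c(ids, corner_id(v))
    }
    out[p, ] <- ids
  }
  out
}

#' Build a structured tetrahedral grid over a box
#'
#' Nodes lie on the tensor grid given by the three coordinate vectors; each
#' hex cell is split into six conforming tetrahedra.
#'
#' @param xs,ys,zs strictly increasing coordinate vectors, mm
#' @return list(nodes, tets) with positively oriented tetrahedra
#' @keywords internal
tet_grid <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  corners <- cbind(nid(ci, cj, ck),       nid(ci + 1L, cj, ck),
                   nid(ci, cj + 1L, ck),  nid(ci + 1L, cj + 1L, ck),
                   nid(ci, cj, ck + 1L),  nid(ci + 1L, cj, ck + 1L),
                   nid(ci, cj + 1L, ck + 1L), nid(ci + 1L, cj + 1L, ck + 1L))
  kt <- kuhn_tets()
  tets <- do.call(rbind, lapply(seq_len(6), function(p) corners[, kt[p, ], drop = FALSE]))
  v <- tet_volumes_raw(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  list(nodes = nodes, tets = tets)
}

tet_volumes_raw <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]; p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]; p4 <- nodes[tets[, 4], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1; w <- p4 - p1
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Element volumes of a tibia model
#' @param model a `tibia_model`
#' @return numeric vector of tetrahedron volumes, mm^3
#' @export
tet_volumes <- function(model) tet_volumes_raw(model$nodes, model$tets)

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
   nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

# z-levels of the shared grid: coarse shaft, fine band at the implant
# interface, moderate spacing through the implant stack
grid_zlevels <- function(geom) {
  band <- geom$interface_band
  lo <- seq(-geom$length, band[1], by = geom$mesh_edge)
  if (max(lo) < band[1]) lo <- c(lo, band[1])
  mid <- seq(band[1], band[2], by = geom$interface_step)
  hi <- seq(band[2], geom$top_extent, by = min(geom$mesh_edge, 2.5))
  sort(unique(round(c(lo, mid, hi), 6)))
}

build_full_grid <- function(geom) {
  h <- geom$mesh_edge
  a <- geom$plateau_a; b <- geom$plateau_b
  xs <- seq(-(a + h), a + h, by = h)
  ys <- seq(-(b + h), b + h, by = h)
  zs <- grid_zlevels(geom)
  g <- tet_grid(xs, ys, zs)
  cen <- tet_centroids(g$nodes, g$tets)
  list(nodes = g$nodes, tets = g$tets, centroids = cen,
       inside = tibia_inside(cen[, 1], cen[, 2], cen[, 3], geom))
}

subset_model <- function(grid, keep, part, density, geom, provenance, extra = list()) {
  tets <- grid$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(grid$nodes)); remap[used] <- seq_along(used)
  m <- c(list(
    nodes = grid$nodes[used, , drop = FALSE],
    tets = matrix(remap[tets], ncol = 4),
    part = part, density = density,
    grid_tet_id = which(keep),
    geometry = geom, provenance = provenance), extra)
  class(m) <- "tibia_model"
  m
}

#' @export
print.tibia_model <- function(x, ...) {
  cat(sprintf("tibia_model (%s): %d nodes, %d tets [%s]\n",
              x$provenance, nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s=%d", names(table(x$part)), table(x$part)),
                    collapse = ", ")))
  invisible(x)
}

#' Subject-specific geometry: cross-sections scaled by the size factor
#'
#' @param record subject record (uses `size_factor`, default 1)
#' @param geom population geometry
#' @return scaled geometry list
#' @export
subject_geometry <- function(record, geom = default_geometry()) {
  sf <- record$size_factor %||% 1
  for (nm in c("plateau_a", "plateau_b", "shaft_a", "shaft_b"))
    geom[[nm]] <- geom[[nm]] * sf
  geom
}

#' Build a preoperative synthetic tibia
#'
#' Meshes the parametric solid with a conforming structured tet grid and
#' assigns an apparent-density field: a periosteal cortical shell (elements
#' with a node on/outside the lofted surface), a cancellous interior decaying
#' from the subchondral plateau into diaphyseal marrow, an alignment-dependent
#' medial-lateral gradient (varus knees denser medially), a subject-level
#' density factor and seeded multiplicative noise.
#'
#' @param record one-row subject record (see [generate_cohort()]); a minimal
#'   list with `subject_id`, `alignment_group` and `density_factor` suffices
#' @param geom geometry from [default_geometry()]
#' @param seed master seed; the density-noise substream is derived from it
#'   and the subject id
#' @return a `tibia_model` with parts all "bone" and per-element density
#' @export
build_preop_tibia <- function(record, geom = default_geometry(), seed = 1) {
  geom <- subject_geometry(record, geom)
  grid <- build_full_grid(geom)
  keep <- grid$inside
  if (!any(keep)) stop("degenerate geometry: empty solid")
  conn <- face_connected_keep(grid$tets[keep, , drop = FALSE], nrow(grid$nodes))
  keep[keep] <- conn
  cen <- grid$centroids[keep, , drop = FALSE]

  model <- subset_model(grid, keep, part = rep("bone", sum(keep)),
                        density = NULL, geom = geom, provenance = "preop",
                        extra = list(grid = grid, record = as.list(record)))
  v <- tet_volumes(model)
  if (any(v <= 0)) stop("degenerate geometry: non-positive element volume")

  # cortical shell: any node on or outside the lofted surface
  nsrel <- tibia_srel(model$nodes[, 1], model$nodes[, 2],
                      pmin(model$nodes[, 3], 0), geom)
  node_out <- nsrel >= 1 - 1e-9 | model$nodes[, 3] < -geom$length + 1e-9 |
              model$nodes[, 3] > 1e-9  # subchondral plate at the plateau
  cortical <- node_out[model$tets[, 1]] | node_out[model$tets[, 2]] |
              node_out[model$tets[, 3]] | node_out[model$tets[, 4]]

  grp <- record$alignment_group %||% "neutral"
  grad <- geom$ml_gradient[[grp]] %||% 0
  dfac <- record$density_factor %||% 1
  # shell elements are one element-layer thick; they carry the areal surface
  # density of a thin metaphyseal / thicker diaphyseal cortex regardless of
  # mesh resolution (equivalent-projection construction)
  flare <- exp(-(pmax(-cen[, 3], 0) / geom$flare_length)^geom$flare_power)
  t_cort <- geom$cortical_thickness_meta +
    (geom$cortical_thickness_shaft - geom$cortical_thickness_meta) * (1 - flare)
  rho_cort_eff <- geom$rho_cort * pmin(1, t_cort / geom$mesh_edge)
  sec <- tibia_section(cen[, 3], geom)
  axial <- geom$rho_marrow + (geom$rho_canc0 - geom$rho_marrow) *
    exp(-(pmax(-cen[, 3], 0) / geom$canc_decay)^geom$canc_decay_power)
  rho <- axial * (1 + grad * cen[, 1] / sec$a) * dfac

  set.seed(substream_seed(seed, paste0("density-noise-", record$subject_id %||% "S")))
  rho <- rho * exp(rnorm(length(rho), 0, geom$density_noise_sd))
  rho[cortical] <- rho_cort_eff[cortical] * dfac
  model$density <- clamp(rho, geom$rho_min, geom$rho_max)
  model$cortical <- cortical
  model
}

#' Implant specification from tray size
#'
#' Tray dimensions follow a linear size table expressed relative to the bone
#' cross-section at the resection depth, so the footprint always fits the
#' plateau; the resulting bone coverage is near 87\% at the median size.
#'
#' @param tray_size ordinal size in 1.5-4
#' @param geom tibia geometry
#' @param cement_thickness cement mantle, mm
#' @param resection_offset distance of the resection below the plateau apex, mm
#' @param posterior_slope posterior tilt of the resection plane, degrees
#' @param keel_length,keel_radius stem dimensions, mm
#' @param plate_thickness,insert_thickness tray and PE insert heights, mm
#' @param distal_cut modeled length below the resection, mm
#' @return an `implant_spec` list with footprint half-axes in mm
#' @export
make_implant_spec <- function(tray_size = 3, geom = default_geometry(),
                              cement_thickness = 0.75, resection_offset = 8,
                              posterior_slope = 5, keel_length = 30,
                              keel_radius = NULL, plate_thickness = 4,
                              insert_thickness = 8, distal_cut = 150) {
  stopifnot(cement_thickness > 0, keel_length < distal_cut)
  sec <- tibia_section(-(resection_offset + 3), geom)
  f <- min(0.84 + 0.036 * tray_size, 0.98)
  # keel sized with the tray so implant and bone stay geometrically similar
  if (is.null(keel_radius)) keel_radius <- 0.20 * f * sec$a
  spec <- list(
    tray_size = tray_size,
    tray_ml_width = 2 * f * sec$a, tray_ap_depth = 2 * f * sec$b,
    footprint_a = f * sec$a, footprint_b = f * sec$b,
    cement_thickness = cement_thickness, resection_offset = resection_offset,
    posterior_slope = posterior_slope, keel_length = keel_length,
    keel_radius = keel_radius, plate_thickness = plate_thickness,
    insert_thickness = insert_thickness, distal_cut = distal_cut,
    keel_center = c(0, 0), coverage = f^2)
  class(spec) <- "implant_spec"
  spec
}

#' Height of the sloped resection plane at AP position y
#'
#' The plane lies `resection_offset` below the plateau apex at the anterior
#' edge and tilts posteriorly by the posterior slope.
#'
#' @param y AP coordinates, mm
#' @param implant an `implant_spec`
#' @param geom tibia geometry
#' @return plane heights z(y), mm
#' @export
resection_plane_z <- function(y, implant, geom) {
  -implant$resection_offset +
    tan(implant$posterior_slope * pi / 180) * (y - geom$plateau_b)
}

#' Perform a virtual TKA on a preoperative tibia
#'
#' Removes bone elements whose centroids lie above the sloped resection plane
#' or inside the keel cavity, and adds cement, tray (plate + keel) and insert
#' element blocks on the same structured grid, so all parts share nodes
#' (fixed/tied contact) and every retained bone element corresponds to its
#' preoperative self by grid element id.
#'
#' @param preop `tibia_model` from [build_preop_tibia()]
#' @param implant an `implant_spec`
#' @return postop `tibia_model`; `$correspondence` maps each retained postop
#'   bone element (row index) to its preop element index, `$resected_preop`
#'   lists preop element indices removed
#' @export
perform_virtual_tka <- function(preop, implant) {
  geom <- preop$geometry
  grid <- preop$grid
  if (is.null(grid)) stop("preop model lacks its build grid")
  cen <- grid$centroids
  zp <- resection_plane_z(cen[, 2], implant, geom)

  sec_res <- tibia_section(mean(resection_plane_z(0, implant, geom)), geom)
  if (implant$footprint_a > sec_res$a || implant$footprint_b > sec_res$b)
    stop(sprintf(paste0("implant footprint exceeds plateau: overhang ML %.1f mm, ",
                        "AP %.1f mm"),
                 max(0, implant$footprint_a - sec_res$a),
                 max(0, implant$footprint_b - sec_res$b)))

  foot <- ((cen[, 1] - 0) / implant$footprint_a)^2 +
          ((cen[, 2] - 0) / implant$footprint_b)^2 <= 1
  rk2 <- (cen[, 1] - implant$keel_center[1])^2 +
         (cen[, 2] - implant$keel_center[2])^2
  keel_top <- zp
  keel_bot <- resection_plane_z(implant$keel_center[2], implant, geom) -
    implant$keel_length
  in_keel <- rk2 <= implant$keel_radius^2 & cen[, 3] <= keel_top &
    cen[, 3] >= keel_bot & grid$inside
  z_cem_top <- zp + implant$cement_thickness
  z_tray_top <- z_cem_top + implant$plate_thickness
  z_ins_top <- z_tray_top + implant$insert_thickness

  # the cement mantle spreads over the entire cut surface, so the cortical
  # rim participates in load transfer even at coarse mesh resolution
  cut_sec <- tibia_srel(cen[, 1], cen[, 2], zp, geom) <= 1
  part <- rep(NA_character_, nrow(cen))
  part[grid$inside & cen[, 3] <= zp] <- "bone"
  part[in_keel] <- "tray"
  part[cut_sec & cen[, 3] > zp & cen[, 3] <= z_cem_top] <- "cement"
  part[foot & cen[, 3] > z_cem_top & cen[, 3] <= z_tray_top] <- "tray"
  part[foot & cen[, 3] > z_tray_top & cen[, 3] <= z_ins_top] <- "insert"

  keep <- !is.na(part)
  # drop slivers hanging on a single node or edge (FE mechanisms)
  conn <- face_connected_keep(grid$tets[keep, , drop = FALSE], nrow(grid$nodes))
  keep[keep] <- conn
  post <- subset_model(grid, keep, part = part[keep], density = NULL,
                       geom = geom, provenance = "postop",
                       extra = list(record = preop$record, implant = implant))
  # correspondence by grid element id
  pre_ids <- preop$grid_tet_id
  match_pre <- match(post$grid_tet_id, pre_ids)
  is_bone <- post$part == "bone"
  if (anyNA(match_pre[is_bone]))
    stop("internal: retained bone element without preop parent")
  dens <- rep(NA_real_, nrow(post$tets))
  dens[is_bone] <- preop$density[match_pre[is_bone]]
  post$density <- dens
  post$cortical <- rep(FALSE, nrow(post$tets))
  post$cortical[is_bone] <- preop$cortical[match_pre[is_bone]]
  post$correspondence <- data.frame(postop_elem = which(is_bone),
                                    preop_elem = match_pre[is_bone])
  post$resected_preop <- setdiff(seq_along(pre_ids),
                                 match_pre[is_bone])
  post
}
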