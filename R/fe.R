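# linear-elastic FE on first-order tetrahedra (constant-strain elements)

#' Condyle peak-load table
#'
#' Alignment- and activity-specific tibiofemoral peak forces for gait, step
#' down (SD) and deep knee bend (DKB), per condyle, in percent body weight.
#'
#' @return data.frame(alignment, activity, condyle, f_med, f_ant, f_dist, f_res)
#' @export
condyle_load_table <- function() {
  path <- system.file("extdata", "condyle_peak_loads.csv", package = "tkaremod")
  if (path == "") path <- file.path("inst", "extdata", "condyle_peak_loads.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Resultant condyle force from its components
#'
#' @param components numeric length-3 (F_med, F_ant, F_dist) in \%BW, or a
#'   matrix with such rows
#' @return Euclidean norm(s), \%BW (unrounded; round only for table display)
#' @export
resultant_force <- function(components) {
  if (is.matrix(components)) return(sqrt(rowSums(components^2)))
  if (!all(is.finite(components))) stop("force components must be finite")
  sqrt(sum(components^2))
}

#' Scale a \%BW force triple to Newtons
#'
#' force_N = (\%BW / 100) * BW_kg * 9.81; missing body weight falls back to
#' the average female body weight of the modeled population (59 kg).  The
#' returned vector is the force applied to the tibia: medial (+x), anterior
#' (+y) and distal (-z) components.
#'
#' @param components c(F_med, F_ant, F_dist) in \%BW
#' @param bw_kg subject body weight, kg (NA allowed)
#' @param fallback_bw_kg imputation value for missing body weight
#' @return force vector in N, length 3
#' @export
scale_loads <- function(components, bw_kg, fallback_bw_kg = 59) {
  if (is.na(bw_kg)) bw_kg <- fallback_bw_kg
  if (!is.finite(bw_kg) || bw_kg <= 0) stop("body weight must be positive")
  f <- components / 100 * bw_kg * 9.81
  c(f[1], f[2], -f[3])
}

# unit-modulus isotropic Lame constants
lame0 <- function(nu) {
  list(lambda = nu / ((1 + nu) * (1 - 2 * nu)), mu = 1 / (2 * (1 + nu)))
}

#' Precompute the FE system structure for a tetrahedral model
#'
#' Computes element shape-function gradients, volumes and unit-modulus
#' stiffness triplets, folds in optional cartilage springs (each spring set
#' adds one anchor node loaded at the center of pressure), applies the fixed
#' boundary and caches the sparse-matrix slot mapping so re-assembly for new
#' element moduli is a single sparse product.
#'
#' @param model a `tibia_model`
#' @param fixed_nodes node indices fully constrained (e.g. the distal base)
#' @param fixed_dofs optional explicit constrained dof indices (3(n-1)+i for
#'   node n, direction i), overriding `fixed_nodes`; allows roller supports
#' @param springs optional list of spring sets from
#'   [build_cartilage_springs()]
#' @param nu Poisson ratio (single value for all parts)
#' @return an `fe_system` environment
#' @export
fe_setup <- function(model, fixed_nodes = NULL, springs = NULL, nu = 0.3,
                     fixed_dofs = NULL) {
  nodes <- model$nodes; tets <- model$tets
  n <- nrow(nodes); m <- nrow(tets)
  if (!length(fixed_nodes) && !length(fixed_dofs))
    stop("at least one constrained node or dof is required")

  p1 <- nodes[tets[, 1], , drop = FALSE]; p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]; p4 <- nodes[tets[, 4], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1; w <- p4 - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vxw <- cr(v, w)
  det <- rowSums(u * vxw)           # 6 V
  if (any(det <= 0)) stop("non-positively-oriented element encountered")
  vol <- det / 6
  g2 <- vxw / det; g3 <- cr(w, u) / det; g4 <- cr(u, v) / det
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  lam <- lame0(nu)
  # triplets: K_ab[i,j] = V (lam ga_i gb_j + mu ga_j gb_i + mu dij ga.gb)
  nt_tot <- 144L * m
  ii <- integer(nt_tot); jj <- integer(nt_tot); xx <- numeric(nt_tot)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    ga <- grads[[a]]; gb <- grads[[b]]
    dot <- rowSums(ga * gb)
    for (i in 1:3) for (j in 1:3) {
      val <- vol * (lam$lambda * ga[, i] * gb[, j] + lam$mu * ga[, j] * gb[, i] +
                    (if (i == j) lam$mu * dot else 0))
      idx <- pos + seq_len(m)
      ii[idx] <- 3L * (tets[, a] - 1L) + i
      jj[idx] <- 3L * (tets[, b] - 1L) + j
      xx[idx] <- val
      pos <- pos + m
    }
  }
  elem_of <- rep(seq_len(m), times = 144)

  # spring anchors appended as extra nodes
  n_anchor <- length(springs)
  anchor_ids <- if (n_anchor) n + seq_len(n_anchor) else integer(0)
  sp_i <- integer(0); sp_j <- integer(0); sp_x <- numeric(0)
  if (n_anchor) for (s in seq_len(n_anchor)) {
    sp <- springs[[s]]; q <- anchor_ids[s]
    d <- cbind(sp$anchor[1] - nodes[sp$nodes, 1],
               sp$anchor[2] - nodes[sp$nodes, 2],
               sp$anchor[3] - nodes[sp$nodes, 3])
    len <- sqrt(rowSums(d^2))
    d <- d / len
    for (i in 1:3) for (j in 1:3) {
      kd <- sp$k * d[, i] * d[, j]
      pdof <- 3L * (sp$nodes - 1L); qdof <- 3L * (q - 1L)
      sp_i <- c(sp_i, pdof + i, rep(qdof + i, length(sp$nodes)), pdof + i, rep(qdof + i, length(sp$nodes)))
      sp_j <- c(sp_j, pdof + j, rep(qdof + j, length(sp$nodes)), rep(qdof + j, length(sp$nodes)), pdof + j)
      sp_x <- c(sp_x, kd, kd, -kd, -kd)
    }
  }

  ntot <- n + n_anchor
  ndof <- 3L * ntot
  if (is.null(fixed_dofs))
    fixed_dofs <- as.vector(outer(1:3, 3L * (fixed_nodes - 1L), "+"))
  free <- rep(TRUE, ndof); free[fixed_dofs] <- FALSE
  fmap <- integer(ndof); fmap[free] <- seq_len(sum(free))
  Nf <- sum(free)

  keep_t <- free[ii] & free[jj]
  iif <- fmap[ii[keep_t]]; jjf <- fmap[jj[keep_t]]
  xxf <- xx[keep_t]; elemf <- elem_of[keep_t]
  lower <- iif >= jjf
  iif <- iif[lower]; jjf <- jjf[lower]; xxf <- xxf[lower]; elemf <- elemf[lower]

  keep_s <- if (length(sp_i)) free[sp_i] & free[sp_j] else logical(0)
  spi <- fmap[sp_i[keep_s]]; spj <- fmap[sp_j[keep_s]]; spx <- sp_x[keep_s]
  slow <- spi >= spj
  spi <- spi[slow]; spj <- spj[slow]; spx <- spx[slow]

  # pattern matrix (upper storage: row = col index of lower pair)
  K0 <- Matrix::sparseMatrix(i = c(jjf, spj), j = c(iif, spi),
                             x = c(xxf, spx), dims = c(Nf, Nf),
                             symmetric = TRUE)
  Kcs <- methods::as(K0, "CsparseMatrix")
  colK <- rep(seq_len(Nf), diff(Kcs@p))
  idK <- (as.double(colK) - 1) * Nf + (Kcs@i + 1)
  id_t <- (as.double(iif) - 1) * Nf + jjf
  slot <- match(id_t, idK)
  Mmap <- Matrix::sparseMatrix(i = slot, j = elemf, x = xxf,
                               dims = c(length(idK), m))
  spring_x <- numeric(length(idK))
  if (length(spi)) {
    id_s <- (as.double(spi) - 1) * Nf + spj
    slot_s <- match(id_s, idK)
    for (t in seq_along(slot_s))
      spring_x[slot_s[t]] <- spring_x[slot_s[t]] + spx[t]
  }

  sys <- new.env(parent = emptyenv())
  sys$model <- model
  sys$n_mesh_nodes <- n; sys$n_anchor <- n_anchor; sys$anchor_ids <- anchor_ids
  sys$springs <- springs
  sys$nu <- nu; sys$vol <- vol; sys$grads <- grads
  sys$tets <- tets; sys$m <- m; sys$ntot <- ntot
  sys$free <- free; sys$fmap <- fmap; sys$Nf <- Nf
  sys$K <- Kcs; sys$Mmap <- Mmap; sys$spring_x <- spring_x
  sys$chol <- NULL
  class(sys) <- c("fe_system", class(sys))
  sys
}

#' Assemble and factorize the stiffness for given element moduli
#'
#' @param sys an `fe_system`
#' @param E per-element elastic moduli, MPa (all > 0)
#' @return the system, with an up-to-date Cholesky factor cached
#' @export
fe_assemble <- function(sys, E) {
  stopifnot(length(E) == sys$m, all(E > 0))
  x <- as.numeric(sys$Mmap %*% E) + sys$spring_x
  K <- sys$K
  K@x <- x
  sys$K <- K
  if (is.null(sys$chol)) {
    sys$chol <- Matrix::Cholesky(K, LDL = FALSE)
  } else {
    sys$chol <- Matrix::update(sys$chol, K)
  }
  invisible(sys)
}

#' Solve the assembled system for one or more load cases
#'
#' @param sys an `fe_system` after [fe_assemble()]
#' @param forces a (total nodes x 3) force matrix in N, or a list of them;
#'   rows beyond the mesh nodes address spring anchor nodes
#' @return displacement matrix (total nodes x 3) in mm, or a list of them
#' @export
fe_solve <- function(sys, forces) {
  if (is.null(sys$chol)) stop("call fe_assemble() first")
  single <- !is.list(forces)
  flist <- if (single) list(forces) else forces
  out <- lapply(flist, function(fm) {
    stopifnot(nrow(fm) == sys$ntot)
    f <- as.vector(t(fm))          # dof order (3(n-1)+i)
    uf <- as.numeric(Matrix::solve(sys$chol, f[sys$free], system = "A"))
    u <- numeric(3L * sys$ntot)
    u[sys$free] <- uf
    matrix(u, ncol = 3, byrow = TRUE)
  })
  if (single) out[[1]] else out
}

#' Per-element strain energy density for a solved displacement field
#'
#' U = 1/2 eps^T sigma from the constant element strain, in MPa (N mm/mm^3).
#'
#' @param sys an `fe_system`
#' @param u displacement matrix from [fe_solve()]
#' @param E per-element moduli used in the solve
#' @return numeric vector of SED per element (non-negative)
#' @export
element_sed <- function(sys, u, E) {
  g <- sys$grads; tets <- sys$tets
  exx <- eyy <- ezz <- gxy <- gyz <- gzx <- numeric(sys$m)
  for (a in 1:4) {
    ga <- g[[a]]
    ua <- u[tets[, a], , drop = FALSE]
    exx <- exx + ga[, 1] * ua[, 1]
    eyy <- eyy + ga[, 2] * ua[, 2]
    ezz <- ezz + ga[, 3] * ua[, 3]
    gxy <- gxy + ga[, 2] * ua[, 1] + ga[, 1] * ua[, 2]
    gyz <- gyz + ga[, 3] * ua[, 2] + ga[, 2] * ua[, 3]
    gzx <- gzx + ga[, 1] * ua[, 3] + ga[, 3] * ua[, 1]
  }
  lam <- lame0(sys$nu)
  tr <- exx + eyy + ezz
  0.5 * E * (lam$lambda * tr^2 + 2 * lam$mu * (exx^2 + eyy^2 + ezz^2) +
             lam$mu * (gxy^2 + gyz^2 + gzx^2))
}

#' Reaction forces at the fixed base
#'
#' Recovers K u over all dofs (including constrained rows) from the element
#' contributions and sums the reactions at the fixed nodes.
#'
#' @param sys an `fe_system`
#' @param u displacement matrix
#' @param E per-element moduli
#' @return length-3 reaction force vector, N
#' @export
base_reactions <- function(sys, u, E) {
  # element-level K u accumulated at fixed nodes only
  g <- sys$grads; tets <- sys$tets; lam <- lame0(sys$nu)
  exx <- eyy <- ezz <- gxy <- gyz <- gzx <- numeric(sys$m)
  for (a in 1:4) {
    ga <- g[[a]]; ua <- u[tets[, a], , drop = FALSE]
    exx <- exx + ga[, 1] * ua[, 1]; eyy <- eyy + ga[, 2] * ua[, 2]
    ezz <- ezz + ga[, 3] * ua[, 3]
    gxy <- gxy + ga[, 2] * ua[, 1] + ga[, 1] * ua[, 2]
    gyz <- gyz + ga[, 3] * ua[, 2] + ga[, 2] * ua[, 3]
    gzx <- gzx + ga[, 1] * ua[, 3] + ga[, 3] * ua[, 1]
  }
  lamE <- lam$lambda * E; muE <- lam$mu * E
  tr <- exx + eyy + ezz
  sxx <- lamE * tr + 2 * muE * exx; syy <- lamE * tr + 2 * muE * eyy
  szz <- lamE * tr + 2 * muE * ezz
  txy <- muE * gxy; tyz <- muE * gyz; tzx <- muE * gzx
  fixed <- which(!sys$free)
  fixed_nodes <- unique((fixed - 1L) %/% 3L + 1L)
  R <- c(0, 0, 0)
  for (a in 1:4) {
    ga <- g[[a]]
    fa <- cbind(sxx * ga[, 1] + txy * ga[, 2] + tzx * ga[, 3],
                txy * ga[, 1] + syy * ga[, 2] + tyz * ga[, 3],
                tzx * ga[, 1] + tyz * ga[, 2] + szz * ga[, 3]) * sys$vol
    sel <- tets[, a] %in% fixed_nodes
    if (any(sel)) R <- R + colSums(fa[sel, , drop = FALSE])
  }
  R
}

#' Build cartilage springs connecting a center of pressure to the surface
#'
#' Selects proximal-surface nodes nearest (in the transverse plane) to the
#' COP until their tributary areas fill the requested contact area; each
#' spring gets k_i = E_cart * A_i / L_i with A_i the node tributary area and
#' L_i its distance to the COP.
#'
#' @param model preoperative `tibia_model`
#' @param cop center of pressure, c(x, y, z) mm (z above the surface)
#' @param contact_area condyle contact area to fill, mm^2
#' @param E_cart compressive modulus of the articular cartilage, MPa
#' @param surface_z_min proximal-surface cutoff: boundary faces with upward
#'   normal and centroid above this height participate
#' @return a spring set list(anchor, nodes, k, areas)
#' @export
build_cartilage_springs <- function(model, cop, contact_area, E_cart = 9,
                                    surface_z_min = -6) {
  stopifnot(contact_area > 0, E_cart > 0)
  faces <- boundary_faces(model)
  top <- faces[faces$nz > 0.5 & faces$cz > surface_z_min, ]
  if (!nrow(top)) stop("no proximal surface found")
  areas <- tributary_areas(top, nrow(model$nodes))
  cand <- which(areas > 0)
  d_xy <- sqrt((model$nodes[cand, 1] - cop[1])^2 +
               (model$nodes[cand, 2] - cop[2])^2)
  ord <- order(d_xy)
  cum <- cumsum(areas[cand][ord])
  n_sel <- max(1L, which(cum >= contact_area)[1])
  if (is.na(n_sel)) n_sel <- length(cand)
  sel <- cand[ord[seq_len(n_sel)]]
  L <- sqrt(rowSums((model$nodes[sel, , drop = FALSE] -
                     matrix(cop, n_sel, 3, byrow = TRUE))^2))
  if (any(L <= 0)) stop("COP coincides with a surface node")
  list(anchor = cop, nodes = sel, k = E_cart * areas[sel] / L,
       areas = areas[sel])
}

#' Axial spring forces of a solved spring set
#'
#' @param sys an `fe_system` with springs
#' @param u displacement matrix from [fe_solve()]
#' @param which_spring index of the spring set
#' @return summed axial spring force vector transmitted from the anchor to
#'   the bone surface, N (equals the condyle load applied at the anchor)
#' @export
spring_forces <- function(sys, u, which_spring = 1) {
  sp <- sys$springs[[which_spring]]
  q <- sys$anchor_ids[which_spring]
  nd <- sys$model$nodes[sp$nodes, , drop = FALSE]
  d <- cbind(sp$anchor[1] - nd[, 1], sp$anchor[2] - nd[, 2],
             sp$anchor[3] - nd[, 3])
  d <- d / sqrt(rowSums(d^2))
  rel <- matrix(u[q, ], nrow(d), 3, byrow = TRUE) - u[sp$nodes, , drop = FALSE]
  ext <- rowSums(rel * d)            # elongation along the spring axis
  colSums(d * (sp$k * ext))
}

#' Distribute condyle forces over insert-surface nodes
#'
#' Area-weighted distribution over insert top-surface nodes within a contact
#' radius around each COP.
#'
#' @param model postop `tibia_model`
#' @param cops list of COP positions (x, y) per condyle
#' @param forces list of length-3 force vectors (N) per condyle
#' @param radius contact patch radius, mm
#' @return (n_nodes x 3) nodal force matrix
#' @export
apply_insert_loads <- function(model, cops, forces, radius = 12) {
  faces <- boundary_faces(model, model$part == "insert")
  if (!nrow(faces)) stop("model has no insert part")
  zmax <- max(faces$cz)
  top <- faces[faces$nz > 0.3 & faces$cz > zmax - 6, ]
  areas <- tributary_areas(top, nrow(model$nodes))
  fmat <- matrix(0, nrow(model$nodes), 3)
  for (c_i in seq_along(cops)) {
    cop <- cops[[c_i]]
    cand <- which(areas > 0)
    d <- sqrt((model$nodes[cand, 1] - cop[1])^2 +
              (model$nodes[cand, 2] - cop[2])^2)
    sel <- cand[d <= radius]
    if (!length(sel)) sel <- cand[order(d)[seq_len(min(4, length(cand)))]]
    w <- areas[sel] / sum(areas[sel])
    fmat[sel, ] <- fmat[sel, ] + outer(w, forces[[c_i]])
  }
  fmat
}

#' Averaged strain energy density over the three activity peak loads
#'
#' @param sed_list list of three per-element SED vectors (gait, SD, DKB)
#' @return per-element arithmetic mean
#' @export
averaged_sed <- function(sed_list) {
  if (length(sed_list) != 3) stop("three activity SED fields are required")
  (sed_list[[1]] + sed_list[[2]] + sed_list[[3]]) / 3
}
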