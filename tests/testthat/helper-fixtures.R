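# shared fixtures, built once per test run and cached across files

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# rectangular block meshed with conforming tets
block_mesh <- function(Lx = 10, Ly = 10, Lz = 20, h = 5, rho = 1) {
  g <- tkaremod:::tet_grid(seq(0, Lx, h), seq(0, Ly, h), seq(0, Lz, h))
  structure(list(nodes = g$nodes, tets = g$tets,
                 part = rep("bone", nrow(g$tets)),
                 density = rep(rho, nrow(g$tets)), provenance = "test"),
            class = "tibia_model")
}

# generic-position block: rotated so element faces do not align with voxel
# lattice planes
rotated_block <- function(L = 10, h = 5, th1 = 20 * pi / 180, th2 = 31 * pi / 180) {
  m <- block_mesh(L, L, L, h)
  R1 <- rbind(c(cos(th1), -sin(th1), 0), c(sin(th1), cos(th1), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(th2), -sin(th2)), c(0, sin(th2), cos(th2)))
  m$nodes <- m$nodes %*% t(R2 %*% R1)
  m
}

test_record <- function(group = "varus", dfac = 1, size = 1, id = "T1",
                        tray = 3, bw = 60) {
  list(subject_id = id, alignment_group = group, density_factor = dfac,
       size_factor = size, tray_size = tray, body_weight = bw)
}

small_tibia <- function() fixture("small_tibia",
  build_preop_tibia(test_record(), default_geometry(8), seed = 7))

small_implant <- function() fixture("small_implant",
  make_implant_spec(3, small_tibia()$geometry))

small_postop <- function() fixture("small_postop",
  perform_virtual_tka(small_tibia(), small_implant()))

# full default cohort pipeline (the heavyweight fixture; several minutes)
cohort_result <- function() fixture("cohort_result",
  run_pipeline(default_run_config(seed = 1)))

# axial patch test solution on a block with roller base
solve_patch <- function(E0 = 1000, sigma = 2, h = 5) {
  mesh <- block_mesh(10, 10, 20, h)
  base <- which(mesh$nodes[, 3] == 0)
  fd <- c(3 * (base - 1) + 3,
          3 * (which(mesh$nodes[, 1] == 0 & mesh$nodes[, 3] == 0) - 1) + 1,
          3 * (which(mesh$nodes[, 2] == 0 & mesh$nodes[, 3] == 0) - 1) + 2)
  sys <- fe_setup(mesh, fixed_dofs = fd)
  fe_assemble(sys, rep(E0, sys$m))
  faces <- boundary_faces(mesh)
  top <- faces[faces$nz > 0.5 & faces$cz == 20, ]
  A <- tributary_areas(top, nrow(mesh$nodes))
  f <- matrix(0, sys$ntot, 3)
  f[, 3] <- A * sigma
  u <- fe_solve(sys, f)
  list(mesh = mesh, sys = sys, u = u, E0 = E0, sigma = sigma)
}
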