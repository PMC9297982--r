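test_that("resultant condyle forces reproduce the tabulated values", {
  expect_equal(round(resultant_force(c(-3, -15, 232))), 233)
  expect_equal(round(resultant_force(c(-9, 9, 294))), 294)
  expect_equal(round(resultant_force(c(-9, 6, 114))), 115)
  expect_equal(round(resultant_force(c(14, -12, 177))), 178)
  expect_equal(round(resultant_force(c(32, 13, 269))), 271)
  expect_equal(resultant_force(c(0, 0, 0)), 0)
  expect_error(resultant_force(c(1, NA, 2)), "finite")
  tab <- condyle_load_table()
  fres <- round(resultant_force(as.matrix(tab[, c("f_med", "f_ant", "f_dist")])))
  expect_true(all(abs(fres - tab$f_res) <= 1))   # components printed rounded
})

test_that("load scaling converts %BW to Newtons with the 59 kg fallback", {
  f <- scale_loads(c(0, 0, 232), bw_kg = 75)
  expect_equal(f[3], -232 / 100 * 75 * 9.81)
  expect_equal(abs(f[3]), 1706.9, tolerance = 1e-4)
  expect_equal(scale_loads(c(10, -5, 100), NA), scale_loads(c(10, -5, 100), 59))
  expect_error(scale_loads(c(1, 1, 1), 0), "positive")
  expect_error(scale_loads(c(1, 1, 1), -5), "positive")
})

test_that("uniaxial patch test is exact: tip displacement and element SED", {
  p <- solve_patch()
  tip <- p$u[p$mesh$nodes[, 3] == 20, 3]
  u_exact <- p$sigma * 20 / p$E0
  expect_lt(max(abs(tip - u_exact)) / u_exact, 1e-8)
  sed <- element_sed(p$sys, p$u, rep(p$E0, p$sys$m))
  sed_exact <- p$sigma^2 / (2 * p$E0)
  expect_lt(max(abs(sed - sed_exact)) / sed_exact, 1e-8)
  expect_true(all(sed >= 0))
})

test_that("zero load on a constrained model gives zero displacement and SED", {
  mesh <- block_mesh(10, 10, 10, 5)
  sys <- fe_setup(mesh, fixed_nodes = which(mesh$nodes[, 3] == 0))
  fe_assemble(sys, rep(500, sys$m))
  u <- fe_solve(sys, matrix(0, sys$ntot, 3))
  expect_equal(max(abs(u)), 0)
  expect_equal(max(element_sed(sys, u, rep(500, sys$m))), 0)
})

test_that("element SED matches a brute-force element-energy oracle", {
  mesh <- rotated_block(10, 5)
  base <- which(abs(mesh$nodes[, 3] - min(mesh$nodes[, 3])) < 3)
  sys <- fe_setup(mesh, fixed_nodes = base)
  E <- withr::with_seed(11, runif(sys$m, 500, 5000))
  fe_assemble(sys, E)
  f <- matrix(0, sys$ntot, 3)
  top <- which(mesh$nodes[, 3] > max(mesh$nodes[, 3]) - 3)
  f[top, ] <- withr::with_seed(12, matrix(rnorm(length(top) * 3, sd = 5), ncol = 3))
  u <- fe_solve(sys, f)
  sed <- element_sed(sys, u, E)

  ke_oracle <- function(X, E1, nu) {      # textbook B^T D B assembly
    M <- cbind(1, X)
    C <- solve(M)
    V <- det(M) / 6
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      g <- C[2:4, a]; col <- (a - 1) * 3
      B[1, col + 1] <- g[1]; B[2, col + 2] <- g[2]; B[3, col + 3] <- g[3]
      B[4, col + 1] <- g[2]; B[4, col + 2] <- g[1]
      B[5, col + 2] <- g[3]; B[5, col + 3] <- g[2]
      B[6, col + 1] <- g[3]; B[6, col + 3] <- g[1]
    }
    lam <- E1 * 0.3 / (1.3 * 0.4); mu <- E1 / 2.6
    D <- matrix(0, 6, 6)
    D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
    list(K = abs(V) * t(B) %*% D %*% B, V = abs(V))
  }
  for (e in unique(round(seq(1, sys$m, length.out = 20)))) {
    X <- mesh$nodes[mesh$tets[e, ], ]
    ko <- ke_oracle(X, E[e], 0.3)
    ue <- as.vector(t(u[mesh$tets[e, ], ]))
    expect_equal(sed[e], 0.5 * drop(ue %*% ko$K %*% ue) / ko$V,
                 tolerance = 1e-9)
  }
})

test_that("global equilibrium holds: base reactions balance applied loads", {
  p <- solve_patch()
  R <- base_reactions(p$sys, p$u, rep(p$E0, p$sys$m))
  applied <- c(0, 0, p$sigma * 100)
  expect_lt(sqrt(sum((R + applied)^2)) / sqrt(sum(applied^2)), 1e-6)
})

test_that("SED is invariant under rigid rotation of model and loads", {
  mesh <- block_mesh(10, 10, 20, 5)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  base0 <- which(mesh$nodes[, 3] == 0)
  sys0 <- fe_setup(mesh, fixed_nodes = base0)
  fe_assemble(sys0, rep(1000, sys0$m))
  f0 <- matrix(0, sys0$ntot, 3)
  top0 <- which(mesh$nodes[, 3] == 20)
  f0[top0, ] <- matrix(c(3, 1, -10), length(top0), 3, byrow = TRUE)
  sed0 <- element_sed(sys0, fe_solve(sys0, f0), rep(1000, sys0$m))

  rot <- mesh; rot$nodes <- mesh$nodes %*% t(R)
  sysr <- fe_setup(rot, fixed_nodes = base0)
  fe_assemble(sysr, rep(1000, sysr$m))
  fr <- matrix(0, sysr$ntot, 3)
  fr[top0, ] <- matrix(as.numeric(R %*% c(3, 1, -10)), length(top0), 3, byrow = TRUE)
  sedr <- element_sed(sysr, fe_solve(sysr, fr), rep(1000, sysr$m))
  expect_equal(sedr, sed0, tolerance = 1e-9)
})

test_that("energy-norm error halves under mesh refinement on a graded-stress bar", {
  # bar under uniform axial body force, nu = 0: exact 1D solution
  E0 <- 1000; b <- 0.5; L <- 16
  energy_at <- function(h) {
    g <- tkaremod:::tet_grid(seq(0, 4, h), seq(0, 4, h), seq(0, L, h))
    mesh <- structure(list(nodes = g$nodes, tets = g$tets,
                           part = rep("bone", nrow(g$tets))),
                      class = "tibia_model")
    base <- which(mesh$nodes[, 3] == 0)
    n <- nrow(mesh$nodes)
    fd <- c(3 * (base - 1) + 3, as.vector(outer(1:2, 3 * (seq_len(n) - 1), "+")))
    sys <- fe_setup(mesh, fixed_dofs = fd, nu = 0)
    fvec <- numeric(n)
    for (a in 1:4) {
      tab <- tapply(sys$vol / 4, mesh$tets[, a], sum)
      fvec[as.integer(names(tab))] <- fvec[as.integer(names(tab))] + tab
    }
    fe_assemble(sys, rep(E0, sys$m))
    f <- matrix(0, sys$ntot, 3); f[, 3] <- b * fvec
    u <- fe_solve(sys, f)
    sum(element_sed(sys, u, rep(E0, sys$m)) * sys$vol)
  }
  exact <- 16 * b^2 * L^3 / (6 * E0)
  err <- sqrt(exact - c(energy_at(2), energy_at(1)))
  expect_gt(err[1] / err[2], 1.7)
  expect_lt(err[1] / err[2], 2.3)
})

test_that("cartilage springs fill the contact area nearest-first with k = EA/L", {
  pre <- small_tibia()
  ztop <- max(pre$nodes[, 3])
  cop <- c(10, 0, ztop + 10)
  sp_small <- build_cartilage_springs(pre, cop, contact_area = 1)
  expect_equal(length(sp_small$nodes), 1)
  L <- sqrt(sum((pre$nodes[sp_small$nodes, ] - cop)^2))
  expect_equal(sp_small$k, 9 * sp_small$areas / L)
  sp_big <- build_cartilage_springs(pre, cop, contact_area = 300)
  expect_gte(length(sp_big$nodes), length(sp_small$nodes))
  sp_bigger <- build_cartilage_springs(pre, cop, contact_area = 600)
  expect_gte(length(sp_bigger$nodes), length(sp_big$nodes))
  expect_true(all(sp_bigger$k > 0))
})

test_that("spring loading is in static equilibrium with the applied condyle force", {
  pre <- small_tibia()
  ztop <- max(pre$nodes[, 3])
  springs <- list(build_cartilage_springs(pre, c(12, 0, ztop + 10), 300),
                  build_cartilage_springs(pre, c(-12, 0, ztop + 10), 300))
  base <- which(pre$nodes[, 3] < min(pre$nodes[, 3]) + 12)
  sys <- fe_setup(pre, base, springs)
  mats <- assign_materials(pre)
  fe_assemble(sys, mats$E)
  fm <- matrix(0, sys$ntot, 3)
  fload <- c(50, -20, -800)
  fm[sys$anchor_ids[1], ] <- fload
  u <- fe_solve(sys, fm)
  transmitted <- spring_forces(sys, u, 1)
  expect_lt(sqrt(sum((transmitted - fload)^2)) / sqrt(sum(fload^2)), 1e-6)
  # unloaded condyle transmits nothing
  expect_lt(sqrt(sum(spring_forces(sys, u, 2)^2)) / sqrt(sum(fload^2)), 1e-6)
})

test_that("insert loads are distributed over the contact patches and sum exactly", {
  post <- small_postop()
  fm <- apply_insert_loads(post, list(c(9, 0), c(-9, 0)),
                           list(c(10, 5, -500), c(0, 0, -300)), radius = 12)
  expect_equal(colSums(fm), c(10, 5, -800))
  loaded <- which(rowSums(abs(fm)) > 0)
  expect_true(all(post$nodes[loaded, 3] > -9))  # on the insert top surface
})

test_that("averaged SED is the arithmetic mean of the three activities", {
  x <- list(c(1, 4), c(2, 5), c(3, 6))
  expect_equal(averaged_sed(x), c(2, 5))
  same <- list(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(averaged_sed(same), c(1, 2))
  expect_error(averaged_sed(x[1:2]), "three")
})

test_that("a floating part makes the solve fail loudly", {
  mesh <- block_mesh(10, 10, 10, 5)
  # duplicate the block far away without any constraint path
  m2 <- mesh
  m2$nodes <- rbind(mesh$nodes, mesh$nodes + 100)
  m2$tets <- rbind(mesh$tets, mesh$tets + nrow(mesh$nodes))
  m2$part <- rep("bone", nrow(m2$tets))
  sys <- fe_setup(m2, fixed_nodes = which(m2$nodes[, 3] == 0 & m2$nodes[, 1] <= 10))
  expect_error(suppressWarnings({
    fe_assemble(sys, rep(1000, sys$m))
    fe_solve(sys, matrix(1, sys$ntot, 3))
  }))
})
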