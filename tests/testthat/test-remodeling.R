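test_that("free surface vanishes for fully dense bone and peaks inside (0,1)", {
  fs <- default_free_surface()
  expect_equal(free_surface(fs$rho_cort, fs), 0)
  # frozen value: independent evaluation of the default quintic at p = 0.5
  # 32.3*.5 - 93.9*.25 + 134*.125 - 101*.0625 + 28.8*.03125 = 4.0125
  expect_equal(free_surface(fs$rho_cort * 0.5, fs), 4.0125)
  p <- seq(0.001, 0.999, length.out = 2000)
  a <- free_surface(fs$rho_cort * (1 - p), fs)
  expect_true(all(a >= 0))
  imax <- which.max(a)
  expect_gt(imax, 1); expect_lt(imax, length(p))
  # single interior maximum: increasing before, decreasing after
  expect_true(all(diff(a[1:imax]) >= -1e-12))
  expect_true(all(diff(a[imax:length(a)]) <= 1e-12))
})

test_that("remodeling rate follows the lazy-zone branches", {
  expect_equal(remodeling_rate(S = 1, Sref = 1, a = 5), 0)
  expect_equal(remodeling_rate(S = 2, Sref = 1, a = 1), 2 - 1.35)
  expect_equal(remodeling_rate(S = 0.5, Sref = 1, a = 1), 0.5 - 0.65)
  expect_equal(remodeling_rate(S = 1.3, Sref = 1, a = 7), 0)   # inside zone
  expect_equal(remodeling_rate(S = 0.7, Sref = 1, a = 7), 0)
  # free-surface scaling
  expect_equal(remodeling_rate(2, 1, a = 3), 3 * 0.65)
  expect_error(remodeling_rate(-1, 1, 1), "non-negative")
})

test_that("rate is continuous at the lazy-zone boundaries to machine precision", {
  eps <- 1e-12
  r_hi_out <- remodeling_rate(1.35 + eps, 1, a = 10)
  r_hi_in <- remodeling_rate(1.35 - eps, 1, a = 10)
  expect_lt(abs(r_hi_out), 1e-10)
  expect_equal(r_hi_in, 0)
  r_lo_out <- remodeling_rate(0.65 - eps, 1, a = 10)
  expect_lt(abs(r_lo_out), 1e-10)
  expect_equal(remodeling_rate(0.65 + eps, 1, a = 10), 0)
  # boundary points themselves: active branch evaluates to exactly zero
  expect_equal(remodeling_rate(1.35, 1, a = 10), 0)
  expect_equal(remodeling_rate(0.65, 1, a = 10), 0)
})

test_that("rate is non-decreasing in S for fixed Sref and a", {
  S <- seq(0, 3, by = 0.01)
  r <- remodeling_rate(S, rep(1, length(S)), rep(2, length(S)))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("elements with negligible reference stimulus stay lazy", {
  expect_equal(remodeling_rate(1, 0, a = 5), 0)
  expect_equal(remodeling_rate(1, 1e-12, a = 5), 0)
})

test_that("adaptive Euler stepping caps the density change and clamps bounds", {
  p <- default_remodeling_params()
  st <- advance_state(c(0.5, 0.6), c(0, 0), p)
  expect_equal(st$rho, c(0.5, 0.6))
  expect_equal(st$dt, p$dt_max)
  # a constant-rate element advances by exactly drho_cap when rate-limited
  r <- 0.2  # drho_cap / r = 0.25 < dt_max
  st2 <- advance_state(0.5, r, p)
  expect_equal(st2$rho - 0.5, p$drho_cap)
  expect_equal(st2$dt, p$drho_cap / r)
  # clamping at the upper bound
  st3 <- advance_state(p$rho_max, 1, p)
  expect_equal(st3$rho, p$rho_max)
})

test_that("single-element trajectory matches a fine-step reference within 1%", {
  p <- default_remodeling_params(dt_max = 5)
  fs <- default_free_surface()
  Sref <- 2e-3
  S <- 0.4 * Sref           # constant under-loading, below the lazy zone
  a0 <- free_surface(0.5, fs)   # held constant
  step_traj <- function(dt_max, drho_cap) {
    pp <- default_remodeling_params(dt_max = dt_max, drho_cap = drho_cap)
    rho <- 0.5; t <- 0; out <- list()
    horizon <- pp$years * pp$ctu_per_year
    while (t < horizon) {
      rate <- remodeling_rate(S, Sref, a0, pp$lazy_zone)
      st <- advance_state(rho, rate, pp)
      rho <- st$rho; t <- t + st$dt
      out[[length(out) + 1]] <- c(t, rho)
    }
    do.call(rbind, out)
  }
  coarse <- step_traj(5, 0.05)
  fine <- step_traj(0.01, 1e-4)     # fine-step reference integration
  at <- function(tr, tq) stats::approx(tr[, 1], tr[, 2], tq, rule = 2)$y
  for (tq in c(60, 150, 348, 450)) {
    expect_lt(abs(at(coarse, tq) - at(fine, tq)) / at(fine, tq), 0.01)
  }
  # closed form while unclamped: rho(t) = 0.5 + a0 (S - 0.65 Sref) t
  r0 <- a0 * (S - 0.65 * Sref)
  expect_lt(abs(at(fine, 100) - (0.5 + r0 * 100)) / (0.5 + r0 * 100), 1e-6)
})

test_that("identical pre/postoperative state is a lazy fixed point over 15 years", {
  mesh <- block_mesh(10, 10, 20, 5, rho = 0.5)
  base <- which(mesh$nodes[, 3] == 0)
  sys <- fe_setup(mesh, fixed_nodes = base)
  mm <- default_material_model()
  E <- element_moduli(mesh, mesh$density, mm)
  fe_assemble(sys, E)
  faces <- boundary_faces(mesh)
  top <- faces[faces$nz > 0.5 & faces$cz == 20, ]
  A <- tributary_areas(top, nrow(mesh$nodes))
  forces <- lapply(c(1, 1.5, 0.7), function(s) {
    f <- matrix(0, sys$ntot, 3); f[, 3] <- -A * s; f
  })
  u3 <- fe_solve(sys, forces)
  Sref <- averaged_sed(lapply(u3, function(u) element_sed(sys, u, E))) /
    mesh$density
  sim <- simulate_remodeling(sys, forces, mesh$density, Sref,
                             default_remodeling_params(),
                             mm, record_years = c(2, 5, 11.6, 15))
  expect_equal(sim$t_final, 450)
  expect_equal(max(abs(sim$rho_snapshots - mesh$density)), 0)
  # time bookkeeping: recorded steps sum to the final time
  expect_lt(sim$iterations, 5)
})

test_that("time bookkeeping is exact and snapshots land on the follow-up grid", {
  mesh <- block_mesh(10, 10, 20, 5, rho = 0.4)
  base <- which(mesh$nodes[, 3] == 0)
  sys <- fe_setup(mesh, fixed_nodes = base)
  mm <- default_material_model()
  E <- element_moduli(mesh, mesh$density, mm)
  fe_assemble(sys, E)
  faces <- boundary_faces(mesh)
  top <- faces[faces$nz > 0.5 & faces$cz == 20, ]
  A <- tributary_areas(top, nrow(mesh$nodes))
  forces <- lapply(c(1, 1.5, 0.7), function(s) {
    f <- matrix(0, sys$ntot, 3); f[, 3] <- -A * s; f
  })
  u3 <- fe_solve(sys, forces)
  # halved reference stimulus -> overload everywhere -> sustained formation
  Sref <- averaged_sed(lapply(u3, function(u) element_sed(sys, u, E))) /
    mesh$density / 2
  prm <- default_remodeling_params(dt_max = 5, years = 2)
  sim <- simulate_remodeling(sys, forces, mesh$density, Sref, prm, mm,
                             record_years = c(0.5, 1, 2))
  tr <- sim$trace
  expect_equal(sum(tr[, "dt"], na.rm = TRUE), sim$t_final, tolerance = 1e-9)
  expect_gte(sim$t_final, 2 * prm$ctu_per_year - 1e-9)
  # formation everywhere: densities non-decreasing across snapshots
  expect_true(all(diff(t(sim$rho_snapshots)) >= -1e-12))
  expect_true(all(sim$rho_snapshots[, 1] >= mesh$density - 1e-12))
})

test_that("stress shielding appears under the tray at the first iteration", {
  res <- fixture("shielding_fields", {
    cfg <- default_run_config(seed = 1)
    rec <- generate_cohort(cfg$cohort, 1)[14, ]   # a neutral knee
    pre <- build_preop_tibia(rec, cfg$geometry, 1)
    geom <- pre$geometry
    imp <- make_implant_spec(rec$tray_size, geom)
    post <- perform_virtual_tka(pre, imp)
    tab <- condyle_load_table()
    rows <- tab[tab$alignment == "neutral", ]
    base_pre <- which(pre$nodes[, 3] < min(pre$nodes[, 3]) + 12)
    ztop <- max(pre$nodes[, 3])
    cop_x <- 0.25 * imp$tray_ml_width
    springs <- lapply(list(c(cop_x, 0, ztop + 10), c(-cop_x, 0, ztop + 10)),
                      function(cp) build_cartilage_springs(pre, cp, 300))
    sys_pre <- fe_setup(pre, base_pre, springs)
    mats <- assign_materials(pre)
    fe_assemble(sys_pre, mats$E)
    fpre <- tkaremod:::preop_force_matrices(sys_pre, rows, rec$body_weight,
                                            default_run_config(1)$loads)
    Upre <- averaged_sed(lapply(fe_solve(sys_pre, fpre),
                                function(u) element_sed(sys_pre, u, mats$E)))
    base_post <- which(post$nodes[, 3] < min(post$nodes[, 3]) + 12)
    sys_post <- fe_setup(post, base_post)
    matsp <- assign_materials(post)
    fe_assemble(sys_post, matsp$E)
    fpost <- lapply(c("gait", "SD", "DKB"), function(act) {
      fs <- lapply(c("medial", "lateral"), function(cd) {
        r <- rows[rows$activity == act & rows$condyle == cd, ]
        scale_loads(c(r$f_med, r$f_ant, r$f_dist), rec$body_weight)
      })
      apply_insert_loads(post, list(c(cop_x, 0), c(-cop_x, 0)), fs, 12)
    })
    Upost <- averaged_sed(lapply(fe_solve(sys_post, fpost),
                                 function(u) element_sed(sys_post, u, matsp$E)))
    list(pre = pre, post = post, Upre = Upre, Upost = Upost)
  })
  corr <- res$post$correspondence
  cen <- tkaremod:::tet_centroids(res$post$nodes, res$post$tets)
  S <- res$Upost[corr$postop_elem] / res$post$density[corr$postop_elem]
  Sref <- res$Upre[corr$preop_elem] / res$pre$density[corr$preop_elem]
  prox <- cen[corr$postop_elem, 3] > -25 & !res$post$cortical[corr$postop_elem]
  # the median proximal cancellous element is unloaded below the lazy zone
  expect_lt(median(S[prox] / Sref[prox], na.rm = TRUE), 0.65)
  rate <- remodeling_rate(S[prox], Sref[prox],
                          free_surface(res$post$density[corr$postop_elem][prox]))
  expect_gt(mean(rate <= 0), 0.9)   # resorption or lazy almost everywhere
  expect_gt(mean(rate < 0), 0.7)
})
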