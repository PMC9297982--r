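# end-to-end pipeline wiring: cohort -> FE -> remodeling -> DEXA -> statistics

#' Default run configuration
#'
#' The "fine" profile uses the reference problem sizes (2 mm mesh edge,
#' 1 CTU maximum step, 0.2 mm projection voxels); the "coarse" profile is
#' the desk-scale configuration for cohort runs (8 mm mesh, 10 CTU cap,
#' 0.8 mm voxels) with otherwise identical physics.
#'
#' @param seed master seed governing all substreams
#' @param profile "coarse" or "fine"
#' @param n_knees cohort size
#' @param years simulated horizon, years
#' @return a `run_config` list
#' @export
default_run_config <- function(seed = 1, profile = c("coarse", "fine"),
                               n_knees = 26, years = 15) {
  profile <- match.arg(profile)
  mesh_edge <- if (profile == "coarse") 8 else 2
  dt_max <- if (profile == "coarse") 10 else 1
  voxel <- if (profile == "coarse") 0.8 else 0.2
  structure(list(
    seed = seed, profile = profile,
    cohort = default_cohort_config(n_knees),
    geometry = default_geometry(mesh_edge),
    material = default_material_model(),
    remodeling = default_remodeling_params(dt_max = dt_max, years = years),
    free_surface = default_free_surface(),
    loads = list(cop_frac = 0.25, cop_y = 0, cop_height = 10,
                 contact_area = 300, contact_radius = 12,
                 fallback_bw_kg = 59, postop_alignment = "neutral"),
    dexa_voxel = voxel,
    record_years = c(0.5, 1, 1.5, 2, 3, 4, 5, 11.6, 15),
    out_dir = NULL), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields in the YAML override the profile defaults; the file must
#' carry an explicit seed.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set an explicit seed")
  cfg <- default_run_config(seed = y$seed,
                            profile = y$profile %||% "coarse",
                            n_knees = y$n_knees %||% 26,
                            years = y$years %||% 15)
  for (nm in intersect(names(y), c("record_years", "dexa_voxel", "out_dir")))
    cfg[[nm]] <- y[[nm]]
  for (nm in intersect(names(y$geometry %||% list()), names(cfg$geometry)))
    cfg$geometry[[nm]] <- y$geometry[[nm]]
  for (nm in intersect(names(y$remodeling %||% list()), names(cfg$remodeling)))
    cfg$remodeling[[nm]] <- y$remodeling[[nm]]
  for (nm in intersect(names(y$loads %||% list()), names(cfg$loads)))
    cfg$loads[[nm]] <- y$loads[[nm]]
  cfg
}

# activity force matrices for one alignment row set, preop spring loading
preop_force_matrices <- function(sys, load_rows, bw, loads_cfg) {
  lapply(c("gait", "SD", "DKB"), function(act) {
    fm <- matrix(0, sys$ntot, 3)
    for (ci in 1:2) {
      condyle <- c("medial", "lateral")[ci]
      row <- load_rows[load_rows$activity == act & load_rows$condyle == condyle, ]
      f <- scale_loads(c(row$f_med, row$f_ant, row$f_dist), bw,
                       loads_cfg$fallback_bw_kg)
      fm[sys$anchor_ids[ci], ] <- f
    }
    fm
  })
}

#' Run the full pipeline for one subject
#'
#' Builds the preoperative tibia, performs the virtual TKA, solves the
#' preoperative reference stimulus under native-alignment spring loading,
#' simulates strain-adaptive remodeling under insert loading, and evaluates
#' the three periprosthetic ROIs on virtual DEXA projections over time.
#'
#' @param record one cohort row
#' @param config a `run_config`
#' @return list with `trajectory` (data.frame subject_id, roi, time_years,
#'   bmd), `implant`, diagnostic fields
#' @export
run_subject <- function(record, config) {
  geom <- config$geometry
  lcfg <- config$loads
  preop <- build_preop_tibia(record, geom, config$seed)
  geom <- preop$geometry            # subject-scaled
  implant <- make_implant_spec(record$tray_size, geom)
  postop <- perform_virtual_tka(preop, implant)
  tab <- condyle_load_table()
  grp <- record$alignment_group
  rows_native <- tab[tab$alignment == grp, ]
  rows_post <- if (identical(lcfg$postop_alignment, "neutral"))
    tab[tab$alignment == "neutral", ] else rows_native

  # --- preoperative reference stimulus (native alignment, spring loading)
  vv <- native_vv_convention(grp)
  th <- vv * pi / 180
  pre_rot <- preop
  pre_rot$grid <- NULL
  pre_rot$nodes <- cbind(
    x = preop$nodes[, 1] * cos(th) + preop$nodes[, 3] * sin(th),
    y = preop$nodes[, 2],
    z = -preop$nodes[, 1] * sin(th) + preop$nodes[, 3] * cos(th))
  zmin <- min(pre_rot$nodes[, 3])
  fixed_pre <- which(pre_rot$nodes[, 3] < zmin + 1.5 * geom$mesh_edge)
  ztop <- max(pre_rot$nodes[, 3])
  cop_x <- lcfg$cop_frac * implant$tray_ml_width
  cops <- list(c(cop_x, lcfg$cop_y, ztop + lcfg$cop_height),
               c(-cop_x, lcfg$cop_y, ztop + lcfg$cop_height))
  springs <- lapply(cops, function(cp)
    build_cartilage_springs(pre_rot, cp, lcfg$contact_area))
  sys_pre <- fe_setup(pre_rot, fixed_pre, springs)
  mats_pre <- assign_materials(preop, matmodel = config$material)
  fe_assemble(sys_pre, mats_pre$E)
  f_pre <- preop_force_matrices(sys_pre, rows_native, record$body_weight, lcfg)
  u_pre <- fe_solve(sys_pre, f_pre)
  U_pre <- averaged_sed(lapply(u_pre, function(u)
    element_sed(sys_pre, u, mats_pre$E)))
  S_pre <- U_pre / preop$density

  corr <- postop$correspondence
  Sref <- rep(NA_real_, nrow(postop$tets))
  Sref[corr$postop_elem] <- S_pre[corr$preop_elem]

  # --- postoperative loading on the insert contact patches
  zmin_post <- min(postop$nodes[, 3])
  fixed_post <- which(postop$nodes[, 3] < zmin_post + 1.5 * geom$mesh_edge)
  sys_post <- fe_setup(postop, fixed_post)
  forces_post <- lapply(c("gait", "SD", "DKB"), function(act) {
    fs <- lapply(c("medial", "lateral"), function(condyle) {
      row <- rows_post[rows_post$activity == act & rows_post$condyle == condyle, ]
      scale_loads(c(row$f_med, row$f_ant, row$f_dist), record$body_weight,
                  lcfg$fallback_bw_kg)
    })
    apply_insert_loads(postop, list(c(cop_x, lcfg$cop_y), c(-cop_x, lcfg$cop_y)),
                       fs, lcfg$contact_radius)
  })

  sim <- simulate_remodeling(sys_post, forces_post, postop$density, Sref,
                             config$remodeling, config$material,
                             config$free_surface, config$record_years)

  # --- virtual DEXA over time
  rois <- place_rois(implant, geom)
  vox_pre <- voxelize(preop, config$dexa_voxel)
  proj_pre <- projection_operator(vox_pre, nrow(preop$tets))
  img0 <- project_ap(proj_pre, preop$density)
  bmd0 <- vapply(rois, function(r) roi_bmd(img0, r), 0)

  vox_post <- voxelize(postop, config$dexa_voxel)
  proj_post <- projection_operator(vox_post, nrow(postop$tets))
  qs <- roi_operators(proj_post, rois)
  times <- c(0, sim$times_ctu / config$remodeling$ctu_per_year)
  rho_snap <- sim$rho_snapshots
  rho_snap[is.na(rho_snap)] <- 0
  snap_bmd <- matrix(0, length(sim$times_ctu), length(qs))
  for (r in seq_along(qs))
    snap_bmd[, r] <- as.numeric(crossprod(rho_snap, qs[[r]]))

  traj <- do.call(rbind, lapply(seq_along(rois), function(r) data.frame(
    subject_id = record$subject_id,
    roi = names(rois)[r],
    time_years = times,
    bmd = c(bmd0[r], if (length(sim$times_ctu)) snap_bmd[, r] else numeric(0)))))

  list(trajectory = traj, implant = implant, sim = sim,
       baseline = bmd0, coverage = implant$coverage)
}

#' Run the full cohort pipeline
#'
#' Generates the cohort, runs every subject (failures isolate the subject
#' and are reported at the end), and aggregates outcomes, subgroup
#' summaries, correlation tables and comparisons against the published
#' clinical reference.  When `config$out_dir` is set, tidy CSV outputs and a
#' JSON manifest are written there.
#'
#' @param config a `run_config`
#' @param progress print per-subject progress
#' @return list(cohort, trajectories, outcomes, comparison, correlations,
#'   subgroups_alignment, subgroups_sex, failures, manifest)
#' @export
run_pipeline <- function(config = default_run_config(), progress = FALSE) {
  cohort <- generate_cohort(config$cohort, config$seed)
  trajs <- list(); failures <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    res <- tryCatch(run_subject(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rec$subject_id]] <- conditionMessage(res)
      if (progress) message(rec$subject_id, " FAILED: ", conditionMessage(res))
      next
    }
    trajs[[rec$subject_id]] <- res$trajectory
    if (progress)
      message(sprintf("%s (%s): baseline %s, %d iterations", rec$subject_id,
                      rec$alignment_group,
                      paste(sprintf("%.3f", res$baseline), collapse = "/"),
                      res$sim$iterations))
  }
  if (!length(trajs)) stop("no subject completed")
  trajectories <- do.call(rbind, trajs)
  rownames(trajectories) <- NULL
  outcomes <- compute_outcomes(trajectories)
  result <- list(
    cohort = cohort,
    trajectories = trajectories,
    outcomes = outcomes,
    comparison = compare_to_reference(outcomes),
    correlations = correlation_table(cohort, outcomes,
                                     followup_years = max(config$record_years)),
    subgroups_alignment = subgroup_summary(outcomes, cohort, "alignment_group"),
    subgroups_sex = subgroup_summary(outcomes, cohort, "sex"),
    failures = failures,
    manifest = list(seed = config$seed, profile = config$profile,
                    n_knees = config$cohort$n_knees,
                    mesh_edge = config$geometry$mesh_edge,
                    dt_max = config$remodeling$dt_max,
                    dexa_voxel = config$dexa_voxel,
                    years = config$remodeling$years,
                    record_years = config$record_years,
                    package_version = as.character(utils::packageVersion("tkaremod")),
                    timestamp = format(Sys.time(), tz = "UTC")))
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

#' Write pipeline results as tidy CSVs plus a JSON manifest
#'
#' @param result list from [run_pipeline()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(result$trajectories, file.path(out_dir, "roi_bmd.csv"),
                   row.names = FALSE)
  utils::write.csv(result$outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(result$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(result$subgroups_alignment$summary,
                   file.path(out_dir, "subgroups_alignment.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
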