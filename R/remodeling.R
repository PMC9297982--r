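# strain-adaptive remodeling: lazy zone, free-surface rate, adaptive CTU steps

#' Default remodeling parameters
#'
#' Lazy zone half-width 0.35 (no net remodeling while the postoperative
#' stimulus is within 35\% of the preoperative reference), 30 computer time
#' units (CTU) per postoperative year, 15-year horizon.  The time step is an
#' adaptive forward Euler: dt = min(dt_max, drho_cap / max |drho/dt|).
#'
#' @param lazy_zone dimensionless half-width s of the dead band
#' @param ctu_per_year CTU per postoperative year
#' @param years simulated horizon, years
#' @param drho_cap maximum density change per iteration, g/cm^3
#' @param dt_max maximum step, CTU (1 for reference runs; larger values are
#'   a coarse-profile choice for cohort-scale runs)
#' @param rho_min,rho_max admissible density bounds, g/cm^3
#' @param sref_floor minimum reference stimulus; elements with smaller
#'   preoperative stimulus are treated as lazy (guards division blow-ups)
#' @return a `remodeling_params` list
#' @export
default_remodeling_params <- function(lazy_zone = 0.35, ctu_per_year = 30,
                                      years = 15, drho_cap = 0.05,
                                      dt_max = 1, rho_min = 0.01,
                                      rho_max = 1.73, sref_floor = 1e-9) {
  stopifnot(lazy_zone > 0, lazy_zone < 1, ctu_per_year > 0, rho_min < rho_max)
  structure(list(lazy_zone = lazy_zone, ctu_per_year = ctu_per_year,
                 years = years, drho_cap = drho_cap, dt_max = dt_max,
                 rho_min = rho_min, rho_max = rho_max,
                 sref_floor = sref_floor), class = "remodeling_params")
}

#' Default free-surface (specific surface) model
#'
#' Quintic polynomial mapping porosity p = 1 - rho/rho_cort to available
#' specific surface a (mm^2/mm^3): a(p) = 32.3p - 93.9p^2 + 134p^3 - 101p^4
#' + 28.8p^5.  Fully dense bone (p = 0) and pure void (p = 1) expose
#' vanishing internal surface; the maximum lies at intermediate porosity.
#'
#' @param coefficients polynomial coefficients of p, p^2, ... (no constant)
#' @param rho_cort fully dense reference density, g/cm^3
#' @return a `free_surface_model`
#' @export
default_free_surface <- function(coefficients = c(32.3, -93.9, 134, -101, 28.8),
                                 rho_cort = 1.73) {
  structure(list(coefficients = coefficients, rho_cort = rho_cort),
            class = "free_surface_model")
}

#' Available free bone surface as a function of density
#'
#' @param rho apparent densities, g/cm^3 (clamped to [0, rho_cort])
#' @param model a `free_surface_model`
#' @return specific surface a >= 0, mm^2/mm^3
#' @export
free_surface <- function(rho, model = default_free_surface()) {
  p <- clamp(1 - rho / model$rho_cort, 0, 1)
  a <- 0
  for (k in seq_along(model$coefficients))
    a <- a + model$coefficients[k] * p^k
  pmax(a, 0)
}

#' Strain-adaptive remodeling rate
#'
#' Zero inside the lazy zone |S/Sref - 1| < s; outside, the rate is the
#' free-surface-scaled overshoot beyond the zone boundary:
#' a (S - (1+s) Sref) above, a (S - (1-s) Sref) below.  Continuous (rate ->
#' 0) at both boundaries.  Elements whose reference stimulus falls below
#' `sref_floor` are treated as lazy.
#'
#' @param S postoperative SED per unit bone mass (vectorised)
#' @param Sref preoperative reference stimulus
#' @param a free surface density from [free_surface()]
#' @param s lazy-zone half-width
#' @param sref_floor minimum meaningful reference stimulus
#' @return drho/dt in g/cm^3 per CTU
#' @export
remodeling_rate <- function(S, Sref, a, s = 0.35, sref_floor = 1e-9) {
  if (any(S < 0, na.rm = TRUE) || any(Sref < 0, na.rm = TRUE) ||
      any(a < 0, na.rm = TRUE))
    stop("S, Sref and a must be non-negative")
  ok <- Sref >= sref_floor
  ratio <- ifelse(ok, S / pmax(Sref, sref_floor), 1)
  up <- ok & ratio - 1 >= s
  dn <- ok & ratio - 1 <= -s
  rate <- numeric(length(S))
  rate[up] <- a[up] * (S[up] - (1 + s) * Sref[up])
  rate[dn] <- a[dn] * (S[dn] - (1 - s) * Sref[dn])
  rate
}

#' Advance a remodeling state by one adaptive Euler step
#'
#' dt = min(dt_max, drho_cap / max |rate|); densities are clamped to
#' [rho_min, rho_max].  With all rates zero the state coasts by dt_max.
#'
#' @param rho current densities
#' @param rate drho/dt per element
#' @param params a `remodeling_params`
#' @return list(rho, dt)
#' @export
advance_state <- function(rho, rate, params) {
  mx <- max(abs(rate))
  dt <- if (mx > 0) min(params$dt_max, params$drho_cap / mx) else params$dt_max
  list(rho = clamp(rho + dt * rate, params$rho_min, params$rho_max), dt = dt)
}

#' Simulate strain-adaptive remodeling of a postoperative tibia
#'
#' Iterates: refresh bone moduli from current densities, re-solve the three
#' activity load cases, average SED, form the stimulus S = U/rho, apply the
#' lazy-zone rate against the precomputed preoperative reference Sref, and
#' advance time adaptively until the horizon.  Snapshots at the requested
#' follow-up times are linearly interpolated in t between iterations.  Once
#' every element is inside the lazy zone the field is a fixed point and the
#' remaining horizon is fast-forwarded exactly.
#'
#' @param sys postop `fe_system` from [fe_setup()]
#' @param forces list of three nodal force matrices (gait, SD, DKB)
#' @param rho0 initial bone densities (NA on non-bone elements)
#' @param Sref preoperative reference stimulus per element (NA non-bone)
#' @param params a `remodeling_params`
#' @param matmodel a `material_model`
#' @param fsmodel a `free_surface_model`
#' @param record_years follow-up times to snapshot, years
#' @return list: `times_ctu`, `rho_snapshots` (elements x times), `t_final`,
#'   `iterations`, `trace` (per-iteration t, dt, max rate, active fraction)
#' @export
simulate_remodeling <- function(sys, forces, rho0, Sref,
                                params = default_remodeling_params(),
                                matmodel = default_material_model(),
                                fsmodel = default_free_surface(),
                                record_years = c(0.5, 1, 1.5, 2, 3, 4, 5, 11.6, 15)) {
  model <- sys$model
  is_bone <- model$part == "bone"
  rho <- rho0
  horizon <- params$years * params$ctu_per_year
  rec_t <- record_years * params$ctu_per_year
  rec_t <- rec_t[rec_t <= horizon + 1e-9]
  snaps <- matrix(NA_real_, length(rho0), length(rec_t))
  rec_done <- rep(FALSE, length(rec_t))
  if (params$years == 0 || !length(rec_t)) {
    return(list(times_ctu = rec_t, rho_snapshots = snaps, t_final = 0,
                iterations = 0L, trace = NULL))
  }

  # shell elements keep the specific surface of fully dense cortex: thinning
  # reduces their areal-equivalent density, not their porosity
  a_fixed <- rep(NA_real_, length(rho0))
  if (!is.null(model$cortical)) {
    rc <- model$geometry$rho_cort %||% fsmodel$rho_cort
    a_fixed[is_bone & model$cortical] <- free_surface(rc, fsmodel)
  }

  t <- 0; it <- 0L
  trace <- list()
  rho_prev <- rho; t_prev <- 0
  repeat {
    it <- it + 1L
    E <- element_moduli(model, rho, matmodel)
    fe_assemble(sys, E)
    u3 <- fe_solve(sys, forces)
    U <- averaged_sed(lapply(u3, function(u) element_sed(sys, u, E)))
    S <- U / rho
    a_el <- free_surface(rho, fsmodel)
    a_el[!is.na(a_fixed)] <- a_fixed[!is.na(a_fixed)]
    rate <- numeric(length(rho))
    rate[is_bone] <- remodeling_rate(S[is_bone], Sref[is_bone], a_el[is_bone],
                                     params$lazy_zone, params$sref_floor)
    # zero rate at an active bound
    rate[is_bone & rho >= params$rho_max & rate > 0] <- 0
    rate[is_bone & rho <= params$rho_min & rate < 0] <- 0

    if (all(rate[is_bone] == 0)) {
      # lazy fixed point: densities constant for all later iterations
      for (r in which(!rec_done)) snaps[, r] <- rho
      trace[[it]] <- c(t = t, dt = NA, max_rate = 0, active = 0)
      t <- horizon
      break
    }

    st <- advance_state(rho, rate, params)
    rho_prev <- rho; t_prev <- t
    rho <- st$rho; t <- t + st$dt
    trace[[it]] <- c(t = t, dt = st$dt, max_rate = max(abs(rate)),
                     active = mean(rate[is_bone] != 0))

    cross <- which(!rec_done & rec_t <= t + 1e-12)
    for (r in cross) {
      w <- (rec_t[r] - t_prev) / (t - t_prev)
      snaps[, r] <- rho_prev + w * (rho - rho_prev)
      rec_done[r] <- TRUE
    }
    if (t >= horizon - 1e-9) {
      for (r in which(!rec_done)) snaps[, r] <- rho
      break
    }
  }
  list(times_ctu = rec_t, rho_snapshots = snaps, t_final = t,
       iterations = it,
       trace = do.call(rbind, trace))
}
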