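# density-modulus laws and CT calibration

#' Default material model
#'
#' Power-law modulus-density relations for cancellous and cortical bone with
#' a density threshold between the regimes, plus fixed elastic moduli for the
#' CoCr tray (210 GPa), PE insert (588 MPa) and bone cement (2551 MPa).
#' The bone-law constants are configurable published defaults
#' (cancellous E = 6850 rho^1.49 MPa, cortical E = 10200 rho^2.01 MPa,
#' rho in g/cm^3 apparent).
#'
#' @param cancellous_law c(coefficient, exponent) for E = c * rho^e, MPa
#' @param cortical_law c(coefficient, exponent)
#' @param cortical_threshold density at the regime switch, g/cm^3
#' @param rho_min,rho_max admissible apparent-density bounds, g/cm^3
#' @return a `material_model` list
#' @export
default_material_model <- function(cancellous_law = c(6850, 1.49),
                                   cortical_law = c(10200, 2.01),
                                   cortical_threshold = 1.2,
                                   rho_min = 0.01, rho_max = 1.73) {
  stopifnot(rho_min > 0, rho_min < rho_max, all(cancellous_law > 0),
            all(cortical_law > 0))
  structure(list(
    cancellous_law = cancellous_law, cortical_law = cortical_law,
    cortical_threshold = cortical_threshold,
    E_tray = 210000, E_insert = 588, E_cement = 2551,
    poisson = c(bone = 0.3, cement = 0.3, tray = 0.3, insert = 0.3),
    rho_min = rho_min, rho_max = rho_max), class = "material_model")
}

#' Elastic modulus from apparent density
#'
#' Applies the cancellous power law below the cortical threshold and the
#' cortical law at or above it; densities outside the admissible range are
#' clamped with a warning (remodeling may drive elements to the bounds).
#'
#' @param rho apparent densities, g/cm^3 (vectorised)
#' @param model a `material_model`
#' @return elastic moduli, MPa
#' @export
density_to_modulus <- function(rho, model = default_material_model()) {
  if (any(rho < model$rho_min - 1e-12 | rho > model$rho_max + 1e-12, na.rm = TRUE))
    warning("densities outside [rho_min, rho_max] clamped")
  rho <- clamp(rho, model$rho_min, model$rho_max)
  ifelse(rho >= model$cortical_threshold,
         model$cortical_law[1] * rho^model$cortical_law[2],
         model$cancellous_law[1] * rho^model$cancellous_law[2])
}

#' Calibrate a linear HU-to-density map from extra-skeletal tissue peaks
#'
#' Finds air, fat and muscle intensity peaks in a smoothed histogram of the
#' volume (local maxima inside nominal HU windows) and fits the scan-specific
#' linear function rho = slope * HU + intercept by least squares through the
#' (peak HU, reference density) pairs.  When no fat peak is detectable (as
#' happens under heavy speckle) the fit falls back to the exact two-point
#' line through air and muscle, with a warning.
#'
#' @param volume a `synthetic_ct` (see [synthesize_ct()]) or a numeric HU array
#' @param tissue_refs named reference densities, g/cm^3 equivalent
#' @param mode "three_point" or "two_point"
#' @param windows named list of HU search windows per tissue
#' @param bin_width histogram bin width, HU
#' @return a `hu_calibration` list with slope, intercept, mode and the
#'   detected reference points
#' @export
calibrate_hu_to_bmd <- function(volume,
                                tissue_refs = c(air = 0, fat = 0.95, muscle = 1.05),
                                mode = c("three_point", "two_point"),
                                windows = list(air = c(-1100, -900),
                                               fat = c(-250, -15),
                                               muscle = c(5, 200)),
                                bin_width = 5) {
  mode <- match.arg(mode)
  hu <- if (is.list(volume)) volume$hu else volume
  hu <- as.numeric(hu)
  hu <- hu[hu < max(vapply(windows, max, 0)) + 100]
  lo <- floor(min(hu) / bin_width) * bin_width
  hi <- ceiling(max(hu) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  h <- graphics::hist(hu, breaks = breaks, plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 5, 5), sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  mids <- h$mids

  find_peak <- function(win) {
    sel <- which(mids >= win[1] & mids <= win[2])
    if (length(sel) < 3) return(NA_real_)
    c0 <- cnt[sel]
    locmax <- sel[which(c0 >= c(c0[-1], -Inf) & c0 >= c(-Inf, c0[-length(c0)]) &
                        c0 > 0.005 * max(cnt))]
    if (!length(locmax)) return(NA_real_)
    best <- locmax[cnt[locmax] > max(cnt[locmax]) - 1e-9]
    peak_mid <- mids[best[ceiling(length(best) / 2)]]   # plateau center
    # sub-bin refinement: centroid of raw intensities near the peak bin
    nb <- hu[abs(hu - peak_mid) <= 3 * bin_width]
    if (length(nb)) mean(nb) else peak_mid
  }

  peaks <- c(air = find_peak(windows$air), fat = find_peak(windows$fat),
             muscle = find_peak(windows$muscle))
  if (is.na(peaks["air"]) || is.na(peaks["muscle"]))
    stop("calibration failed: air or muscle peak not detectable")
  if (mode == "three_point" && is.na(peaks["fat"])) {
    warning("fat peak not detectable; falling back to two-point air/muscle calibration")
    mode <- "two_point"
  }
  tissues <- if (mode == "three_point") c("air", "fat", "muscle") else c("air", "muscle")
  x <- peaks[tissues]; y <- tissue_refs[tissues]
  if (mode == "two_point") {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    intercept <- y[1] - slope * x[1]
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 mode = mode,
                 reference_points = data.frame(tissue = tissues,
                                               hu_peak = unname(x),
                                               rho_ref = unname(y))),
            class = "hu_calibration")
}

#' Two-point HU calibration through explicit reference pairs
#'
#' @param hu1,rho1,hu2,rho2 the two (HU, density) reference pairs
#' @return a `hu_calibration`
#' @export
two_point_calibration <- function(hu1, rho1, hu2, rho2) {
  slope <- (rho2 - rho1) / (hu2 - hu1)
  structure(list(slope = slope, intercept = rho1 - slope * hu1,
                 mode = "two_point",
                 reference_points = data.frame(tissue = c("p1", "p2"),
                                               hu_peak = c(hu1, hu2),
                                               rho_ref = c(rho1, rho2))),
            class = "hu_calibration")
}

#' Per-element elastic moduli for a model state
#'
#' Cancellous bone follows the configured power law.  Cortical-shell
#' elements (flagged at mesh build time) follow a linear equivalent-
#' stiffness law E = (E_cort(rho_cort)/rho_cort) * rho: the shell is one
#' element-layer thick and carries the membrane stiffness of a thinner,
#' fully dense cortex, so its modulus scales with its areal-equivalent
#' density rather than with a porosity power law.  Non-bone parts get their
#' fixed moduli.
#'
#' @param model a `tibia_model`
#' @param rho per-element densities (NA on non-bone elements)
#' @param matmodel a `material_model`
#' @return per-element moduli, MPa
#' @export
element_moduli <- function(model, rho, matmodel = default_material_model()) {
  E <- numeric(length(rho))
  is_bone <- model$part == "bone"
  E[is_bone] <- density_to_modulus(rho[is_bone], matmodel)
  if (!is.null(model$cortical)) {
    rc <- model$geometry$rho_cort %||% matmodel$rho_max
    sh <- is_bone & model$cortical
    E[sh] <- density_to_modulus(rc, matmodel) / rc * pmax(rho[sh], matmodel$rho_min)
  }
  E[model$part == "cement"] <- matmodel$E_cement
  E[model$part == "tray"] <- matmodel$E_tray
  E[model$part == "insert"] <- matmodel$E_insert
  E
}

#' Assign per-element density and modulus
#'
#' Bone elements get density either from the model's own density field or by
#' sampling a calibrated HU volume at element centroids (nearest voxel, with
#' optional trilinear interpolation); non-bone parts receive their fixed
#' moduli regardless of the image.
#'
#' @param model a `tibia_model`
#' @param ct optional `synthetic_ct` volume
#' @param calib optional `hu_calibration` (required with `ct`)
#' @param matmodel a `material_model`
#' @param sampling "nearest" or "trilinear" voxel sampling
#' @return data.frame(element, part, rho, E) plus attribute `n_outside`,
#'   the count of centroids needing the nearest-voxel fallback
#' @export
assign_materials <- function(model, ct = NULL, calib = NULL,
                             matmodel = default_material_model(),
                             sampling = c("nearest", "trilinear")) {
  sampling <- match.arg(sampling)
  m <- nrow(model$tets)
  part <- model$part
  rho <- rep(NA_real_, m)
  is_bone <- part == "bone"
  n_outside <- 0L
  if (!is.null(ct)) {
    stopifnot(!is.null(calib))
    cen <- tet_centroids(model$nodes, model$tets)[is_bone, , drop = FALSE]
    s <- sample_volume(ct, cen, sampling)
    n_outside <- attr(s, "n_outside")
    rho[is_bone] <- clamp(calib$slope * s + calib$intercept,
                          matmodel$rho_min, matmodel$rho_max)
  } else {
    if (is.null(model$density)) stop("model carries no density field and no CT given")
    rho[is_bone] <- model$density[is_bone]
  }
  E <- element_moduli(model, rho, matmodel)
  out <- data.frame(element = seq_len(m), part = part, rho = rho, E = E)
  attr(out, "n_outside") <- n_outside
  out
}

# sample a voxel volume at points (mm); nearest or trilinear
sample_volume <- function(ct, pts, sampling = "nearest") {
  sp <- ct$spacing; org <- ct$origin
  dims <- dim(ct$hu)
  gx <- (pts[, 1] - org[1]) / sp + 1
  gy <- (pts[, 2] - org[2]) / sp + 1
  gz <- (pts[, 3] - org[3]) / sp + 1
  outside <- gx < 1 | gy < 1 | gz < 1 | gx > dims[1] | gy > dims[2] | gz > dims[3]
  if (sampling == "nearest") {
    i <- clamp(round(gx), 1, dims[1]); j <- clamp(round(gy), 1, dims[2])
    k <- clamp(round(gz), 1, dims[3])
    val <- ct$hu[cbind(i, j, k)]
  } else {
    x0 <- clamp(floor(gx), 1, dims[1] - 1); y0 <- clamp(floor(gy), 1, dims[2] - 1)
    z0 <- clamp(floor(gz), 1, dims[3] - 1)
    fx <- clamp(gx - x0, 0, 1); fy <- clamp(gy - y0, 0, 1); fz <- clamp(gz - z0, 0, 1)
    g <- function(dx, dy, dz) ct$hu[cbind(x0 + dx, y0 + dy, z0 + dz)]
    val <- (1 - fx) * (1 - fy) * (1 - fz) * g(0, 0, 0) +
           fx * (1 - fy) * (1 - fz) * g(1, 0, 0) +
           (1 - fx) * fy * (1 - fz) * g(0, 1, 0) +
           (1 - fx) * (1 - fy) * fz * g(0, 0, 1) +
           fx * fy * (1 - fz) * g(1, 1, 0) +
           fx * (1 - fy) * fz * g(1, 0, 1) +
           (1 - fx) * fy * fz * g(0, 1, 1) +
           fx * fy * fz * g(1, 1, 1)
  }
  structure(val, n_outside = sum(outside))
}
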