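# synthetic CT volumes with a known HU-density map

#' Synthesize a CT-like volume from a tibia model
#'
#' Voxelizes the bone and fills voxels with Hounsfield units from the inverse
#' of a known ground-truth linear map, HU = (rho - intercept) / slope.  Two
#' elliptical extra-skeletal shells emulate fat and muscle at their
#' density-equivalent HU so histogram calibration is exercisable; everything
#' else is air.  Optional additive speckle noise.
#'
#' @param model a `tibia_model` with a density field
#' @param true_slope,true_intercept ground-truth map rho = slope*HU + intercept
#' @param spacing voxel edge, mm
#' @param noise_level speckle amplitude (HU standard deviation)
#' @param seed master seed (ct-noise substream)
#' @param fat_shell,muscle_shell relative-radius bands (squared-radius scale
#'   factors of the bone cross-section) for the two halo tissues; set
#'   `fat_shell = NULL` to omit fat (forces two-point calibration downstream)
#' @param tissue_rho densities painted in the halos, g/cm^3 equivalent
#' @return a `synthetic_ct`: `hu` array, `spacing`, `origin`, the true map
#'   and the voxel-wise true density array `rho_true`
#' @export
synthesize_ct <- function(model, true_slope = 0.001, true_intercept = 1.0,
                          spacing = 1.5, noise_level = 0, seed = 1,
                          fat_shell = c(1.0, 1.6), muscle_shell = c(1.6, 3.0),
                          tissue_rho = c(fat = 0.95, muscle = 1.05)) {
  stopifnot(spacing > 0, true_slope > 0)
  geom <- model$geometry
  vox <- voxelize(model, voxel_edge = spacing, parts = "bone")
  dims <- dim(vox$elem)
  # extend the grid laterally so the halo shells fit
  pad <- ceiling(geom$plateau_a * 0.9 / spacing)
  nd <- dims + c(2 * pad, 2 * pad, 0)
  origin <- vox$origin - c(pad, pad, 0) * spacing
  rho <- array(0, nd)
  inner <- vox$elem > 0L
  dens <- model$density[vox$elem[inner]]
  sl <- array(FALSE, nd)
  sl[pad + seq_len(dims[1]), pad + seq_len(dims[2]), ] <- inner
  rho[sl] <- dens

  cx <- origin[1] + (seq_len(nd[1]) - 1) * spacing
  cy <- origin[2] + (seq_len(nd[2]) - 1) * spacing
  cz <- origin[3] + (seq_len(nd[3]) - 1) * spacing
  xs <- array(rep(cx, times = nd[2] * nd[3]), nd)
  ys <- array(rep(rep(cy, each = nd[1]), times = nd[3]), nd)
  zs <- array(rep(cz, each = nd[1] * nd[2]), nd)
  srel <- tibia_srel(xs, ys, pmin(zs, 0), geom)
  empty <- rho == 0
  if (!is.null(fat_shell)) {
    fat <- empty & srel > fat_shell[1] & srel <= fat_shell[2]
    rho[fat] <- tissue_rho[["fat"]]
  }
  mus <- empty & srel > muscle_shell[1] & srel <= muscle_shell[2] &
    !(if (is.null(fat_shell)) FALSE else srel <= fat_shell[2])
  rho[mus] <- tissue_rho[["muscle"]]

  hu <- (rho - true_intercept) / true_slope  # air (rho 0) maps consistently
  if (noise_level > 0) {
    set.seed(substream_seed(seed, "ct-noise"))
    hu <- hu + rnorm(length(hu), 0, noise_level)
  }
  structure(list(hu = hu, spacing = spacing, origin = origin,
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise_level = noise_level, rho_true = rho),
            class = "synthetic_ct")
}

#' Write a synthetic CT as NIfTI-1
#'
#' @param ct a `synthetic_ct`
#' @param path output .nii / .nii.gz path
#' @return `path`, invisibly
#' @export
write_ct_nifti <- function(ct, path) {
  img <- RNifti::asNifti(ct$hu, pixdim = rep(ct$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
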