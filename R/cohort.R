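#' Classify knee alignment from HKA and VV angles
#'
#' A knee is varus when the hip-knee-ankle (HKA) angle is at least 3 degrees
#' (positive angles point toward varus).  Non-varus knees are valgus when the
#' tibial varus-valgus (VV) joint-line angle is strictly negative, and neutral
#' otherwise.
#'
#' @param hka HKA angle in degrees (positive = varus); vectorised
#' @param vv tibial VV angle in degrees (positive = varus); vectorised
#' @return character vector in \code{c("varus", "neutral", "valgus")}
#' @examples
#' classify_alignment(3, 8)    # "varus"
#' classify_alignment(0, -2.4) # "valgus"
#' classify_alignment(0, 0)    # "neutral"
#' @export
classify_alignment <- function(hka, vv) {
  if (!all(is.finite(hka)) || !all(is.finite(vv)))
    stop("alignment angles must be finite")
  ifelse(hka >= 3, "varus", ifelse(vv < 0, "valgus", "neutral"))
}

#' Preoperative VV rotation convention for a native alignment group
#'
#' Preoperative models are rotated to the native joint-line orientation:
#' varus knees adopt a 5 degree VV angle (3 degree constitutional HKA plus a
#' 2 degree anatomical joint-line offset), valgus knees -3 degrees, neutral 0.
#'
#' @param group alignment group string(s)
#' @return VV angle(s) in degrees used for the preoperative solve
#' @export
native_vv_convention <- function(group) {
  unname(c(varus = 5, neutral = 0, valgus = -3)[group])
}

#' Default cohort configuration
#'
#' Marginals follow the modelled TKA population: 26 knees (7 male / 19
#' female), 13 varus (5/8 by sex), 12 neutral (2/10), 1 valgus (0/1), age
#' centred at 69 (60-76), body weight 56 kg (48-70) with a 4/26 missing
#' fraction, height 155 cm (140-165), tray sizes 1.5-4 with median 2.5.
#'
#' @param n_knees total number of knees
#' @return a list of sampling parameters consumed by [generate_cohort()]
#' @export
default_cohort_config <- function(n_knees = 26) {
  scale <- n_knees / 26
  list(
    n_knees = n_knees,
    # alignment x sex counts (male, female); scaled and re-balanced for n != 26
    counts = list(varus = c(m = 5, f = 8), neutral = c(m = 2, f = 10),
                  valgus = c(m = 0, f = 1)),
    age_mean = 69, age_sd = 5.6, age_range = c(60, 76),
    weight_mean = 56, weight_sd = 5.8, weight_range = c(48, 70),
    height_mean = 155, height_sd = 7.0, height_range = c(140, 165),
    sex_height_shift = 8,  # cm added for male subjects
    sex_weight_shift = 6,  # kg added for male subjects
    missing_bw_fraction = 4 / 26,
    tray_sizes = c(1.5, 2, 2.5, 3, 4),
    tray_size_counts = round(c(2, 2, 9, 8, 5) * scale),
    # angle windows per group, sampled uniformly then validated
    hka_window = list(varus = c(3, 5.4), neutral = c(-3, 2.9),
                      valgus = c(-5.7, 2.9)),
    vv_window = list(varus = c(2, 8), neutral = c(0, 5),
                     valgus = c(-2.4, -0.1)),
    # subject-level variability: a density scale (weak positive coupling to
    # age and BMI) and a skeletal size scale (coupled to height); areal BMD
    # varies with both, the remodeling stimulus ratio mostly with the first
    density_factor_sd = 0.14,
    density_age_coef = 0.05,
    density_bmi_coef = 0.05,
    size_factor_sd = 0.05,
    size_height_coef = 0.06
  )
}

#' Generate a synthetic TKA cohort
#'
#' Draws subject records with exact alignment-by-sex marginal counts and
#' seeded continuous covariates.  Body weight is missing for a configurable
#' fraction of female subjects (forces for those knees later fall back to the
#' 59 kg average female body weight).
#'
#' @param config list from [default_cohort_config()]
#' @param seed integer master seed; the cohort substream is derived from it
#' @return a data.frame of subject records, one row per knee
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1) {
  n <- config$n_knees
  if (n == 0) return(empty_cohort())
  counts <- config$counts
  n_by_group <- vapply(counts, sum, 0)
  if (sum(n_by_group) != n)
    stop("infeasible marginals: alignment/sex counts must sum to n_knees")
  set.seed(substream_seed(seed, "cohort"))

  group <- rep(names(counts), times = n_by_group)
  sex <- unlist(lapply(counts, function(cc) rep(c("male", "female"), cc)),
                use.names = FALSE)

  hka <- vv <- numeric(n)
  for (g in names(counts)) {
    idx <- which(group == g)
    hka[idx] <- runif(length(idx), config$hka_window[[g]][1], config$hka_window[[g]][2])
    vv[idx] <- runif(length(idx), config$vv_window[[g]][1], config$vv_window[[g]][2])
  }
  if (!all(classify_alignment(hka, vv) == group))
    stop("internal: sampled angles violate the alignment windows")

  rtrunc <- function(n, mean, sd, rng) {
    x <- rnorm(n, mean, sd)
    clamp(x, rng[1], rng[2])
  }
  male <- sex == "male"
  age <- round(rtrunc(n, config$age_mean, config$age_sd, config$age_range))
  height <- round(rtrunc(n, config$height_mean + ifelse(male, config$sex_height_shift, -2),
                         config$height_sd, config$height_range), 1)
  weight <- round(rtrunc(n, config$weight_mean + ifelse(male, config$sex_weight_shift, -1),
                         config$weight_sd, config$weight_range), 1)

  n_missing <- round(config$missing_bw_fraction * n)
  fem_idx <- which(!male)
  miss <- if (n_missing > 0 && length(fem_idx) > 0)
    sample(fem_idx, min(n_missing, length(fem_idx))) else integer(0)
  weight[miss] <- NA_real_

  bmi <- round(weight / (height / 100)^2, 1)

  sizes <- config$tray_sizes
  cnt <- config$tray_size_counts
  pool <- rep(sizes, cnt)
  pool <- if (length(pool) >= n) pool[seq_len(n)] else
    c(pool, sample(sizes, n - length(pool), replace = TRUE))
  tray_size <- sample(pool)

  side <- sample(c("left", "right"), n, replace = TRUE)

  # latent density factor: multiplicative scale on the cancellous field,
  # weakly and positively tied to age and BMI
  zage <- as.numeric(scale(age))
  zbmi <- as.numeric(scale(ifelse(is.na(bmi), mean(bmi, na.rm = TRUE), bmi)))
  if (any(!is.finite(zage))) zage <- rep(0, n)
  if (any(!is.finite(zbmi))) zbmi <- rep(0, n)
  density_factor <- exp(config$density_age_coef * zage +
                        config$density_bmi_coef * zbmi +
                        rnorm(n, 0, config$density_factor_sd))
  zht <- as.numeric(scale(height))
  if (any(!is.finite(zht))) zht <- rep(0, n)
  size_factor <- exp(config$size_height_coef * zht +
                     rnorm(n, 0, config$size_factor_sd))

  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = sex, age = age, body_weight = weight, height = height, bmi = bmi,
    hka_angle = round(hka, 1), vv_angle = round(vv, 1),
    alignment_group = group, tray_size = tray_size, side = side,
    density_factor = density_factor, size_factor = size_factor,
    stringsAsFactors = FALSE
  )
}

empty_cohort <- function() {
  data.frame(subject_id = character(0), sex = character(0), age = numeric(0),
             body_weight = numeric(0), height = numeric(0), bmi = numeric(0),
             hka_angle = numeric(0), vv_angle = numeric(0),
             alignment_group = character(0), tray_size = numeric(0),
             side = character(0), density_factor = numeric(0),
             size_factor = numeric(0),
             stringsAsFactors = FALSE)
}
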