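# population-level outcome measures and statistics

#' Compute per-subject outcome records from ROI trajectories
#'
#' delta_abs = bmd(t) - bmd(baseline); delta_rel = 100 * delta_abs /
#' bmd(baseline).  Subjects without a baseline sample are excluded with a
#' message.
#'
#' @param trajectories data.frame(subject_id, roi, time_years, bmd)
#' @param baseline_time time of the baseline sample, years
#' @return data.frame with added delta_abs and delta_rel columns
#' @export
compute_outcomes <- function(trajectories, baseline_time = 0) {
  stopifnot(all(c("subject_id", "roi", "time_years", "bmd") %in%
                names(trajectories)))
  base <- trajectories[abs(trajectories$time_years - baseline_time) < 1e-9,
                       c("subject_id", "roi", "bmd")]
  names(base)[3] <- "bmd0"
  out <- merge(trajectories, base, by = c("subject_id", "roi"), all.x = TRUE)
  drop <- unique(out$subject_id[is.na(out$bmd0)])
  if (length(drop)) {
    message("excluding subjects without baseline: ", paste(drop, collapse = ", "))
    out <- out[!out$subject_id %in% drop, ]
  }
  out$delta_abs <- out$bmd - out$bmd0
  out$delta_rel <- 100 * out$delta_abs / out$bmd0
  out$bmd0 <- NULL
  out[order(out$subject_id, out$roi, out$time_years), ]
}

#' Two-sample Z-test from summary statistics
#'
#' z = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2); two-tailed p from the
#' standard normal.  Normality is assumed; no multiplicity adjustment is
#' applied.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @param alpha significance level
#' @return list(z, p, significant, se)
#' @export
z_test_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  if (se == 0) {
    p <- if (mean1 == mean2) 1 else 0
    z <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    z <- (mean1 - mean2) / se
    p <- 2 * pnorm(-abs(z))
  }
  list(z = z, p = p, significant = p < alpha, se = se)
}

#' Pearson correlation with a two-tailed t-approximation p-value
#'
#' Pairwise-complete observations; a zero-variance input yields an undefined
#' entry rather than being dropped silently.
#'
#' @param x,y numeric vectors
#' @param alpha significance level
#' @return list(r, p, n, significant, undefined)
#' @export
pearson_test <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA, p = NA, n = n, significant = FALSE,
                         undefined = TRUE))
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(r = NA, p = NA, n = n, significant = FALSE, undefined = TRUE))
  r <- cor(x[ok], y[ok])
  p <- if (abs(r) >= 1) 0 else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tv), df = n - 2)
  }
  list(r = r, p = p, n = n, significant = p < alpha, undefined = FALSE)
}

#' Per-subject wide outcome measures
#'
#' One row per subject: baseline ROI BMD and relative/net ROI change at the
#' requested follow-up time, per ROI.
#'
#' @param outcomes data.frame from [compute_outcomes()]
#' @param followup_years follow-up time for the change measures
#' @return wide data.frame keyed by subject_id
#' @export
subject_measures <- function(outcomes, followup_years = 15) {
  rois <- unique(outcomes$roi)
  out <- data.frame(subject_id = unique(outcomes$subject_id))
  for (r in rois) {
    b <- outcomes[outcomes$roi == r & outcomes$time_years == 0, ]
    f <- outcomes[outcomes$roi == r &
                  abs(outcomes$time_years - followup_years) < 1e-9, ]
    out[[paste0("baseline_", r)]] <- b$bmd[match(out$subject_id, b$subject_id)]
    out[[paste0("drel_", r)]] <- f$delta_rel[match(out$subject_id, f$subject_id)]
    out[[paste0("dabs_", r)]] <- f$delta_abs[match(out$subject_id, f$subject_id)]
  }
  out
}

#' Correlation table between subject covariates and remodeling outcome
#'
#' @param cohort subject table (see [generate_cohort()])
#' @param outcomes data.frame from [compute_outcomes()]
#' @param covariates cohort columns to correlate (baseline ROI BMD columns
#'   are always included)
#' @param followup_years follow-up time for the change measures
#' @return long data.frame(covariate, measure, r, p, n, significant)
#' @export
correlation_table <- function(cohort, outcomes,
                              covariates = c("age", "body_weight", "height",
                                             "bmi", "tray_size"),
                              followup_years = 15) {
  wide <- subject_measures(outcomes, followup_years)
  wide <- merge(wide, cohort, by = "subject_id")
  rois <- unique(outcomes$roi)
  covs <- c(paste0("baseline_", rois), covariates)
  meas <- c(paste0("baseline_", rois), paste0("drel_", rois),
            paste0("dabs_", rois))
  rows <- list()
  for (cv in covs) for (ms in meas) {
    if (cv == ms) next
    ct <- pearson_test(wide[[cv]], wide[[ms]])
    rows[[length(rows) + 1]] <- data.frame(
      covariate = cv, measure = ms, r = ct$r, p = ct$p, n = ct$n,
      significant = isTRUE(ct$significant), undefined = ct$undefined)
  }
  do.call(rbind, rows)
}

#' Group mean and SD trajectories with pairwise Z-tests
#'
#' Summaries per group x ROI x time; groups with fewer than two subjects are
#' summarized without tests.  No multiple-testing adjustment is applied.
#'
#' @param outcomes data.frame from [compute_outcomes()]
#' @param cohort subject table
#' @param grouping cohort column to group by ("alignment_group" or "sex")
#' @param value outcome column to compare ("bmd", "delta_rel", "delta_abs")
#' @return list(summary, tests)
#' @export
subgroup_summary <- function(outcomes, cohort, grouping = "alignment_group",
                             value = "bmd") {
  dat <- merge(outcomes, cohort[, c("subject_id", grouping)], by = "subject_id")
  names(dat)[names(dat) == grouping] <- "group"
  agg <- aggregate(dat[[value]],
                   by = list(group = dat$group, roi = dat$roi,
                             time_years = dat$time_years),
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  summary <- data.frame(agg[, 1:3], mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                        n = agg$x[, "n"])
  groups <- unique(summary$group)
  tests <- list()
  if (length(groups) >= 2) {
    cmb <- utils::combn(as.character(groups), 2)
    for (k in seq_len(ncol(cmb))) {
      g1 <- cmb[1, k]; g2 <- cmb[2, k]
      s1 <- summary[summary$group == g1, ]; s2 <- summary[summary$group == g2, ]
      mg <- merge(s1, s2, by = c("roi", "time_years"),
                  suffixes = c("_1", "_2"))
      mg <- mg[mg$n_1 >= 2 & mg$n_2 >= 2, ]
      if (!nrow(mg)) next
      zt <- mapply(function(m1, d1, k1, m2, d2, k2)
        unlist(z_test_two_sample(m1, d1, k1, m2, d2, k2)[c("z", "p")]),
        mg$mean_1, mg$sd_1, mg$n_1, mg$mean_2, mg$sd_2, mg$n_2)
      tests[[length(tests) + 1]] <- data.frame(
        group1 = g1, group2 = g2, roi = mg$roi, time_years = mg$time_years,
        z = zt["z", ], p = zt["p", ], significant = zt["p", ] < 0.05)
    }
  }
  list(summary = summary,
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       note = "no multiple-testing adjustment applied")
}

#' Published clinical reference summaries
#'
#' Reported mean/SD BMD and BMD-change values of the comparison clinical
#' DEXA cohort (n = 17) and of the reference FE population (n = 26), used
#' for population-level Z-test comparisons.
#'
#' @return data.frame(population, roi, time_years, measure, mean, sd, n)
#' @export
clinical_reference <- function() {
  path <- system.file("extdata", "clinical_reference.csv", package = "tkaremod")
  if (path == "") path <- file.path("inst", "extdata", "clinical_reference.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Z-test comparison of cohort outcomes against the clinical reference
#'
#' @param outcomes data.frame from [compute_outcomes()]
#' @param reference data.frame from [clinical_reference()] (clinical rows)
#' @return data.frame of comparisons per ROI x time x measure
#' @export
compare_to_reference <- function(outcomes, reference = clinical_reference()) {
  ref <- reference[reference$population == "clinical", ]
  rows <- list()
  for (i in seq_len(nrow(ref))) {
    rr <- ref[i, ]
    col <- switch(rr$measure, bmd = "bmd", delta_rel = "delta_rel",
                  delta_abs = "delta_abs", NA)
    if (is.na(col)) next
    sub <- outcomes[outcomes$roi == rr$roi &
                    abs(outcomes$time_years - rr$time_years) < 1e-9, ]
    if (nrow(sub) < 2) next
    zt <- z_test_two_sample(mean(sub[[col]]), sd(sub[[col]]), nrow(sub),
                            rr$mean, rr$sd, rr$n)
    rows[[length(rows) + 1]] <- data.frame(
      roi = rr$roi, time_years = rr$time_years, measure = rr$measure,
      fe_mean = mean(sub[[col]]), fe_sd = sd(sub[[col]]), fe_n = nrow(sub),
      ref_mean = rr$mean, ref_sd = rr$sd, ref_n = rr$n,
      z = zt$z, p = zt$p, significant = zt$significant)
  }
  do.call(rbind, rows)
}
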