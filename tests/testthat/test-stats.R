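test_that("outcome deltas follow their definitions exactly", {
  traj <- data.frame(subject_id = "A", roi = "medial",
                     time_years = c(0, 2), bmd = c(0.594, 0.289))
  oc <- compute_outcomes(traj)
  expect_equal(oc$delta_abs[oc$time_years == 2], -0.305)
  expect_equal(oc$delta_rel[oc$time_years == 2], 100 * -0.305 / 0.594)
  expect_equal(oc$delta_abs[oc$time_years == 0], 0)
  # constant trajectory
  tc <- data.frame(subject_id = "B", roi = "distal",
                   time_years = c(0, 1, 5), bmd = 0.7)
  occ <- compute_outcomes(tc)
  expect_true(all(occ$delta_abs == 0) && all(occ$delta_rel == 0))
  # +50%
  tu <- data.frame(subject_id = "C", roi = "lateral",
                   time_years = c(0, 3), bmd = c(1, 1.5))
  expect_equal(compute_outcomes(tu)$delta_rel[2], 50)
})

test_that("outcome computation is lossless and excludes baseline-free subjects", {
  traj <- expand.grid(subject_id = c("A", "B"), roi = c("m", "l"),
                      time_years = c(0, 2, 5))
  traj$bmd <- withr::with_seed(4, runif(nrow(traj), 0.3, 1))
  oc <- compute_outcomes(traj)
  base <- oc[oc$time_years == 0, c("subject_id", "roi", "bmd")]
  rec <- merge(oc, base, by = c("subject_id", "roi"), suffixes = c("", "0"))
  expect_equal(rec$bmd0 + rec$delta_abs, rec$bmd)  # exact arithmetic
  nob <- traj[traj$time_years > 0 | traj$subject_id == "A", ]
  expect_message(oc2 <- compute_outcomes(nob), "excluding")
  expect_false("B" %in% oc2$subject_id)
})

test_that("the two-sample Z-test matches its closed form and flags the
           preoperative medial ROI difference", {
  # printed preoperative medial ROI summaries: FE vs clinical populations
  zt <- z_test_two_sample(0.594, 0.162, 26, 0.854, 0.311, 17)
  expect_lt(zt$p, 0.05)
  expect_true(zt$significant)
  expect_lt(zt$z, 0)
  ident <- z_test_two_sample(1, 0.2, 10, 1, 0.2, 10)
  expect_equal(ident$z, 0); expect_equal(ident$p, 1)
  zt2 <- z_test_two_sample(0, 1, 100, 1, 1, 100)
  expect_equal(zt2$z, -1 / sqrt(0.02), tolerance = 1e-12)
  expect_lt(zt2$p, 2e-12); expect_gt(zt2$p, 1e-12)
  # zero-variance edge cases
  expect_equal(z_test_two_sample(1, 0, 5, 1, 0, 5)$p, 1)
  expect_equal(z_test_two_sample(1, 0, 5, 2, 0, 5)$p, 0)
})

test_that("Z-test p agrees with a quadrature normal-tail oracle over |z| <= 8", {
  for (z in seq(0.5, 8, by = 0.5)) {
    p_pkg <- z_test_two_sample(z, 1, 2, 0, 1, 2)$p
    # oracle: se = sqrt(1/2+1/2) = 1, so the statistic is exactly z
    tail <- stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-13)$value
    expect_lt(abs(p_pkg - 2 * tail), 1e-10)
  }
})

test_that("Pearson correlation handles exact, shuffled and degenerate inputs", {
  x <- 1:20
  ct <- pearson_test(x, 2 * x + 1)
  expect_equal(ct$r, 1); expect_equal(ct$p, 0)
  expect_true(pearson_test(x, rep(3, 20))$undefined)
  # seeded shuffles stay below the alpha=0.05 critical |r| at n=26 mostly
  withr::with_seed(99, {
    x26 <- rnorm(26)
    y26 <- rnorm(26)
    tcrit <- stats::qt(0.975, 24)
    rcrit <- tcrit / sqrt(24 + tcrit^2)
    hits <- mean(replicate(100, abs(pearson_test(x26, sample(y26))$r) < rcrit))
    expect_gte(hits, 0.9)
  })
})

test_that("correlation table has a symmetric baseline block", {
  co <- generate_cohort(seed = 2)
  oc <- fixture("toy_outcomes", {
    # synthetic trajectories: deterministic function of the cohort factors
    do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
      base <- c(medial = 0.6, lateral = 0.47, distal = 0.7) * co$density_factor[i]
      do.call(rbind, lapply(names(base), function(r) data.frame(
        subject_id = co$subject_id[i], roi = r, time_years = c(0, 15),
        bmd = c(base[[r]], base[[r]] * ifelse(r == "distal", 1.5, 0.6)))))
    }))
  })
  tab <- correlation_table(co, compute_outcomes(oc), covariates = "age",
                           followup_years = 15)
  r_ml <- tab$r[tab$covariate == "baseline_medial" & tab$measure == "baseline_lateral"]
  r_lm <- tab$r[tab$covariate == "baseline_lateral" & tab$measure == "baseline_medial"]
  expect_equal(r_ml, r_lm)
})

test_that("subgroup summaries report small groups without tests", {
  co <- generate_cohort(seed = 3)   # one valgus knee
  oc <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) data.frame(
    subject_id = co$subject_id[i], roi = "medial", time_years = c(0, 2),
    bmd = c(0.6, 0.45) * co$density_factor[i])))
  sg <- subgroup_summary(compute_outcomes(oc), co, "alignment_group")
  expect_true("valgus" %in% sg$summary$group)
  expect_equal(sg$summary$n[sg$summary$group == "valgus"][1], 1)
  if (!is.null(sg$tests))
    expect_false(any(grepl("valgus", paste(sg$tests$group1, sg$tests$group2))))
  expect_match(sg$note, "no multiple-testing")
  # two identical groups are never significant
  co2 <- co[co$alignment_group != "valgus", ]
  oc2 <- do.call(rbind, lapply(seq_len(nrow(co2)), function(i) data.frame(
    subject_id = co2$subject_id[i], roi = "medial", time_years = c(0, 2),
    bmd = c(0.6, 0.45))))
  sg2 <- subgroup_summary(compute_outcomes(oc2), co2, "alignment_group")
  expect_false(any(sg2$tests$significant))
})

test_that("comparison against the published clinical summaries runs per measure", {
  ref <- clinical_reference()
  expect_true(all(c("population", "roi", "time_years", "measure") %in% names(ref)))
  oc <- do.call(rbind, lapply(sprintf("S%02d", 1:5), function(id) {
    expand.grid(subject_id = id, roi = c("medial", "lateral", "distal"),
                time_years = c(0, 2, 5, 11.6))
  }))
  withr::with_seed(8, oc$bmd <- runif(nrow(oc), 0.4, 0.8))
  cmp <- compare_to_reference(compute_outcomes(oc))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$significant == (cmp$p < 0.05)))
  expect_setequal(unique(cmp$measure), c("bmd", "delta_rel", "delta_abs"))
})
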