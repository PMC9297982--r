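#!/usr/bin/env Rscript
# Stage 3: figures — ROI BMD trajectories (mean +/- SD) for the whole
# cohort and split by native alignment, plus a virtual DEXA image of one
# subject.  Written under results/figures/.

suppressPackageStartupMessages({
  library(tkaremod)
})
if (!requireNamespace("ggplot2", quietly = TRUE))
  stop("ggplot2 is required for the figures stage")
library(ggplot2)

in_dir <- file.path("results", "cohort")
out_dir <- file.path("results", "figures")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
traj <- utils::read.csv(file.path(in_dir, "roi_bmd.csv"))
cohort <- utils::read.csv(file.path(in_dir, "cohort.csv"))
outcomes <- compute_outcomes(traj)

summ <- aggregate(bmd ~ roi + time_years, outcomes,
                  function(v) c(mean = mean(v), sd = sd(v)))
summ <- data.frame(summ[, 1:2], mean = summ$bmd[, "mean"], sd = summ$bmd[, "sd"])
p1 <- ggplot(summ, aes(time_years, mean)) +
  geom_ribbon(aes(ymin = mean - sd, ymax = mean + sd), alpha = 0.2) +
  geom_line() + geom_point(size = 1) +
  facet_wrap(~roi, scales = "free_y") +
  labs(x = "Postoperative time (years)", y = "Areal BMD (g/cm²)",
       title = "Simulated periprosthetic BMD (mean ± SD, n = 26)") +
  theme_bw()
ggsave(file.path(out_dir, "roi_trajectories.png"), p1,
       width = 9, height = 3.2, dpi = 150)

sg <- merge(outcomes, cohort[, c("subject_id", "alignment_group")])
sg <- sg[sg$alignment_group %in% c("varus", "neutral") & sg$roi != "distal", ]
s2 <- aggregate(delta_rel ~ roi + time_years + alignment_group, sg, mean)
p2 <- ggplot(s2, aes(time_years, delta_rel, colour = alignment_group)) +
  geom_line() + geom_point(size = 1) +
  facet_wrap(~roi) +
  labs(x = "Postoperative time (years)", y = "Relative BMD change (%)",
       colour = "Native alignment",
       title = "Proximal remodeling by native alignment") +
  theme_bw()
ggsave(file.path(out_dir, "alignment_subgroups.png"), p2,
       width = 8, height = 3.2, dpi = 150)

# one subject's virtual DEXA projection with ROI rectangles
cfg <- default_run_config(seed = 1)
rec <- generate_cohort(cfg$cohort, cfg$seed)[1, ]
pre <- build_preop_tibia(rec, cfg$geometry, cfg$seed)
imp <- make_implant_spec(rec$tray_size, pre$geometry)
rois <- place_rois(imp, pre$geometry)
img <- project_ap(voxelize(pre, cfg$dexa_voxel), pre$density)
df <- expand.grid(x = img$origin[1] + (seq_len(nrow(img$bmd)) - 1) * img$spacing,
                  z = img$origin[2] + (seq_len(ncol(img$bmd)) - 1) * img$spacing)
df$bmd <- as.vector(img$bmd)
rdf <- do.call(rbind, lapply(rois, function(r)
  data.frame(xmin = r$x[1], xmax = r$x[2], zmin = r$z[1], zmax = r$z[2])))
p3 <- ggplot(df, aes(x, z, fill = bmd)) +
  geom_raster() +
  geom_rect(data = rdf, aes(xmin = xmin, xmax = xmax, ymin = zmin, ymax = zmax),
            inherit.aes = FALSE, fill = NA, colour = "red") +
  scale_fill_viridis_c(name = "g/cm²") +
  coord_equal() +
  labs(x = "ML (mm, +medial)", y = "Axial (mm)",
       title = "Virtual AP DEXA projection with densitometry ROIs") +
  theme_minimal()
ggsave(file.path(out_dir, "virtual_dexa.png"), p3, width = 5, height = 7,
       dpi = 150)
message("Figures written under ", out_dir)
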