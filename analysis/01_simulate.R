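#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analyses:
# two wounded-monolayer conditions (coordinated / uncoordinated polarity),
# a co-localization time-course, photobleach pairs, biosensor traces,
# force-distance curves and a correlated velocity field. Everything is
# written as CSV under results/sim/ with its ground truth, so each later
# stage can be checked against what was actually simulated.

suppressPackageStartupMessages(library(ecpolarity))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Wounded monolayers: 4 images per condition, ~600 cells per 600x400 um
## field. Coordinated: kappa = 2 up to 300 um from the edge. Uncoordinated:
## only the geometric edge bias (kappa floor 0.2, leader band 0.8).
for (cond in c("coordinated", "uncoordinated")) {
  prof <- if (cond == "coordinated") kappa_coordinated() else kappa_floor()
  seeds <- if (cond == "coordinated") 5:8 else 1:4
  cells <- do.call(rbind, lapply(seeds, function(s) {
    sim <- gen_monolayer(monolayer_spec(n_cells = 600,
                                        field_size_um = c(600, 400),
                                        kappa_profile = prof, seed = s))
    cbind(image = paste0("img", s), sim$cells)
  }))
  write.csv(cells, file.path(out, paste0("monolayer_", cond, ".csv")),
            row.names = FALSE)
}
write.csv(data.frame(x_um = c(0, 0), y_um = c(-60, 660)),
          file.path(out, "edge_polyline.csv"), row.names = FALSE)

## Calcium-switch-like co-localization series: overlap ramps 0 -> 50%
tps <- c(0, 1, 5, 10, 20, 30)
ramp <- c(0, 0.05, 0.15, 0.3, 0.45, 0.5)
coloc_truth <- data.frame(time_min = tps, target = ramp, achieved = NA_real_)
for (i in seq_along(tps)) {
  g <- gen_coloc_pair(40, 40, ramp[i], seed = 300 + i)
  coloc_truth$achieved[i] <- g$true_overlap_fraction
  write_image(list(g$image_a, g$image_b),
              file.path(out, sprintf("coloc_t%02d.tif", tps[i])),
              scale = 300)
}
write.csv(coloc_truth, file.path(out, "coloc_truth.csv"), row.names = FALSE)

## Biosensor traces: junctions are peaky, free edges comparable in both
## conditions (events per 300 s trace)
trace_specs <- rbind(
  data.frame(region_id = paste0("j", 1:6), kind = "junction",
             n_peaks = c(4, 3, 5, 2, 4, 3)),
  data.frame(region_id = paste0("e", 1:3), kind = "free-edge",
             n_peaks = c(3, 4, 3)))
traces <- lapply(seq_len(nrow(trace_specs)), function(i) {
  set.seed(400 + i)
  pf <- sort(sample(5:295, trace_specs$n_peaks[i]))
  tr <- gen_activation_trace(pf, peak_height = 60, noise_sd = 6,
                             region_kind = trace_specs$kind[i],
                             region_id = trace_specs$region_id[i],
                             seed = 400 + i)
  data.frame(region_id = tr$region_id, region_kind = tr$region_kind,
             frame = tr$time_s, intensity = tr$intensity,
             background = tr$background, truth_events = tr$truth_events)
})
write.csv(do.call(rbind, traces), file.path(out, "biosensor_traces.csv"),
          row.names = FALSE)

## AFM curves: strong-adhesion vs weak-adhesion populations
set.seed(77)
curves <- list(); truth <- list()
for (i in 1:40) {
  strong <- i <= 20
  depth <- max(10, rnorm(1, if (strong) 220 else 110, 60))
  width <- max(0.5, rnorm(1, 2, 0.4))
  g <- gen_force_curve(force_curve_spec(adhesion_depth_pN = depth,
                                        adhesion_width_um = width,
                                        baseline_noise_sd_pN = 3,
                                        seed = 500 + i))
  id <- sprintf("%s_%02d", if (strong) "ctrl" else "kd", i)
  curves[[i]] <- cbind(curve_id = id, condition =
                         if (strong) "control" else "knockdown",
                       rbind(cbind(g$curve$approach, segment = "approach"),
                             cbind(g$curve$retract, segment = "retract")))
  truth[[i]] <- data.frame(curve_id = id, true_work_fJ = g$true_work_fJ,
                           true_max_force_pN = g$true_max_force_pN)
}
write.csv(do.call(rbind, curves), file.path(out, "afm_curves.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, truth), file.path(out, "afm_truth.csv"),
          row.names = FALSE)

## Velocity field with 100 um correlation length
f <- gen_velocity_field(velocity_field_spec(seed = 1))
nodes <- expand.grid(iy = seq_len(nrow(f$u)), ix = seq_len(ncol(f$u)))
write.csv(data.frame(x_um = (nodes$ix - 1) * f$grid_spacing_um,
                     y_um = (nodes$iy - 1) * f$grid_spacing_um,
                     u_um_h = as.numeric(f$u), v_um_h = as.numeric(f$v)),
          file.path(out, "velocity_field.csv"), row.names = FALSE)

cat("synthetic datasets written under", out, "\n")
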