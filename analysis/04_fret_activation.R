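#!/usr/bin/env Rscript
# FRET analyses: (1) acceptor-photobleaching efficiency recovered from
# synthetic donor pairs across a range of true efficiencies; (2) biosensor
# activation-peak counts per junction and per leading edge from the
# simulated trace set, honoring the 3-frame merge rule.

suppressPackageStartupMessages(library(ecpolarity))
simdir <- "results/sim"

## acceptor photobleaching
ef_grid <- c(0.05, 0.1, 0.2, 0.3, 0.4)
ef_tab <- do.call(rbind, lapply(seq_along(ef_grid), function(i) {
  p <- gen_photobleach_pair(ef_grid[i], i_post = 100, noise_sd = 2,
                            image_shape = c(100, 100), seed = 600 + i)
  r <- fret_efficiency(p$donor_pre, p$donor_post, p$roi)
  data.frame(ef_true = ef_grid[i], ef_measured = r$ef, flag = r$flag)
}))
cat("acceptor photobleaching: EF recovery\n")
print(ef_tab, digits = 3)

## biosensor peak counting
tr_raw <- read.csv(file.path(simdir, "biosensor_traces.csv"))
traces <- lapply(split(tr_raw, tr_raw$region_id), function(g) {
  g <- g[order(g$frame), ]
  structure(list(time_s = g$frame, intensity = g$intensity,
                 background = g$background,
                 region_kind = g$region_kind[1],
                 region_id = g$region_id[1],
                 truth_events = g$truth_events[1]),
            class = "activation_trace")
})
pr <- peaks_per_region(traces, z_cutoff = 3)
truth <- vapply(traces, `[[`, numeric(1), "truth_events")
pr$per_region$truth <- truth[pr$per_region$region_id]
cat("\nactivation events per region (detected vs simulated):\n")
print(pr$per_region, row.names = FALSE)
cat("\nper-kind summary:\n")
print(pr$summary, digits = 3)

write_results(tables = list(photobleach = ef_tab,
                            peaks = pr$per_region,
                            peaks_summary = pr$summary),
              summary = list(max_ef_error =
                               max(abs(ef_tab$ef_true - ef_tab$ef_measured)),
                             total_events = sum(pr$per_region$n_events)),
              out_dir = "results",
              config = run_config(gaussian_sd_px = 0.75, merge_window = 3,
                                  z_cutoff = 3),
              prefix = "fret")
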