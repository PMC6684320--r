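#!/usr/bin/env Rscript
# Single-cell force spectroscopy: parse the simulated force-distance
# curves, compute detachment work and maximum detachment force per curve,
# build force histograms per condition and the cadherin-dependent fraction
# (events above 150 pN).

suppressPackageStartupMessages(library(ecpolarity))
simdir <- "results/sim"
tab <- read.csv(file.path(simdir, "afm_curves.csv"))
truth <- read.csv(file.path(simdir, "afm_truth.csv"))

res <- do.call(rbind, lapply(split(tab, tab$curve_id), function(g) {
  cv <- parse_curve(g)
  w <- detachment_work(cv)
  data.frame(curve_id = g$curve_id[1], condition = g$condition[1],
             work_fJ = w$work_fJ, flag = w$flag,
             max_force_pN = max_detachment_force(cv))
}))
res <- merge(res, truth, by = "curve_id")

cat("detachment work (fJ) by condition:\n")
for (cond in unique(res$condition)) {
  r <- res[res$condition == cond, ]
  cat(sprintf("  %s: mean %.3f fJ (truth %.3f), n = %d\n", cond,
              mean(r$work_fJ), mean(r$true_work_fJ), nrow(r)))
  cat(sprintf("  %s: cadherin-dependent fraction (>150 pN): %.0f %%\n",
              cond, cadherin_fraction(r$max_force_pN)))
}
hist_ctrl <- force_histogram(res$max_force_pN[res$condition == "control"])

write_results(tables = list(curves = res, force_histogram_control = hist_ctrl),
              summary = list(
                mean_work_control_fJ =
                  mean(res$work_fJ[res$condition == "control"]),
                mean_work_knockdown_fJ =
                  mean(res$work_fJ[res$condition == "knockdown"]),
                cadherin_fraction_control =
                  cadherin_fraction(res$max_force_pN[res$condition ==
                                                       "control"])),
              out_dir = "results",
              config = run_config(threshold_pN = 150, baseline_frac = 0.1,
                                  mode = "hysteresis"),
              prefix = "afm")
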