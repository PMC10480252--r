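#!/usr/bin/env Rscript
# Step 4: how the pressure-drop metrics relate to one another.
#
# Pools the harness runs from step 3 and regresses each metric on the
# others within each flow mode. The net drop tracks the instantaneous peak
# tightly (slope ~ 1 - 2r(1-r): pressure recovery), while the peak-to-peak
# drop correlates poorly with both - it is ruled partly by wave-reflection
# coupling rather than by the valve.

suppressPackageStartupMessages(library(flowphantom))

tbl <- tryCatch(utils::read.csv("results/harness_runs.csv"),
                error = function(e) stop("run analysis/03_reproducibility.R first"))

pairs <- list(c("peak_drop", "net_drop"),
              c("peak_drop", "peak_to_peak_drop"),
              c("net_drop", "peak_to_peak_drop"))
rows <- list()
for (mode in c("pulsatile", "constant")) {
  for (p in pairs) {
    if (mode == "constant" && "peak_to_peak_drop" %in% p) next
    mr <- metric_relation(tbl, p[1], p[2], mode)
    rows[[length(rows) + 1]] <-
      tibble::tibble(mode = mode, x = p[1], y = p[2], n = mr$n,
                     slope = mr$slope, intercept = mr$intercept,
                     r_squared = mr$r_squared)
  }
}
rel <- do.call(rbind, rows)
utils::write.csv(rel, "results/metric_relations.csv", row.names = FALSE)
print(as.data.frame(rel), digits = 3)

np <- rel[rel$x == "peak_drop" & rel$y == "net_drop", ]
cat(sprintf("\nNet underestimates the peak drop by the recovery factor: slopes %.2f (pulsatile), %.2f (constant)\n",
            np$slope[np$mode == "pulsatile"], np$slope[np$mode == "constant"]))
pp <- rel[rel$y == "peak_to_peak_drop", ]
cat(sprintf("Peak-to-peak relates poorly to both instantaneous metrics (r2 = %.2f, %.2f)\n",
            pp$r_squared[1], pp$r_squared[2]))
write_manifest("results/metric_relations_manifest.json",
               command = "04_metric_relations",
               inputs = "results/harness_runs.csv",
               outputs = "results/metric_relations.csv")
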