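#!/usr/bin/env Rscript
# Segment the simulated populations from 01_simulate_populations.R and
# compute per-animal navigation indices over the standard 10-min analysis
# window, mirroring the gradient-assay readout: chemotactic index (mean
# velocity along the gradient over mean crawling speed), biased-random-walk
# index (relative up/down run durations) and klinotaxis index (relative
# probability of post-reorientation runs starting up-gradient). Writes
# per-animal tables plus boxplot-style group summaries under results/.

suppressPackageStartupMessages(library(wormnav))

g <- gradient_spec()
w <- analysis_window() # 0-600 s, >= 300 s active
conditions <- c("mock", "conditioned", "mutant_cond")

all_idx <- NULL
for (nm in conditions) {
  path <- file.path("results", paste0("tracks_", nm, ".csv"))
  if (!file.exists(path))
    stop("run analysis/01_simulate_populations.R first (missing ", path, ")")
  trajs <- lapply(read_trajectories(path), compute_speed)
  idx <- navigation_indices(trajs, g, w)
  idx$group <- nm
  all_idx <- rbind(all_idx, idx)
  cat(sprintf("%-12s n=%3d  chemotactic %+0.3f  brw %+0.3f  klinotaxis %+0.3f  mean pos %+5.1f mm\n",
              nm, nrow(idx), mean(idx$chemotactic),
              mean(idx$brw, na.rm = TRUE),
              mean(idx$klinotaxis, na.rm = TRUE), mean(idx$mean_pos_mm)))
  mp <- mean_position_trace(lapply(trajs, clip_trajectory,
                                   t_start = 0, t_end = 1800), g)
  write.csv(mp, file.path("results", paste0("mean_position_", nm, ".csv")),
            row.names = FALSE)
}
write_report(all_idx, "results/navigation_indices")
cat("per-animal indices in results/navigation_indices.tsv;",
    "group summaries (median, quartiles, Tukey whiskers)",
    "in results/navigation_indices.json\n")
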