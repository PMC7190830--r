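#!/usr/bin/env Rscript
# Foraging readouts: roaming/dwelling classification on food (10 s bins in
# speed--angular-speed space split by the line Speed = Curvature/450) and
# off-food local-search state fractions from the behavioral segmentation.

suppressPackageStartupMessages(library(wormnav))

seed <- 20260904L
g <- gradient_spec()
fp <- foraging_params()
sp <- segmentation_params()

# on-food emulation: an exploratory (roaming-prone) and a sedentary
# (dwelling-prone) parameter set, 20 animals each
sets <- list(
  explorer = locomotion_params(speed_mean = 0.18, run_rate_hz = 0.02,
                               pause_rate_hz = 0.002, heading_noise_deg = 4),
  sedentary = locomotion_params(speed_mean = 0.05, run_rate_hz = 0.25,
                                pause_rate_hz = 0.05, pause_mean_s = 8,
                                heading_noise_deg = 25))
rows <- NULL
for (nm in names(sets)) {
  pop <- simulate_population(sets[[nm]], g, 20, fp$min_track_s_on_food,
                             seed = seed + match(nm, names(sets)))
  for (tr in pop) {
    bins <- bin_speed_curvature(tr, fp)
    s <- foraging_summary(classify_roaming_dwelling(bins, fp), bins)
    s$group <- nm; s$worm_id <- tr$worm_id
    rows <- rbind(rows, s)
  }
  sub <- rows[rows$group == nm, ]
  cat(sprintf("%-9s fraction roaming %.2f (speed roaming %.3f, dwelling %.3f mm/s)\n",
              nm, mean(sub$frac_roaming),
              mean(sub$speed_roaming, na.rm = TRUE),
              mean(sub$speed_dwelling, na.rm = TRUE)))
}
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/roaming_dwelling.csv", row.names = FALSE)

# off-food local search: 15 min assay, state-time fractions per animal
pop <- simulate_population(locomotion_params(pirouette_prob = 0.4,
                                             run_rate_hz = 0.08),
                           g, 20, fp$offfood_duration_s, seed = seed + 10)
ls <- do.call(rbind, lapply(pop, function(tr)
  local_search_summary(segment_trajectory(tr, sp, g), tr)))
cat(sprintf("off food (15 min, n=20): run %.2f pause %.2f turn %.2f pirouette %.2f, mean speed %.3f mm/s\n",
            mean(ls$frac_run), mean(ls$frac_pause), mean(ls$frac_turn),
            mean(ls$frac_pirouette), mean(ls$mean_speed)))
write.csv(ls, "results/local_search.csv", row.names = FALSE)
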