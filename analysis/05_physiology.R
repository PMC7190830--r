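#!/usr/bin/env Rscript
# Physiology readouts: dF/F0 and ratiometric dR/R normalization of
# simulated calcium traces, and four-parameter-logistic EC50 fits of
# simulated GPCR concentration-response series at the three potencies
# reported for the CAPA-1 peptides on NMUR-1 (6 nM, 8 uM, 142 nM).

suppressPackageStartupMessages(library(wormnav))

seed <- 20260905L
dir.create("results", showWarnings = FALSE)

# single-channel (GCaMP-style) trace: 35% step with realistic noise
tr <- simulate_calcium(35, baseline = 100, bg_level = 10, noise_sd = 1.5,
                       seed = seed)
dff <- delta_f_over_f(tr)
cat(sprintf("dF/F0: plateau mean %.1f%% (generated 35%%), baseline sd %.1f%%\n",
            mean(dff[tr$t >= 25 & tr$t < 40]), sd(dff[tr$t < 10])))
write.csv(data.frame(t = tr$t, dff_pct = dff), "results/dff_trace.csv",
          row.names = FALSE)

# ratiometric (cameleon-style) trace
fret <- simulate_calcium_fret(0.08, 0.08, noise_sd = 0.4, seed = seed + 1)
drr <- delta_r_over_r(fret)
cat(sprintf("dR/R: plateau mean %.1f%% (expected %.1f%%)\n",
            mean(drr[fret$t >= 25 & fret$t < 40]), (1.08 / 0.92 - 1) * 100))
write.csv(data.frame(t = fret$t, drr_pct = drr), "results/drr_trace.csv",
          row.names = FALSE)

# concentration-response fits, 0.1 nM - 100 uM, 6 wells per concentration
concs <- 10^seq(-10, -4, length.out = 10)
peptides <- list(capa1_1 = 6e-9, capa1_2 = 8e-6, capa1_3 = 1.42e-7)
fits <- list()
for (nm in names(peptides)) {
  lg <- list(bottom = 0.05, top = 0.55, logEC50 = log10(peptides[[nm]]),
             hill = 1)
  tab <- simulate_dose_response(lg, concentrations = concs, n_replicates = 6,
                                noise_sd = 0.01,
                                seed = seed + match(nm, names(peptides)))
  norm <- normalize_responses(tab)
  f <- fit_dose_response(norm$wells)
  fits[[nm]] <- list(EC50_M = f$EC50, logEC50 = f$coefficients[["logEC50"]],
                     hill = f$coefficients[["hill"]],
                     se_logEC50 = f$se[["logEC50"]], flagged = f$flagged)
  cat(sprintf("%s: EC50 %.3g M (generated %.3g M), hill %.2f\n",
              nm, f$EC50, peptides[[nm]], f$coefficients[["hill"]]))
}
jsonlite::write_json(fits, "results/dose_response_fits.json",
                     auto_unbox = TRUE, digits = NA)
cat("fits written to results/dose_response_fits.json\n")
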