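#' Simulate a single-channel calcium imaging trace
#'
#' Step-response model: a piecewise-linear rise to plateau at stimulus onset
#' followed by exponential decay after stimulus offset,
#' `F(t) = bg_level + baseline * (1 + amplitude_pct/100 * kernel(t)) + noise`.
#' The kernel reaches exactly 1 at plateau, so with zero noise the recovered
#' peak dF/F0 equals `amplitude_pct` exactly.
#'
#' @param amplitude_pct peak dF/F0 in percent.
#' @param stim_interval `c(on, off)` stimulus window (s).
#' @param baseline fluorescence baseline above background (a.u.).
#' @param bg_level additive background level (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed RNG seed.
#' @param duration_s,dt trace span and sampling interval (s).
#' @param rise_s,decay_s kernel rise time (linear) and decay constant.
#' @return a calcium trace: list with `t`, `F`, `background`,
#'   `stim_onset_s`, `pre_window_s`.
#' @export
simulate_calcium <- function(amplitude_pct, stim_interval = c(20, 40),
                             baseline = 100, bg_level = 10, noise_sd = 0,
                             seed = 1, duration_s = 60, dt = 0.1,
                             rise_s = 2, decay_s = 5) {
  stopifnot(baseline > bg_level, bg_level >= 0,
            stim_interval[1] >= 10, stim_interval[2] > stim_interval[1],
            stim_interval[2] <= duration_s)
  set.seed(as.integer(seed))
  t <- seq(0, duration_s, by = dt)
  kernel <- calcium_kernel(t, stim_interval, rise_s, decay_s)
  f <- bg_level + baseline * (1 + amplitude_pct / 100 * kernel)
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), 0, noise_sd)
  list(t = t, F = f, background = bg_level,
       stim_onset_s = stim_interval[1], pre_window_s = 10)
}

calcium_kernel <- function(t, stim_interval, rise_s, decay_s) {
  on <- stim_interval[1]; off <- stim_interval[2]
  k <- numeric(length(t))
  during <- t >= on & t < off
  k[during] <- pmin(1, (t[during] - on) / rise_s)
  after <- t >= off
  k_off <- min(1, (off - on) / rise_s)
  k[after] <- k_off * exp(-(t[after] - off) / decay_s)
  k
}

#' Simulate a ratiometric (FRET) calcium trace pair
#'
#' Anti-correlated donor/acceptor channels: on stimulation YFP rises by
#' `yfp_step` (fractional) while CFP falls by `cfp_step`, so the plateau
#' ratio change is `(1 + yfp_step)/(1 - cfp_step) - 1` exactly with zero
#' noise and zero background (e.g. +22.2% for a +/-10% step). A non-zero
#' `bg_level` damps the apparent ratio change, which makes it a fixture for
#' probing background sensitivity.
#'
#' @param yfp_step,cfp_step fractional channel changes at plateau.
#' @inheritParams simulate_calcium
#' @param baseline_cfp,baseline_yfp channel baselines above background.
#' @return a trace list with `t`, `CFP`, `YFP`, `background`,
#'   `stim_onset_s`, `pre_window_s`.
#' @export
simulate_calcium_fret <- function(yfp_step = 0.1, cfp_step = 0.1,
                                  stim_interval = c(20, 40),
                                  baseline_cfp = 80, baseline_yfp = 120,
                                  bg_level = 0, noise_sd = 0, seed = 1,
                                  duration_s = 60, dt = 0.1,
                                  rise_s = 2, decay_s = 5) {
  stopifnot(cfp_step < 1, stim_interval[1] >= 10)
  set.seed(as.integer(seed))
  t <- seq(0, duration_s, by = dt)
  kernel <- calcium_kernel(t, stim_interval, rise_s, decay_s)
  cfp <- bg_level + baseline_cfp * (1 - cfp_step * kernel)
  yfp <- bg_level + baseline_yfp * (1 + yfp_step * kernel)
  if (noise_sd > 0) {
    cfp <- cfp + stats::rnorm(length(t), 0, noise_sd)
    yfp <- yfp + stats::rnorm(length(t), 0, noise_sd)
  }
  list(t = t, CFP = cfp, YFP = yfp, background = bg_level,
       stim_onset_s = stim_interval[1], pre_window_s = 10)
}

#' Simulate a GPCR concentration-response table
#'
#' Draws normalized responses from a four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 c) * hill))`
#' plus Gaussian noise, and emits raw ligand/lysis luminescence pairs
#' consistent with the normalized value (`normalized = ligand/(ligand +
#' lysis)`), mimicking an aequorin assay where cell lysis yields the total
#' calcium response.
#'
#' @param logistic list with `bottom`, `top`, `logEC50`, `hill` (`logEC50`
#'   in log10 molar).
#' @param concentrations molar concentrations (> 0); default 8 points
#'   spanning 0.1 nM to 100 uM.
#' @param n_replicates wells per concentration.
#' @param noise_sd Gaussian noise sd on the normalized response.
#' @param seed RNG seed.
#' @param lysis_lum mean post-lysis luminescence per well (a.u.).
#' @return data frame with `concentration`, `replicate`, `ligand_lum`,
#'   `lysis_lum`, `normalized`.
#' @export
simulate_dose_response <- function(logistic,
                                   concentrations = 10^seq(-10, -4, length.out = 8),
                                   n_replicates = 3, noise_sd = 0, seed = 1,
                                   lysis_lum = 5e5) {
  stopifnot(all(concentrations > 0), n_replicates >= 1,
            all(c("bottom", "top", "logEC50", "hill") %in% names(logistic)))
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration = concentrations)
  y <- four_param_logistic(grid$concentration, logistic$bottom, logistic$top,
                           logistic$logEC50, logistic$hill)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  lys <- lysis_lum * (1 + if (noise_sd > 0)
    stats::rnorm(length(y), 0, 0.02) else 0)
  lig <- y / (1 - y) * lys
  data.frame(concentration = grid$concentration, replicate = grid$replicate,
             ligand_lum = lig, lysis_lum = lys, normalized = y)
}

#' Four-parameter logistic concentration-response curve
#'
#' @param c molar concentration (> 0).
#' @param bottom,top lower and upper asymptotes.
#' @param logEC50 log10 of the half-maximal concentration.
#' @param hill Hill slope.
#' @return response values.
#' @export
four_param_logistic <- function(c, bottom, top, logEC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logEC50 - log10(c)) * hill))
}
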