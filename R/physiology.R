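#' Percent fluorescence change relative to the pre-stimulus baseline
#'
#' `dF/F0 (%) = 100 * (F_corr - F0) / F0` where `F_corr` is the
#' background-corrected fluorescence and `F0` the mean of `F_corr` over the
#' 10 s window before stimulus onset. When a per-sample background stream is
#' supplied, the correction subtracts the median of that stream (the median
#' background intensity of the entire channel stream); a scalar background
#' is subtracted as-is.
#'
#' @param trace a calcium trace: list with `t`, `F`, `background` (scalar or
#'   per-sample), `stim_onset_s` and `pre_window_s` (default 10 s).
#' @return numeric dF/F0 series in percent, or `NA` series with a `"reason"`
#'   attribute if the baseline is non-positive.
#' @export
delta_f_over_f <- function(trace) {
  stopifnot(!is.null(trace$F), !is.null(trace$t))
  pre <- if (!is.null(trace$pre_window_s)) trace$pre_window_s else 10
  bg <- trace$background
  if (length(bg) > 1) bg <- stats::median(bg)
  if (is.null(bg)) bg <- 0
  f_corr <- trace$F - bg
  base_win <- trace$t >= trace$stim_onset_s - pre & trace$t < trace$stim_onset_s
  if (!any(base_win)) stop("no samples in the pre-stimulus window")
  f0 <- mean(f_corr[base_win])
  if (f0 <= 0)
    return(structure(rep(NA_real_, length(f_corr)),
                     reason = "non-positive baseline F0 after background correction"))
  100 * (f_corr - f0) / f0
}

#' Percent ratio change of a ratiometric (FRET) indicator
#'
#' `R = YFP/CFP` by default (the standard FRET convention for yellow
#' cameleon indicators); `R0` is the mean ratio over the 10 s pre-stimulus
#' window and the series is `100 * (R - R0)/R0`. Samples with non-positive
#' denominator are undefined (`NA`).
#'
#' @param trace a two-channel trace: list with `t`, `CFP`, `YFP`,
#'   `stim_onset_s`, `pre_window_s`.
#' @param ratio_order `"yfp_over_cfp"` (default) or `"cfp_over_yfp"`.
#' @return numeric dR/R series in percent.
#' @export
delta_r_over_r <- function(trace, ratio_order = c("yfp_over_cfp", "cfp_over_yfp")) {
  ratio_order <- match.arg(ratio_order)
  stopifnot(!is.null(trace$CFP), !is.null(trace$YFP))
  pre <- if (!is.null(trace$pre_window_s)) trace$pre_window_s else 10
  num <- if (ratio_order == "yfp_over_cfp") trace$YFP else trace$CFP
  den <- if (ratio_order == "yfp_over_cfp") trace$CFP else trace$YFP
  r <- ifelse(den > 0, num / den, NA_real_)
  base_win <- trace$t >= trace$stim_onset_s - pre & trace$t < trace$stim_onset_s
  if (!any(base_win)) stop("no samples in the pre-stimulus window")
  r0 <- mean(r[base_win])
  100 * (r - r0) / r0
}

#' Normalize concentration-response wells to percent activation
#'
#' Each well's ligand-evoked luminescence is normalized to the total calcium
#' response, `normalized = ligand/(ligand + lysis)`, then expressed relative
#' to the highest normalized value of the series (100% activation). Wells
#' with zero total luminescence are excluded with a warning.
#'
#' @param table data frame with `concentration`, `ligand_lum`, `lysis_lum`
#'   and optionally `replicate`.
#' @return list with `wells` (input plus `normalized` and
#'   `percent_activation`) and `summary` (per-concentration mean percent and
#'   S.E.M.).
#' @export
normalize_responses <- function(table) {
  need <- c("concentration", "ligand_lum", "lysis_lum")
  stopifnot(all(need %in% names(table)))
  tot <- table$ligand_lum + table$lysis_lum
  if (any(tot == 0)) {
    warning(sprintf("%d well(s) with zero total luminescence excluded", sum(tot == 0)))
    table <- table[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  table$normalized <- table$ligand_lum / tot
  table$percent_activation <- 100 * table$normalized / max(table$normalized)
  agg <- split(table$percent_activation, table$concentration)
  summary <- data.frame(
    concentration = as.numeric(names(agg)),
    mean_percent = vapply(agg, mean, numeric(1)),
    sem_percent = vapply(agg, function(v)
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
    n = vapply(agg, length, integer(1)))
  summary <- summary[order(summary$concentration), ]
  rownames(summary) <- NULL
  list(wells = table, summary = summary)
}

#' Fit a sigmoidal concentration-response curve
#'
#' Least-squares fit of the variable-slope four-parameter logistic
#' `y = bottom + (top - bottom)/(1 + 10^((logEC50 - log10 c) * hill))` on
#' log10 concentration, with all wells (replicates) as observations.
#' Initialization: `bottom = min(y)`, `top = max(y)`, `hill = 1`, `logEC50`
#' at the half-range crossing by linear interpolation of per-concentration
#' means.
#'
#' @param table data frame with `concentration` and a response column.
#' @param response name of the response column (default `"normalized"`,
#'   falling back to `"percent_activation"`).
#' @return list with `coefficients` (bottom, top, logEC50, hill), `se`
#'   (asymptotic standard errors), `EC50` (molar), `flagged` plus a
#'   `flag_reason`, the `fit` object and `fitted` values.
#' @export
fit_dose_response <- function(table, response = NULL) {
  stopifnot("concentration" %in% names(table), all(table$concentration > 0))
  if (is.null(response))
    response <- if ("normalized" %in% names(table)) "normalized"
                else "percent_activation"
  y <- table[[response]]
  logc <- log10(table$concentration)
  if (length(unique(table$concentration)) < 4)
    stop("need at least 4 distinct concentrations")
  mu <- vapply(split(y, logc), mean, numeric(1))
  lc <- as.numeric(names(mu))
  o <- order(lc); lc <- lc[o]; mu <- mu[o]
  half <- (min(mu) + max(mu)) / 2
  cross <- which(diff(sign(mu - half)) != 0)
  mu <- unname(mu)
  logec50_0 <- if (length(cross)) {
    i <- cross[1]
    lc[i] + (half - mu[i]) * (lc[i + 1] - lc[i]) / (mu[i + 1] - mu[i])
  } else stats::median(lc)
  df <- data.frame(y = y, logc = logc)
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^((logEC50 - logc) * hill)),
    data = df,
    start = list(bottom = min(y), top = max(y), logEC50 = logec50_0, hill = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(coefficients = NULL, se = NULL, EC50 = NA_real_,
                flagged = TRUE, flag_reason = "fit did not converge",
                fit = NULL, fitted = NULL))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  flagged <- FALSE; reason <- NA_character_
  if (cf[["hill"]] <= 0) { flagged <- TRUE; reason <- "non-positive Hill slope at optimum" }
  rng <- abs(cf[["top"]] - cf[["bottom"]])
  if (rng < 1e-10 * max(1, abs(cf[["top"]]))) {
    flagged <- TRUE; reason <- "no inflection (flat response)"
  }
  list(coefficients = cf, se = se, EC50 = 10^cf[["logEC50"]],
       flagged = flagged, flag_reason = reason, fit = fit,
       fitted = stats::fitted(fit))
}
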