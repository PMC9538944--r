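## OECD TG 305 aqueous-exposure study evaluation.
##
## Steady-state BCF = mean fish concentration on plateau days / TWA water
## concentration over the uptake phase; the depuration-phase decline
## C_f(t) = C_f0 * exp(-kT t) gives the overall depuration rate constant
## kT, from which the in vivo biotransformation rate constant is
## back-calculated as kB = kT - (k2 + kE + kG).

#' Time-weighted average water concentration
#'
#' Interval-weighted (trapezoidal) mean over a sampling window.  With a
#' single sample (or all samples at one time) the plain mean is returned.
#'
#' @param days Sampling times (days), non-decreasing.
#' @param conc Water concentrations (ng/L), same length.
#' @param window Optional `c(from, to)` restricting the samples used
#'   (inclusive); default all.
#' @return TWA concentration (ng/L).
#' @examples
#' twa_concentration(c(0, 7, 14), c(4, 4, 8))
#' @export
twa_concentration <- function(days, conc, window = NULL) {
  if (!is.numeric(days) || !is.numeric(conc) || length(days) != length(conc)) {
    stop_invalid("days and conc must be numeric vectors of equal length")
  }
  if (is.unsorted(days)) stop_invalid("days must be non-decreasing")
  if (any(conc < 0)) stop_invalid("concentrations must be non-negative")
  if (!is.null(window)) {
    keep <- days >= window[1] & days <= window[2]
    days <- days[keep]
    conc <- conc[keep]
  }
  if (length(days) == 0L) stop_insufficient("no water samples in window")
  span <- days[length(days)] - days[1]
  if (span == 0) return(mean(conc))
  dt <- diff(days)
  sum(dt * (conc[-1] + conc[-length(conc)]) / 2) / span
}

#' Steady-state bioconcentration factor
#'
#' Mean of all individual fish concentrations on the plateau days divided
#' by the TWA water concentration of the uptake phase.
#'
#' @param fish Data frame in the fish schema (columns `day`, `phase`,
#'   `conc_ng_kg`; see [read_fish_csv()]).
#' @param twa TWA water concentration (ng/L), > 0.
#' @param plateau_days Uptake sampling days considered at steady state;
#'   `NULL` auto-detects via [detect_plateau()].
#' @param alpha Trend-test level passed to [detect_plateau()].
#' @return An object of class `bcf_result`: list with `bcf_ss` (L/kg),
#'   `cf_ss_mean` (ng/kg), `twa_water` (ng/L), `steady_state_days`, `n_fish`.
#' @export
steady_state_bcf <- function(fish, twa, plateau_days = NULL, alpha = 0.05) {
  check_number(twa, "twa", 0, strict_min = TRUE)
  up <- fish[fish$phase == "uptake", , drop = FALSE]
  if (nrow(up) == 0L) stop_insufficient("no uptake-phase fish samples")
  if (is.null(plateau_days)) plateau_days <- detect_plateau(up, alpha = alpha)
  sel <- up[up$day %in% plateau_days, , drop = FALSE]
  if (nrow(sel) == 0L) stop_insufficient("no fish samples on plateau days")
  cf <- mean(sel$conc_ng_kg)
  structure(list(bcf_ss = cf / twa, cf_ss_mean = cf, twa_water = twa,
                 steady_state_days = sort(unique(sel$day)),
                 n_fish = nrow(sel)),
            class = "bcf_result")
}

#' @export
print.bcf_result <- function(x, ...) {
  cat(sprintf("BCF_SS = %.4g L/kg (mean C_f %.4g ng/kg on days %s / TWA %.4g ng/L, n = %d fish)\n",
              x$bcf_ss, x$cf_ss_mean,
              paste(x$steady_state_days, collapse = ","), x$twa_water, x$n_fish))
  invisible(x)
}

#' Auto-detect steady-state (plateau) days of the uptake phase
#'
#' Starting from the final three uptake sampling days, earlier days are
#' added while the log-linear trend of per-fish log concentrations over the
#' candidate days stays non-significant (slope p-value > `alpha`).
#'
#' @param fish Uptake-phase fish records (columns `day`, `conc_ng_kg`).
#' @param alpha Significance level of the trend test (default 0.05).
#' @return Sorted vector of plateau days (>= 3 days when available).
#' @export
detect_plateau <- function(fish, alpha = 0.05) {
  days <- sort(unique(fish$day))
  if (length(days) < 3L) return(days)
  trend_ok <- function(cand) {
    sub <- fish[fish$day %in% cand & fish$conc_ng_kg > 0, , drop = FALSE]
    if (length(unique(sub$day)) < 3L) return(FALSE)
    fit <- stats::lm(log(conc_ng_kg) ~ day, data = sub)
    coefs <- summary(fit)$coefficients
    if (nrow(coefs) < 2L) return(TRUE)
    coefs["day", "Pr(>|t|)"] > alpha
  }
  n <- length(days)
  best <- days[(n - 2L):n]
  if (!trend_ok(best)) return(best)
  for (start in rev(seq_len(n - 3L))) {
    cand <- days[start:n]
    if (!trend_ok(cand)) break
    best <- cand
  }
  best
}

#' Fit the depuration-phase exponential decline
#'
#' OLS of ln(concentration) on days since depuration start, the log-linear
#' form of `C_f = C_f0 * exp(-kT t)`; `kT = -slope`, `C_f0 =
#' exp(intercept)`.  Individual fish are treated as independent
#' observations.  Non-positive concentrations are excluded with a warning.
#'
#' @param fish Data frame with columns `day` (days since depuration start),
#'   `phase`, `conc_ng_kg`; only `phase == "depuration"` rows are used, or
#'   all rows if no phase column is present.
#' @return An object of class `depuration_fit`: list with `kT` (1/d),
#'   `cf0` (ng/kg), `r_squared`, `n_points`, `n_days`.
#' @export
fit_depuration <- function(fish) {
  dep <- if ("phase" %in% names(fish)) {
    fish[fish$phase == "depuration", , drop = FALSE]
  } else fish
  if (any(dep$conc_ng_kg <= 0)) {
    warning("excluding non-positive fish concentrations from depuration fit")
    dep <- dep[dep$conc_ng_kg > 0, , drop = FALSE]
  }
  if (length(unique(dep$day)) < 3L) {
    stop_insufficient("need >= 3 depuration sampling days with positive concentrations")
  }
  fit <- stats::lm.fit(cbind(1, dep$day), log(dep$conc_ng_kg))
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  y <- log(dep$conc_ng_kg)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 0
  structure(list(kT = -slope, cf0 = exp(intercept), r_squared = r2,
                 n_points = nrow(dep), n_days = length(unique(dep$day))),
            class = "depuration_fit")
}

#' @export
print.depuration_fit <- function(x, ...) {
  cat(sprintf("Depuration fit: kT = %.4g 1/d, C_f0 = %.4g ng/kg (r^2 = %.4f, %d fish over %d days)\n",
              x$kT, x$cf0, x$r_squared, x$n_points, x$n_days))
  invisible(x)
}

#' Measured growth rate from fish weights
#'
#' OLS slope of ln(weight) on day: the specific growth rate used for
#' growth-dilution correction.
#'
#' @param fish Data frame with columns `day` and `weight_g`.
#' @return kG (1/d).
#' @examples
#' growth_rate(data.frame(day = c(0, 35), weight_g = c(20, 40)))  # ln 2 / 35
#' @export
growth_rate <- function(fish) {
  w <- fish[is.finite(fish$weight_g) & fish$weight_g > 0, , drop = FALSE]
  if (length(unique(w$day)) < 2L) {
    stop_insufficient("need weights on >= 2 days to estimate growth")
  }
  fit <- stats::lm.fit(cbind(1, w$day), log(w$weight_g))
  unname(fit$coefficients[2])
}

#' Evaluate a full TG 305 aqueous-exposure study
#'
#' Computes the uptake-phase TWA water concentration, the steady-state BCF,
#' the depuration rate constant kT, the measured growth rate, and the in
#' vivo biotransformation rate constant back-calculated through the kinetic
#' mass-balance model.
#'
#' @param water Data frame in the water schema (columns `sample_date_day`,
#'   `phase`, `conc_ng_L`; see [read_water_csv()]).
#' @param fish Data frame in the fish schema (see [read_fish_csv()]); in
#'   depuration rows `day` counts from transfer to clean water.
#' @param phys,chem,suite Mass-balance parameterization for the
#'   back-calculation (see [rate_constants()]).
#' @param plateau_days Steady-state days; `NULL` auto-detects.
#' @param use_measured_growth Use [growth_rate()] from the fish weights for
#'   kG instead of the modeled value (default `TRUE` when weights are
#'   present).
#' @return An object of class `tg305_result`: list with `twa_water`,
#'   `bcf` (a `bcf_result`), `depuration` (a `depuration_fit`),
#'   `kg_measured`, `rates` (non-metabolic rate constants), and `kb_in_vivo`
#'   (from [kb_from_depuration()]).
#' @export
tg305_analyze <- function(water, fish, phys, chem,
                          suite = rate_constant_suite(),
                          plateau_days = NULL, use_measured_growth = TRUE) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  up_w <- water[water$phase == "uptake", , drop = FALSE]
  twa <- twa_concentration(up_w$sample_date_day, up_w$conc_ng_L)
  bcf <- steady_state_bcf(fish, twa, plateau_days = plateau_days)
  dep <- fit_depuration(fish)
  up_f <- fish[fish$phase == "uptake", , drop = FALSE]
  kg_measured <- if (use_measured_growth && "weight_g" %in% names(fish) &&
                     any(is.finite(up_f$weight_g))) {
    # uptake rows only: the depuration day column restarts at transfer
    g <- tryCatch(growth_rate(up_f), fishbcf_error = function(e) NULL)
    if (!is.null(g) && g >= 0) g else NULL
  } else NULL
  rates <- rate_constants(phys, chem, suite, kb = 0, kg_measured = kg_measured)
  kb <- kb_from_depuration(dep$kT, rates$k2, rates$kE, rates$kG)
  structure(list(species = phys$species, chemical = chem$name,
                 twa_water = twa, bcf = bcf, depuration = dep,
                 kg_measured = kg_measured, rates = rates,
                 kb_in_vivo = kb),
            class = "tg305_result")
}

#' @export
print.tg305_result <- function(x, ...) {
  cat(sprintf("TG 305 evaluation: %s / %s\n", x$species, x$chemical))
  cat(sprintf("  TWA water: %.4g ng/L\n", x$twa_water))
  cat(sprintf("  BCF_SS:    %.4g L/kg (days %s)\n", x$bcf$bcf_ss,
              paste(x$bcf$steady_state_days, collapse = ",")))
  cat(sprintf("  kT:        %.4g 1/d (r^2 = %.3f)\n", x$depuration$kT,
              x$depuration$r_squared))
  cat(sprintf("  kB in vivo: %.4g 1/d%s\n", x$kb_in_vivo$kb,
              if (x$kb_in_vivo$distinguishable_from_zero) "" else
                " (not distinguishable from zero)"))
  invisible(x)
}
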