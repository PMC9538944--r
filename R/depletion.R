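## In vitro hepatocyte substrate-depletion analysis.
##
## Substrate depletion in hepatocyte suspensions follows first-order
## kinetics; the elimination rate constant k (1/h) is obtained from the
## slope of an ordinary least-squares regression of log10 concentration on
## incubation time, k = -ln(10) * slope.  Intrinsic clearance normalizes k
## to the nominal density of viable hepatocytes.

#' Default in vitro sampling grid
#'
#' The standard 4 h incubation sampled at 5, 15, 20, 30, 60, 120, 180 and
#' 240 min, returned in hours.
#' @return Numeric vector of 8 sampling times (h).
#' @export
depletion_times <- function() c(5, 15, 20, 30, 60, 120, 180, 240) / 60

validate_timecourse <- function(times, concentrations, min_points = 4L) {
  if (!is.numeric(times) || !is.numeric(concentrations)) {
    stop_invalid("times and concentrations must be numeric")
  }
  if (length(times) != length(concentrations)) {
    stop_invalid("times and concentrations must have equal length")
  }
  if (length(times) < min_points) {
    stop_insufficient(sprintf("need at least %d time points, got %d",
                              min_points, length(times)))
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop_invalid("times must be non-negative and strictly increasing")
  }
  if (any(concentrations < 0)) {
    stop_invalid("concentrations must be non-negative")
  }
  invisible(TRUE)
}

#' Normalize a depletion time course to its first sampling point
#'
#' Rescales concentrations so the first sampled value is 1.  This is a
#' presentation aid for comparing runs; it does not change the fitted
#' slope, since rescaling only shifts the log-scale intercept.
#'
#' @param concentrations Numeric vector of substrate amounts.
#' @return Rescaled concentrations with first element 1.
#' @examples
#' normalize_to_first(c(2, 1, 0.5))
#' @export
normalize_to_first <- function(concentrations) {
  if (!is.numeric(concentrations) || length(concentrations) < 1L) {
    stop_invalid("concentrations must be a non-empty numeric vector")
  }
  if (!is.finite(concentrations[1]) || concentrations[1] <= 0) {
    stop_invalid("first concentration must be > 0 to normalize")
  }
  concentrations / concentrations[1]
}

#' Fit a first-order elimination rate constant to depletion data
#'
#' Ordinary least squares of log10(concentration) on time; the rate
#' constant is `k = -ln(10) * slope` (1/h).  The commonly quoted factor
#' 2.3 is the rounded print of ln(10) = 2.302585; the exact value is used
#' here.
#'
#' @param times Sampling times (h).
#' @param concentrations Substrate amounts (any consistent unit; the slope,
#'   and hence k, is unit-invariant).
#' @param window Optional integer indices of the points to use (default all).
#' @param loq Optional limit of quantification; concentrations at or below
#'   it are excluded from the fit rather than substituted.
#' @return An object of class `clearance_fit`: list with `k` (1/h),
#'   `slope_log10` (1/h), `intercept_log10`, `r_squared`, `window`
#'   (indices used), `n`.
#' @examples
#' t <- depletion_times()
#' fit_first_order(t, 2 * exp(-0.5 * t))
#' @export
fit_first_order <- function(times, concentrations, window = NULL, loq = NULL) {
  validate_timecourse(times, concentrations, min_points = 3L)
  idx <- sort(unique(as.integer(window %||% seq_along(times))))
  if (any(idx < 1L) || any(idx > length(times))) {
    stop_invalid("window indices out of range")
  }
  if (!is.null(loq)) {
    check_number(loq, "loq", 0)
    idx <- idx[concentrations[idx] > loq]
  }
  if (length(idx) < 3L) {
    stop_insufficient("fewer than 3 usable points in fitting window")
  }
  if (any(concentrations[idx] <= 0)) {
    stop_invalid("non-positive concentration inside the fitting window")
  }
  x <- times[idx]
  y <- log10(concentrations[idx])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(
    k = -log(10) * slope,
    slope_log10 = slope,
    intercept_log10 = intercept,
    r_squared = r2,
    window = idx,
    n = length(idx)
  ), class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("First-order depletion fit: k = %.4g 1/h (r^2 = %.4f, n = %d)\n",
              x$k, x$r_squared, x$n))
  if (!is.null(x$clint)) {
    cat(sprintf("  CL_in vitro,int = %.4g mL/h/10^6 cells\n", x$clint))
  }
  invisible(x)
}

#' Select the log-linear portion of a depletion curve
#'
#' Cryopreserved cells can lose activity toward the end of a 4 h
#' incubation, flattening the tail of the depletion curve.  The default
#' policy iteratively drops the final time point when its standardized
#' residual -- relative to a fit on the remaining points -- exceeds a
#' threshold, at most `max_drop` times, and never below 3 points.
#'
#' @param times Sampling times (h).
#' @param concentrations Substrate amounts (> 0).
#' @param threshold Standardized-residual threshold above which the
#'   trailing point is excluded (default 2).
#' @param max_drop Maximum number of trailing points to drop (default 1).
#' @return Integer indices of the retained points.
#' @examples
#' t <- depletion_times()
#' conc <- 2 * exp(-0.8 * t); conc[8] <- conc[7]  # activity lost after 3 h
#' select_linear_window(t, conc)
#' @export
select_linear_window <- function(times, concentrations, threshold = 2,
                                 max_drop = 1) {
  validate_timecourse(times, concentrations, min_points = 4L)
  if (any(concentrations <= 0)) {
    stop_invalid("all concentrations must be > 0 to assess log-linearity")
  }
  check_number(threshold, "threshold", 0, strict_min = TRUE)
  max_drop <- as.integer(max_drop)
  idx <- seq_along(times)
  dropped <- 0L
  while (dropped < max_drop) {
    last <- idx[length(idx)]
    keep <- idx[-length(idx)]
    x <- times[keep]
    y <- log10(concentrations[keep])
    fit <- stats::lm.fit(cbind(1, x), y)
    sigma <- sqrt(sum(fit$residuals^2) / max(length(keep) - 2L, 1L))
    pred <- fit$coefficients[1] + fit$coefficients[2] * times[last]
    resid_last <- log10(concentrations[last]) - pred
    # absolute floor (log10 units) so machine-precision scatter around a
    # perfectly log-linear fit never triggers a drop
    triggered <- abs(resid_last) > 1e-08 &&
      (sigma == 0 || abs(resid_last) / sigma > threshold)
    if (!triggered) break
    if (length(keep) < 3L) {
      stop_insufficient("window policy would leave fewer than 3 points")
    }
    idx <- keep
    dropped <- dropped + 1L
  }
  idx
}

#' Convert an elimination rate constant to in vitro intrinsic clearance
#'
#' @param k First-order elimination rate constant (1/h).
#' @param cell_density Nominal density of viable hepatocytes (cells/mL);
#'   default 2e6.
#' @return CL_in vitro,int in mL/h/10^6 cells.
#' @examples
#' clint_from_k(0.575)          # 0.2875 mL/h/10^6 cells
#' @export
clint_from_k <- function(k, cell_density = 2e6) {
  check_number(k, "k")
  check_number(cell_density, "cell_density", 0, strict_min = TRUE)
  k / (cell_density / 1e6)
}

#' Heat-inactivated control QC
#'
#' Abiotic substrate loss measured in heat-inactivated ("dead") cell
#' suspensions must stay small relative to live-cell clearance; the default
#' acceptance threshold is 5\% of the live rate.
#'
#' @param live_k Live-cell elimination rate (1/h).
#' @param dead_k Inactivated-control elimination rate (1/h).
#' @param threshold Maximum acceptable `dead_k / live_k` ratio (default 0.05).
#' @return List with `ratio`, `pass` (logical; `NA` when the live rate is
#'   not positive so the ratio is undefined) and `threshold`.
#' @examples
#' qc_inactivated(0.5, 0.02)
#' @export
qc_inactivated <- function(live_k, dead_k, threshold = 0.05) {
  check_number(dead_k, "dead_k")
  check_number(threshold, "threshold", 0, strict_min = TRUE)
  if (!is.numeric(live_k) || length(live_k) != 1L || !is.finite(live_k) ||
      live_k <= 0) {
    return(list(ratio = NA_real_, pass = NA, threshold = threshold))
  }
  ratio <- dead_k / live_k
  list(ratio = ratio, pass = ratio <= threshold, threshold = threshold)
}

#' Summarize intrinsic clearance across independent runs
#'
#' @param clints Numeric vector of per-run CL_in vitro,int values
#'   (mL/h/10^6 cells).
#' @return List with `mean_clint`, `sd_clint`, `cv_percent`
#'   (100 * SD / mean, sample SD with n - 1), and `n_runs`.  With a single
#'   run, SD and CV are `NA`.
#' @examples
#' summarize_runs(c(0.1, 0.2, 0.3))
#' @export
summarize_runs <- function(clints) {
  if (length(clints) == 0L) stop_insufficient("no clearance values supplied")
  if (!is.numeric(clints) || any(!is.finite(clints))) {
    stop_invalid("clints must be finite numbers")
  }
  m <- mean(clints)
  if (length(clints) < 2L) {
    return(list(mean_clint = m, sd_clint = NA_real_, cv_percent = NA_real_,
                n_runs = 1L))
  }
  s <- stats::sd(clints)
  cv <- if (m > 0) 100 * s / m else NA_real_
  list(mean_clint = m, sd_clint = s, cv_percent = cv,
       n_runs = length(clints))
}

#' Estimate intrinsic clearance for one in vitro run
#'
#' Convenience wrapper for a full run: fits each live replicate (optionally
#' after window selection), averages the replicate rate constants, fits the
#' heat-inactivated control, applies the dead-cell QC, and converts to
#' CL_in vitro,int.
#'
#' @param data Data frame in the long depletion schema (columns
#'   `condition` (`"live"`/`"inactivated"`), `replicate`, `time_h`,
#'   `concentration`), e.g. from [read_depletion_csv()] or
#'   [simulate_depletion()]; one run only.
#' @param cell_density Viable-cell density (cells/mL), default 2e6.
#' @param select_window Apply [select_linear_window()] per replicate before
#'   fitting (default `FALSE`; set `TRUE` for cryopreserved cells losing
#'   activity late in the incubation).
#' @param threshold,max_drop Window-policy parameters, see
#'   [select_linear_window()].
#' @param loq Optional limit of quantification passed to
#'   [fit_first_order()].
#' @return An object of class `clint_run`: list with per-replicate fits,
#'   `k_mean` (1/h), `clint` (mL/h/10^6 cells), intra-run `cv_percent`
#'   across replicate clints, and `qc` from [qc_inactivated()].
#' @export
estimate_clint <- function(data, cell_density = 2e6, select_window = FALSE,
                           threshold = 2, max_drop = 1, loq = NULL) {
  need <- c("condition", "replicate", "time_h", "concentration")
  if (!all(need %in% names(data))) {
    stop_schema(sprintf("depletion data must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  live <- data[data$condition == "live", , drop = FALSE]
  if (nrow(live) == 0L) stop_insufficient("no live-cell records in run")
  fit_one <- function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    win <- if (select_window) {
      select_linear_window(df$time_h, df$concentration,
                           threshold = threshold, max_drop = max_drop)
    } else NULL
    fit_first_order(df$time_h, df$concentration, window = win, loq = loq)
  }
  fits <- lapply(split(live, live$replicate), fit_one)
  ks <- vapply(fits, function(f) f$k, numeric(1))
  clints <- vapply(ks, clint_from_k, numeric(1), cell_density = cell_density)
  k_mean <- mean(ks)

  dead <- data[data$condition == "inactivated", , drop = FALSE]
  qc <- if (nrow(dead) > 0L) {
    dead_fits <- lapply(split(dead, dead$replicate), fit_one)
    dead_k <- mean(vapply(dead_fits, function(f) f$k, numeric(1)))
    qc_inactivated(k_mean, dead_k)
  } else {
    list(ratio = NA_real_, pass = NA, threshold = 0.05)
  }
  rep_summary <- summarize_runs(clints)
  structure(list(
    replicate_fits = fits,
    k_replicates = ks,
    clint_replicates = clints,
    k_mean = k_mean,
    clint = clint_from_k(k_mean, cell_density),
    cv_percent = rep_summary$cv_percent,
    cell_density = cell_density,
    qc = qc
  ), class = "clint_run")
}

#' @export
print.clint_run <- function(x, ...) {
  cat(sprintf("In vitro run: %d live replicates\n", length(x$k_replicates)))
  cat(sprintf("  k = %.4g 1/h; CL_in vitro,int = %.4g mL/h/10^6 cells (intra-run CV %.3g%%)\n",
              x$k_mean, x$clint, x$cv_percent))
  if (!is.na(x$qc$pass)) {
    cat(sprintf("  inactivated-control QC: ratio %.3g (threshold %.3g) -> %s\n",
                x$qc$ratio, x$qc$threshold, if (isTRUE(x$qc$pass)) "pass" else "FAIL"))
  }
  invisible(x)
}
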