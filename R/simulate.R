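## Synthetic-data generators with known ground truth.
##
## Both generators use multiplicative lognormal noise (mean 1, given CV),
## the analytical-chemistry convention for concentration measurements.  A
## single master seed fans out to deterministic substreams per replicate /
## component so that adding replicates does not perturb existing draws.

#' Simulate an in vitro substrate-depletion run
#'
#' Live replicates follow `C(t) = c0 * exp(-k_true * t) * eps` with
#' lognormal noise `eps` (mean 1, CV `noise_cv`); the heat-inactivated
#' control depletes at the abiotic `dead_loss_rate`.
#'
#' @param k_true True first-order depletion rate (1/h).
#' @param c0 Initial substrate concentration (uM); 2 for MXC-like, 0.5 for
#'   BaP-like scenarios.
#' @param times Sampling times (h); default [depletion_times()].
#' @param n_replicates Number of live replicates (default 3).
#' @param noise_cv Multiplicative lognormal CV of the analytical noise
#'   (fraction, default 0.1).
#' @param dead_loss_rate Abiotic loss rate of the inactivated control
#'   (1/h, default 0.01).
#' @param seed Integer seed; identical seeds give identical data.
#' @param run_id,species,chemical,cell_state Labels copied into the output.
#' @return Data frame in the long depletion schema: columns `run_id`,
#'   `species`, `chemical`, `cell_state`, `condition`, `replicate`,
#'   `time_h`, `concentration`.
#' @examples
#' d <- simulate_depletion(k_true = 0.5, seed = 1)
#' estimate_clint(d)
#' @export
simulate_depletion <- function(k_true = 0.5, c0 = 2, times = depletion_times(),
                               n_replicates = 3, noise_cv = 0.1,
                               dead_loss_rate = 0.01, seed = NULL,
                               run_id = "sim", species = "trout",
                               chemical = "MXC", cell_state = "fresh") {
  check_number(k_true, "k_true", 0)
  check_number(c0, "c0", 0, strict_min = TRUE)
  check_number(noise_cv, "noise_cv", 0)
  check_number(dead_loss_rate, "dead_loss_rate", 0)
  validate_timecourse(times, rep(1, length(times)))
  one_series <- function(rate, sub_seed) {
    mu <- c0 * exp(-rate * times)
    eps <- with_seed(sub_seed, rlnorm_mean1(length(times), noise_cv))
    mu * eps
  }
  out <- vector("list", n_replicates + 1L)
  for (r in seq_len(n_replicates)) {
    out[[r]] <- data.frame(
      run_id = run_id, species = species, chemical = chemical,
      cell_state = cell_state, condition = "live", replicate = r,
      time_h = times,
      concentration = one_series(k_true,
                                 if (is.null(seed)) NULL else substream_seed(seed, r)))
  }
  out[[n_replicates + 1L]] <- data.frame(
    run_id = run_id, species = species, chemical = chemical,
    cell_state = cell_state, condition = "inactivated", replicate = 1L,
    time_h = times,
    concentration = one_series(dead_loss_rate,
                               if (is.null(seed)) NULL else substream_seed(seed, 1000L)))
  do.call(rbind, out)
}

#' Default TG 305 sampling schedules
#'
#' Fish sampling on uptake days 0, 7, 14, 21, 28, 31, 35 and depuration
#' days 4, 10, 21, 35 (days since transfer to clean water).
#' @return List with `uptake` and `depuration` day vectors.
#' @export
tg305_schedule <- function() {
  list(uptake = c(0, 7, 14, 21, 28, 31, 35), depuration = c(4, 10, 21, 35))
}

#' Simulate a TG 305 aqueous-exposure study
#'
#' One-compartment kinetics: during uptake
#' `C_f(t) = (k1 * C_w / kT) * (1 - exp(-kT t))`; after transfer to clean
#' water `C_f(t') = C_f(T_up) * exp(-kT t')`.  Water samples scatter
#' lognormally around `water_mean` (CV `water_cv`); each sampled fish gets
#' independent lognormal measurement noise (`fish_noise_cv`) and an
#' exponentially growing weight.
#'
#' @param k1 Gill uptake rate constant (L/kg/d).
#' @param kT Overall depuration rate constant (1/d); the sum of its
#'   components `k2 + kE + kG + kB`.  Supply either `kT` directly or the
#'   components.
#' @param k2,kE,kG,kB Optional components (1/d); when given, `kT` is their
#'   sum.
#' @param water_mean True mean water concentration (ng/L).
#' @param water_cv CV of water-concentration variability (default 0.15).
#' @param uptake_days,depuration_days Phase lengths (d), default 35/35.
#' @param fish_days Fish sampling schedule, default [tg305_schedule()].
#' @param water_interval Water sampling interval (d, default 2: at least
#'   three samples per week).
#' @param fish_per_day Fish sampled per occasion (default 4).
#' @param fish_noise_cv Per-fish lognormal CV (default 0.15).
#' @param initial_weight_g,kg_weight Initial fish weight and specific
#'   growth rate of the weight trajectory (1/d).
#' @param seed Integer master seed.
#' @return List with `water` (columns `sample_date_day`, `phase`,
#'   `conc_ng_L`), `fish` (columns `day`, `phase`, `fish_id`, `conc_ng_kg`,
#'   `weight_g`; depuration `day` counts from transfer) and `truth` (the
#'   generating parameters, including the implied steady-state BCF).
#' @examples
#' sim <- simulate_tg305(k1 = 325, kT = 0.12, water_mean = 7, seed = 1)
#' fit_depuration(sim$fish)
#' @export
simulate_tg305 <- function(k1 = 325, kT = NULL, k2 = NULL, kE = NULL,
                           kG = NULL, kB = NULL, water_mean = 7,
                           water_cv = 0.15, uptake_days = 35,
                           depuration_days = 35, fish_days = tg305_schedule(),
                           water_interval = 2, fish_per_day = 4,
                           fish_noise_cv = 0.15, initial_weight_g = 30,
                           kg_weight = 0.005, seed = NULL) {
  comps <- c(k2 = k2 %||% NA, kE = kE %||% NA, kG = kG %||% NA, kB = kB %||% NA)
  if (is.null(kT)) {
    if (any(is.na(comps[c("k2", "kE", "kG")]))) {
      stop_invalid("supply kT or its components k2, kE, kG (and optionally kB)")
    }
    if (is.na(comps["kB"])) comps["kB"] <- 0
    kT <- sum(comps)
  }
  check_number(k1, "k1", 0)
  check_number(kT, "kT", 0)
  check_number(water_mean, "water_mean", 0, strict_min = TRUE)
  if (any(fish_days$uptake > uptake_days) ||
      any(fish_days$depuration > depuration_days)) {
    stop_invalid("sampling schedule exceeds phase lengths")
  }

  water_days <- sort(unique(c(seq(0, uptake_days, by = water_interval), uptake_days)))
  eps_w <- with_seed(if (is.null(seed)) NULL else substream_seed(seed, 1L),
                     rlnorm_mean1(length(water_days), water_cv))
  water <- data.frame(sample_date_day = water_days, phase = "uptake",
                      conc_ng_L = water_mean * eps_w)

  cf_uptake <- function(t) (k1 * water_mean / kT) * (1 - exp(-kT * t))
  cf_end <- cf_uptake(uptake_days)
  sample_fish <- function(day, phase, true_conc, abs_day, stream) {
    eps <- with_seed(if (is.null(seed)) NULL else substream_seed(seed, stream),
                     rlnorm_mean1(2 * fish_per_day, fish_noise_cv))
    data.frame(
      day = day, phase = phase, fish_id = seq_len(fish_per_day),
      conc_ng_kg = true_conc * eps[seq_len(fish_per_day)],
      weight_g = initial_weight_g * exp(kg_weight * abs_day) *
        eps[fish_per_day + seq_len(fish_per_day)])
  }
  fish <- list()
  for (i in seq_along(fish_days$uptake)) {
    d <- fish_days$uptake[i]
    fish[[length(fish) + 1L]] <-
      sample_fish(d, "uptake", cf_uptake(d), d, 100L + i)
  }
  for (i in seq_along(fish_days$depuration)) {
    d <- fish_days$depuration[i]
    fish[[length(fish) + 1L]] <-
      sample_fish(d, "depuration", cf_end * exp(-kT * d), uptake_days + d, 200L + i)
  }
  truth <- list(k1 = k1, kT = kT, k2 = unname(comps["k2"]),
                kE = unname(comps["kE"]), kG = unname(comps["kG"]),
                kB = unname(comps["kB"]), water_mean = water_mean,
                bcf_ss = k1 / kT, kg_weight = kg_weight)
  list(water = water, fish = do.call(rbind, fish), truth = truth)
}

#' Monte-Carlo recovery report for the estimators
#'
#' Repeatedly simulates depletion runs and/or TG 305 studies across a
#' scenario grid and summarizes the relative bias and RMSE of the
#' recovered parameters against ground truth.
#'
#' @param scenarios A data frame with one row per scenario.  For
#'   `type = "depletion"`: columns `k_true` and `noise_cv`.  For
#'   `type = "tg305"`: columns `k1`, `kT`, `fish_noise_cv` (optionally
#'   `fish_per_day`).
#' @param type `"depletion"` or `"tg305"`.
#' @param n_seeds Number of Monte-Carlo replicates per scenario (>= 10).
#' @param master_seed Master seed; replicate s of scenario i uses a
#'   deterministic substream of it.
#' @return Data frame with one row per scenario: the true value, median
#'   estimate, median relative bias, mean relative bias and relative RMSE.
#' @export
recovery_report <- function(scenarios, type = c("depletion", "tg305"),
                            n_seeds = 100, master_seed = 1) {
  type <- match.arg(type)
  if (nrow(scenarios) < 1L) stop_insufficient("need at least one scenario")
  if (n_seeds < 10L) stop_insufficient("need at least 10 seeds per scenario")
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, , drop = FALSE]
    est <- vapply(seq_len(n_seeds), function(s) {
      sd <- substream_seed(master_seed, i * 100000L + s)
      if (type == "depletion") {
        d <- simulate_depletion(k_true = sc$k_true, noise_cv = sc$noise_cv,
                                seed = sd)
        estimate_clint(d)$k_mean
      } else {
        sim <- simulate_tg305(k1 = sc$k1, kT = sc$kT,
                              fish_noise_cv = sc$fish_noise_cv,
                              fish_per_day = sc$fish_per_day %||% 4,
                              seed = sd)
        fit_depuration(sim$fish)$kT
      }
    }, numeric(1))
    truth <- if (type == "depletion") sc$k_true else sc$kT
    rel <- (est - truth) / truth
    data.frame(scenario = i, parameter = if (type == "depletion") "k" else "kT",
               truth = truth, median_estimate = stats::median(est),
               median_rel_bias = stats::median(rel), mean_rel_bias = mean(rel),
               rel_rmse = sqrt(mean(rel^2)), n_seeds = n_seeds)
  })
  do.call(rbind, rows)
}
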