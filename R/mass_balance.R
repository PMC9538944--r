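## Kinetic mass-balance BCF model.
##
## A one-compartment description of a fish in water: uptake across the
## gills (k1, L/kg/d) against first-order losses by respiratory
## elimination (k2), fecal egestion (kE), growth dilution (kG) and
## biotransformation (kB), all in 1/d.  At steady state
## BCF = k1 / (k2 + kE + kG + kB).

#' Dissolved oxygen concentration
#'
#' `C_OX = saturation * C_sat(T)` with the default solubility relation
#' `C_sat(T) = 468 / (31.6 + T)` mg/L.
#'
#' @param temperature Water temperature (degC), validated to 0-35.
#' @param saturation Fraction of saturation, in (0, 1.2].
#' @param suite A [rate_constant_suite()] (solubility coefficients).
#' @return Dissolved oxygen (mg/L).
#' @examples
#' dissolved_oxygen(21, 0.77)  # ~6.85 mg/L
#' @export
dissolved_oxygen <- function(temperature, saturation = 1,
                             suite = rate_constant_suite()) {
  if (temperature < 0 || temperature > 35) {
    stop_config("temperature outside the validated 0-35 degC range")
  }
  check_number(saturation, "saturation", 0, strict_min = TRUE)
  if (saturation > 1.2) stop_invalid("saturation must be <= 1.2")
  saturation * suite$cox_a / (suite$cox_b + temperature)
}

#' Gill uptake rate constant k1
#'
#' Gill uptake efficiency `E_W = 1 / (ew_a + ew_b / Kow)` combined with the
#' allometric ventilation rate `G_V = gv_coef * W^gv_exp / C_OX` (L/d)
#' gives `k1 = E_W * G_V / W` (L/kg/d).
#'
#' @param phys A [fish_physiology()] object or built-in set name.
#' @param chem A [chemical_props()] object or built-in chemical name.
#' @param suite A [rate_constant_suite()].
#' @return k1 (L/kg/d).
#' @examples
#' gill_uptake_k1("carp_study", "MXC")  # ~328 L/kg/d
#' @export
gill_uptake_k1 <- function(phys, chem, suite = rate_constant_suite()) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  kow <- 10^chem$log_kow
  e_w <- 1 / (suite$ew_a + suite$ew_b / kow)
  c_ox <- dissolved_oxygen(phys$temperature, phys$do_saturation, suite)
  if (c_ox <= 0) stop_config("dissolved oxygen must be > 0")
  g_v <- suite$gv_coef * phys$body_mass^suite$gv_exp / c_ox
  e_w * g_v / phys$body_mass
}

#' Fish-water partition coefficient
#'
#' Default lipid-only closure `K_FW = lipid_fraction * Kow`; an optional
#' non-lipid organic matter term (`nonlipid_fraction` in the suite, with
#' octanol proportionality 0.035) can be enabled.
#'
#' @inheritParams gill_uptake_k1
#' @return K_FW (L/kg).
#' @export
fish_water_partition <- function(phys, chem, suite = rate_constant_suite()) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  kow <- 10^chem$log_kow
  kfw <- (phys$lipid_fraction +
            suite$nonlipid_proportionality * suite$nonlipid_fraction) * kow
  if (kfw <= 0) stop_config("fish-water partition coefficient must be > 0")
  kfw
}

#' Respiratory elimination rate constant k2
#'
#' Thermodynamic consistency closure: `k2 = k1 / K_FW` so that the
#' no-loss steady state recovers equilibrium partitioning.
#'
#' @param k1 Gill uptake rate constant (L/kg/d).
#' @inheritParams gill_uptake_k1
#' @return k2 (1/d).
#' @examples
#' partition_k2(325, "carp_study", "MXC")  # ~0.0283 1/d
#' @export
partition_k2 <- function(k1, phys, chem, suite = rate_constant_suite()) {
  check_number(k1, "k1", 0)
  k1 / fish_water_partition(phys, chem, suite)
}

#' Fecal egestion rate constant kE
#'
#' `kE = egestion_factor * E_D * G_D / W` with feeding rate
#' `G_D = feed_a * W^feed_exp * exp(feed_temp * T)` (kg/d) and dietary
#' uptake efficiency `E_D = 1 / (ed_a * Kow + ed_b)`.
#'
#' @inheritParams gill_uptake_k1
#' @return kE (1/d).
#' @examples
#' egestion_kE("carp_study", "MXC")  # ~0.0076 1/d
#' @export
egestion_kE <- function(phys, chem, suite = rate_constant_suite()) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  kow <- 10^chem$log_kow
  g_d <- suite$feed_a * phys$body_mass^suite$feed_exp *
    exp(suite$feed_temp * phys$temperature)
  e_d <- 1 / (suite$ed_a * kow + suite$ed_b)
  suite$egestion_factor * e_d * g_d / phys$body_mass
}

#' Growth dilution rate constant kG
#'
#' `kG = c * W^growth_exp` with the cold-water coefficient (5e-4) for
#' salmonids and the warm-water coefficient (2.51e-3) for cyprinids; the
#' regime defaults to the one stored in the physiology set.
#'
#' @inheritParams gill_uptake_k1
#' @param regime `"cold"` or `"warm"`; default taken from `phys`.
#' @return kG (1/d).
#' @examples
#' growth_kG("trout_study")  # ~0.0011 1/d
#' @export
growth_kG <- function(phys, regime = NULL, suite = rate_constant_suite()) {
  phys <- as_physiology(phys)
  regime <- match.arg(regime %||% phys$growth_regime, c("cold", "warm"))
  coef <- if (regime == "cold") suite$growth_cold else suite$growth_warm
  coef * phys$body_mass^suite$growth_exp
}

#' Full rate-constant set for a species/chemical scenario
#'
#' @inheritParams gill_uptake_k1
#' @param kb Biotransformation rate constant to include (1/d, default 0).
#' @param kg_measured Optional measured growth rate (1/d) overriding the
#'   modeled kG (e.g. from [growth_rate()] on study fish weights).
#' @return An object of class `rate_constants`: list with `k1`, `k2`, `kE`,
#'   `kG`, `kB` plus scenario labels.
#' @examples
#' rate_constants("carp_study", "MXC")
#' @export
rate_constants <- function(phys, chem, suite = rate_constant_suite(),
                           kb = 0, kg_measured = NULL) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  check_number(kb, "kb", 0)
  k1 <- gill_uptake_k1(phys, chem, suite)
  k2 <- partition_k2(k1, phys, chem, suite)
  ke <- egestion_kE(phys, chem, suite)
  kg <- if (!is.null(kg_measured)) {
    check_number(kg_measured, "kg_measured", 0)
    kg_measured
  } else {
    growth_kG(phys, suite = suite)
  }
  structure(list(species = phys$species, chemical = chem$name,
                 k1 = k1, k2 = k2, kE = ke, kG = kg, kB = kb),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Rate constants: %s / %s\n", x$species, x$chemical))
  cat(sprintf("  k1 %.4g L/kg/d; k2 %.4g; kE %.4g; kG %.4g; kB %.4g 1/d\n",
              x$k1, x$k2, x$kE, x$kG, x$kB))
  invisible(x)
}

#' Predict the steady-state BCF from rate constants
#'
#' `BCF = k1 / (k2 + kE + kG + kB)` (L/kg wet weight).
#'
#' @param rates A [rate_constants()] object, or a named list with elements
#'   `k1`, `k2`, `kE`, `kG` and optionally `kB`.
#' @return An object of class `bcf_prediction`: list with `bcf` (L/kg),
#'   the rates used, and `with_biotransformation`.
#' @examples
#' predict_bcf(rate_constants("carp_study", "MXC"))
#' @export
predict_bcf <- function(rates) {
  kb <- rates$kB %||% 0
  denom <- rates$k2 + rates$kE + rates$kG + kb
  if (!is.finite(denom) || denom <= 0) {
    stop_invalid("total elimination (k2 + kE + kG + kB) must be > 0")
  }
  structure(list(bcf = rates$k1 / denom, rates = rates,
                 with_biotransformation = kb > 0),
            class = "bcf_prediction")
}

#' @export
print.bcf_prediction <- function(x, ...) {
  cat(sprintf("Predicted BCF = %.0f L/kg (%s biotransformation)\n", x$bcf,
              if (x$with_biotransformation) "with" else "without"))
  invisible(x)
}

#' Back-calculate in vivo kB from a measured depuration rate constant
#'
#' `kB = kT - (k2 + kE + kG)`.  A negative result means measured
#' depuration is not distinguishable from the sum of the non-metabolic
#' losses; it is returned unchanged with a flag, never truncated to zero.
#'
#' @param kT Overall depuration rate constant (1/d).
#' @param k2,kE,kG Non-metabolic elimination rate constants (1/d).
#' @return List with `kb` (1/d) and `distinguishable_from_zero` (logical).
#' @examples
#' kb_from_depuration(0.5, 0.05, 0.03, 0.02)
#' @export
kb_from_depuration <- function(kT, k2, kE, kG) {
  check_number(kT, "kT", 0)
  check_number(k2, "k2", 0)
  check_number(kE, "kE", 0)
  check_number(kG, "kG", 0)
  kb <- kT - (k2 + kE + kG)
  list(kb = kb, distinguishable_from_zero = kb > 0)
}

#' Uncertainty interval for an in vivo kB estimate
#'
#' Given a multiplicative uncertainty factor `uf` (the 95\% probability
#' factor of the back-calculation), the interval is `(kb / uf, kb * uf)`.
#'
#' @param kb Biotransformation rate constant (1/d), > 0.
#' @param uf Uncertainty factor, >= 1.
#' @return Numeric vector `c(lower, upper)` (1/d).
#' @examples
#' kb_uncertainty(0.40, 3)  # 0.133 - 1.2
#' @export
kb_uncertainty <- function(kb, uf) {
  check_number(kb, "kb", 0, strict_min = TRUE)
  if (!is.numeric(uf) || length(uf) != 1L || !is.finite(uf) || uf < 1) {
    stop_invalid("uncertainty factor must be a single number >= 1")
  }
  c(lower = kb / uf, upper = kb * uf)
}
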