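#' Fish physiology parameter set
#'
#' Bundles the whole-organism parameters used by the IVIVE chain and the
#' kinetic mass-balance model.  Masses are wet weights in kilograms;
#' fractions are unitless (g/g); hepatocellularity is in 10^6 cells per gram
#' of liver.
#'
#' Three named parameter sets are built in:
#' \describe{
#'   \item{`trout_reference`}{The conventional 10 g rainbow trout held at
#'     15 degrees C with 5\% whole-body lipid, the reference scenario of
#'     laboratory bioconcentration tests.}
#'   \item{`trout_study`}{An 18.5 g rainbow trout at 12 degrees C with
#'     9.08\% lipid and 91\% dissolved-oxygen saturation, matching the
#'     bundled trout exposure study.}
#'   \item{`carp_study`}{A 44.6 g common carp at 21 degrees C with 9.57\%
#'     lipid, 77\% oxygen saturation and a fractional liver weight of
#'     0.0174, matching the bundled carp exposure study.}
#' }
#'
#' @param species Name of a built-in set (`"trout_reference"`,
#'   `"trout_study"`, `"carp_study"`), or an arbitrary label when the
#'   remaining arguments are supplied explicitly.
#' @param body_mass Wet body mass (kg).
#' @param temperature Water/holding temperature (degrees C).
#' @param lipid_fraction Whole-body lipid content (g lipid / g fish).
#' @param liver_fraction Liver weight as a fraction of body weight
#'   (g liver / g fish); 0.015 for trout, 0.0174 for carp.
#' @param hepatocellularity Hepatocytes per gram liver (10^6 cells/g);
#'   default 510 for both species.
#' @param hepatic_flow_fraction Fraction of cardiac output perfusing the
#'   liver; default 0.259.
#' @param do_saturation Dissolved-oxygen saturation as a fraction of the
#'   temperature-dependent solubility.
#' @param growth_regime `"cold"` (salmonids) or `"warm"` (cyprinids);
#'   selects the growth-dilution coefficient.
#' @return An object of class `fish_physiology` (a named list).
#' @examples
#' fish_physiology("carp_study")
#' fish_physiology("my_trout", body_mass = 0.5, temperature = 12,
#'                 lipid_fraction = 0.05, liver_fraction = 0.015)
#' @export
fish_physiology <- function(species = "trout_reference",
                            body_mass = NULL,
                            temperature = NULL,
                            lipid_fraction = NULL,
                            liver_fraction = NULL,
                            hepatocellularity = 510,
                            hepatic_flow_fraction = 0.259,
                            do_saturation = NULL,
                            growth_regime = NULL) {
  builtin <- builtin_physiology()
  if (species %in% names(builtin)) {
    base <- builtin[[species]]
    body_mass <- body_mass %||% base$body_mass
    temperature <- temperature %||% base$temperature
    lipid_fraction <- lipid_fraction %||% base$lipid_fraction
    liver_fraction <- liver_fraction %||% base$liver_fraction
    do_saturation <- do_saturation %||% base$do_saturation
    growth_regime <- growth_regime %||% base$growth_regime
  }
  if (is.null(body_mass) || is.null(temperature) || is.null(lipid_fraction) ||
      is.null(liver_fraction)) {
    stop_config(sprintf(
      "unknown parameter set '%s': supply body_mass, temperature, lipid_fraction and liver_fraction",
      species))
  }
  do_saturation <- do_saturation %||% 0.9
  growth_regime <- growth_regime %||% "cold"
  check_number(body_mass, "body_mass", 0, strict_min = TRUE)
  check_number(temperature, "temperature")
  check_number(lipid_fraction, "lipid_fraction", 0, strict_min = TRUE)
  check_number(liver_fraction, "liver_fraction", 0, strict_min = TRUE)
  check_number(hepatocellularity, "hepatocellularity", 0, strict_min = TRUE)
  check_number(hepatic_flow_fraction, "hepatic_flow_fraction", 0, strict_min = TRUE)
  check_number(do_saturation, "do_saturation", 0, strict_min = TRUE)
  if (lipid_fraction > 1 || liver_fraction > 1 || hepatic_flow_fraction > 1) {
    stop_config("fractions must lie in (0, 1]")
  }
  growth_regime <- match.arg(growth_regime, c("cold", "warm"))
  structure(list(
    species = species,
    body_mass = body_mass,
    temperature = temperature,
    lipid_fraction = lipid_fraction,
    liver_fraction = liver_fraction,
    hepatocellularity = hepatocellularity,
    hepatic_flow_fraction = hepatic_flow_fraction,
    do_saturation = do_saturation,
    growth_regime = growth_regime
  ), class = "fish_physiology")
}

builtin_physiology <- function() {
  list(
    trout_reference = list(body_mass = 0.010, temperature = 15,
                           lipid_fraction = 0.05, liver_fraction = 0.015,
                           do_saturation = 0.90, growth_regime = "cold"),
    trout_study = list(body_mass = 0.0185, temperature = 12,
                       lipid_fraction = 0.0908, liver_fraction = 0.015,
                       do_saturation = 0.91, growth_regime = "cold"),
    carp_study = list(body_mass = 0.0446, temperature = 21,
                      lipid_fraction = 0.0957, liver_fraction = 0.0174,
                      do_saturation = 0.77, growth_regime = "warm")
  )
}

#' @export
print.fish_physiology <- function(x, ...) {
  cat(sprintf("Fish physiology: %s\n", x$species))
  cat(sprintf("  body mass      %.4g kg\n", x$body_mass))
  cat(sprintf("  temperature    %.3g degC\n", x$temperature))
  cat(sprintf("  lipid fraction %.4g\n", x$lipid_fraction))
  cat(sprintf("  liver fraction %.4g\n", x$liver_fraction))
  cat(sprintf("  hepatocellularity %.4g x10^6 cells/g liver\n", x$hepatocellularity))
  cat(sprintf("  hepatic flow fraction %.3g; DO saturation %.3g; growth regime %s\n",
              x$hepatic_flow_fraction, x$do_saturation, x$growth_regime))
  invisible(x)
}

#' Chemical property set
#'
#' The only required descriptor is the octanol-water partition coefficient
#' (log10), which drives gill uptake efficiency, fish-water partitioning,
#' blood-water partitioning and the binding correction.  Two built-ins are
#' provided: `"MXC"` (methoxychlor, log Kow 5.08) and `"BaP"`
#' (benzo[a]pyrene, log Kow 5.99).
#'
#' @param name Chemical name or one of the built-ins.
#' @param log_kow log10 octanol-water partition coefficient.
#' @return An object of class `chemical_props`.
#' @examples
#' chemical_props("MXC")
#' chemical_props("pyrene", log_kow = 4.88)
#' @export
chemical_props <- function(name, log_kow = NULL) {
  builtin <- list(MXC = 5.08, BaP = 5.99)
  if (is.null(log_kow)) {
    if (!name %in% names(builtin)) {
      stop_config(sprintf("unknown chemical '%s': supply log_kow", name))
    }
    log_kow <- builtin[[name]]
  }
  check_number(log_kow, "log_kow")
  structure(list(name = name, log_kow = log_kow), class = "chemical_props")
}

#' @export
print.chemical_props <- function(x, ...) {
  cat(sprintf("Chemical: %s (log Kow %.3g)\n", x$name, x$log_kow))
  invisible(x)
}

#' Binding model for the in vitro / in vivo fraction-unbound correction
#'
#' The fraction unbound used in the well-stirred liver model corrects for
#' differential chemical binding between the hepatocyte incubation and
#' blood: `fu = fu_blood / fu_incubation`.  In `"qsar"` mode both terms are
#' hydrophobicity regressions:
#' \deqn{fu_{blood} = 1 / P_{BW}, \quad P_{BW} = a_{bw} 10^{b_{bw} \log K_{OW}} + c_{bw}}
#' \deqn{fu_{inc} = 1 / (1 + a_{inc} VR\, 10^{q_2 \log K_{OW}^2 + q_1 \log K_{OW} + q_0})}
#' where `VR` is the cell volume per volume of incubation (0.005 at the
#' nominal 2 x 10^6 cells/mL).  In `"unity"` mode `fu = 1`.
#' All coefficients are configurable so alternative binding QSARs can be
#' swapped in without code changes.
#'
#' @param mode `"qsar"` or `"unity"`.
#' @param vr Cell volume ratio of the incubation (mL cells / mL incubation).
#' @param pbw_a,pbw_b,pbw_c Blood-water partition coefficients.
#' @param inc_a,inc_q2,inc_q1,inc_q0 Incubation-binding coefficients.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(mode = c("qsar", "unity"), vr = 0.005,
                          pbw_a = 0.16, pbw_b = 0.73, pbw_c = 0.84,
                          inc_a = 125, inc_q2 = 0.072, inc_q1 = 0.067,
                          inc_q0 = -1.126) {
  mode <- match.arg(mode)
  check_number(vr, "vr", 0, strict_min = TRUE)
  structure(list(mode = mode, vr = vr,
                 pbw_a = pbw_a, pbw_b = pbw_b, pbw_c = pbw_c,
                 inc_a = inc_a, inc_q2 = inc_q2, inc_q1 = inc_q1,
                 inc_q0 = inc_q0),
            class = "binding_model")
}

#' Kinetic rate-constant suite for the mass-balance BCF model
#'
#' Named coefficients of the default allometric/thermodynamic correlations
#' used to compute the gill uptake rate constant (k1), respiratory
#' elimination (k2), fecal egestion (kE) and growth dilution (kG).  Every
#' coefficient is configurable; the defaults form one internally consistent
#' suite used for both forward BCF prediction and in vivo kB
#' back-calculation.
#'
#' @param ew_a,ew_b Gill uptake efficiency: `E_W = 1 / (ew_a + ew_b / Kow)`.
#' @param gv_coef,gv_exp Ventilation: `G_V = gv_coef * W^gv_exp / C_OX`
#'   (W in kg, C_OX in mg/L, G_V in L/d).
#' @param cox_a,cox_b Oxygen solubility: `C_sat(T) = cox_a / (cox_b + T)` mg/L.
#' @param feed_a,feed_exp,feed_temp Feeding rate:
#'   `G_D = feed_a * W^feed_exp * exp(feed_temp * T)` (kg/d).
#' @param egestion_factor Fecal egestion scaling (default 0.125).
#' @param ed_a,ed_b Dietary uptake efficiency: `E_D = 1 / (ed_a * Kow + ed_b)`.
#' @param growth_cold,growth_warm,growth_exp Growth dilution:
#'   `kG = c * W^growth_exp` with the cold-water coefficient for salmonids
#'   and the warm-water coefficient for cyprinids.
#' @param nonlipid_fraction Optional non-lipid organic matter term in the
#'   fish-water partition coefficient (`K_FW = (lipid + 0.035 *
#'   nonlipid_fraction_of_dry_matter) * Kow` when enabled); default 0
#'   (lipid-only partitioning).
#' @param nonlipid_proportionality Partitioning proportionality of non-lipid
#'   organic matter relative to octanol (default 0.035).
#' @return An object of class `rate_constant_suite`.
#' @export
rate_constant_suite <- function(ew_a = 1.85, ew_b = 155,
                                gv_coef = 1400, gv_exp = 0.65,
                                cox_a = 468, cox_b = 31.6,
                                feed_a = 0.022, feed_exp = 0.85,
                                feed_temp = 0.06,
                                egestion_factor = 0.125,
                                ed_a = 3e-07, ed_b = 2,
                                growth_cold = 5e-04, growth_warm = 2.51e-03,
                                growth_exp = -0.2,
                                nonlipid_fraction = 0,
                                nonlipid_proportionality = 0.035) {
  vals <- list(ew_a = ew_a, ew_b = ew_b, gv_coef = gv_coef, gv_exp = gv_exp,
               cox_a = cox_a, cox_b = cox_b, feed_a = feed_a,
               feed_exp = feed_exp, feed_temp = feed_temp,
               egestion_factor = egestion_factor, ed_a = ed_a, ed_b = ed_b,
               growth_cold = growth_cold, growth_warm = growth_warm,
               growth_exp = growth_exp,
               nonlipid_fraction = nonlipid_fraction,
               nonlipid_proportionality = nonlipid_proportionality)
  pos <- setdiff(names(vals), c("growth_exp", "nonlipid_fraction"))
  for (nm in pos) check_number(vals[[nm]], nm, 0, strict_min = TRUE)
  check_number(vals$growth_exp, "growth_exp")
  check_number(vals$nonlipid_fraction, "nonlipid_fraction", 0)
  structure(vals, class = "rate_constant_suite")
}

#' Read species and chemical parameter sets from a YAML file
#'
#' The file holds `species:` blocks (fields of [fish_physiology()]) and
#' `chemicals:` blocks (fields of [chemical_props()]); see
#' `system.file("extdata", "parameter_sets.yaml", package = "fishbcf")` for
#' the bundled defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `species` (named list of `fish_physiology`)
#'   and `chemicals` (named list of `chemical_props`).
#' @export
read_parameter_sets <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  species <- lapply(names(raw$species %||% list()), function(nm) {
    do.call(fish_physiology, c(list(species = nm), raw$species[[nm]]))
  })
  names(species) <- names(raw$species %||% list())
  chemicals <- lapply(names(raw$chemicals %||% list()), function(nm) {
    do.call(chemical_props, c(list(name = nm), raw$chemicals[[nm]]))
  })
  names(chemicals) <- names(raw$chemicals %||% list())
  list(species = species, chemicals = chemicals)
}

as_physiology <- function(x) {
  if (inherits(x, "fish_physiology")) return(x)
  if (is.character(x) && length(x) == 1L) return(fish_physiology(x))
  stop_config("expected a fish_physiology object or a built-in set name")
}

as_chemical <- function(x) {
  if (inherits(x, "chemical_props")) return(x)
  if (is.character(x) && length(x) == 1L) return(chemical_props(x))
  stop_config("expected a chemical_props object or a built-in chemical name")
}
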