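## In vitro - in vivo extrapolation (IVIVE) of hepatocyte clearance to a
## whole-body biotransformation rate constant kB.
##
## Chain: CL_in vitro,int (mL/h/10^6 cells)
##   -> whole-liver in vivo intrinsic clearance (L/d/kg fish), via
##      hepatocellularity and fractional liver weight
##   -> hepatic clearance CL_H (L/d/kg), via the well-stirred liver model
##      with a binding correction fu and hepatic blood flow Q_H
##   -> kB = CL_H / V_D, with V_D the apparent volume of distribution
##      referenced to blood.

#' Scale in vitro intrinsic clearance to whole-liver in vivo clearance
#'
#' `CL_in vivo,int = CL_in vitro,int x hepatocellularity x liver_fraction x 24`.
#' Units: mL/h/10^6 cells x 10^6 cells/g liver = mL/h/g liver; times the
#' liver fraction (g liver/g fish) gives mL/h/g fish = L/h/kg fish; times
#' 24 gives L/d/kg fish.
#'
#' @param clint In vitro intrinsic clearance (mL/h/10^6 cells).
#' @param phys A [fish_physiology()] object (uses `hepatocellularity`,
#'   `liver_fraction`).
#' @return Whole-body in vivo intrinsic clearance (L/d/kg fish).
#' @examples
#' scale_to_whole_liver(0.250, fish_physiology("trout_study"))  # 45.9
#' @export
scale_to_whole_liver <- function(clint, phys) {
  phys <- as_physiology(phys)
  check_number(clint, "clint", 0)
  clint * phys$hepatocellularity * phys$liver_fraction * 24
}

blood_water_partition <- function(log_kow, binding) {
  binding$pbw_a * 10^(binding$pbw_b * log_kow) + binding$pbw_c
}

#' Fraction unbound correction for the well-stirred liver model
#'
#' @param chem A [chemical_props()] object or built-in chemical name.
#' @param binding A [binding_model()]; `mode = "unity"` returns 1.
#' @return Unitless fu (> 0); a warning is emitted when fu > 1, which can
#'   occur for unusual coefficient choices and is deliberately not clamped.
#' @examples
#' fraction_unbound("MXC", binding_model())   # about 0.010
#' fraction_unbound("MXC", binding_model("unity"))
#' @export
fraction_unbound <- function(chem, binding = binding_model()) {
  chem <- as_chemical(chem)
  if (binding$mode == "unity") return(1)
  fu_blood <- 1 / blood_water_partition(chem$log_kow, binding)
  log_kow <- chem$log_kow
  fu_inc <- 1 / (1 + binding$inc_a * binding$vr *
                   10^(binding$inc_q2 * log_kow^2 + binding$inc_q1 * log_kow +
                         binding$inc_q0))
  fu <- fu_blood / fu_inc
  if (fu > 1) warning("computed fraction unbound exceeds 1; check binding coefficients")
  fu
}

#' Hepatic blood flow
#'
#' Cardiac output `Q_C (L/h/kg) = (qc_a * T - qc_b) * (W_g / 500)^mass_exp`
#' with defaults `qc_a = 0.23`, `qc_b = 0.78`, `mass_exp = -0.1`, scaled by
#' the fraction of cardiac output perfusing the liver and converted to
#' L/d/kg.
#'
#' @param phys A [fish_physiology()] object.
#' @param qc_a,qc_b,mass_ref_g,mass_exp Cardiac-output coefficients.
#' @return Hepatic blood flow Q_H (L/d/kg fish).
#' @examples
#' hepatic_blood_flow(fish_physiology("x", body_mass = 0.5, temperature = 12,
#'                    lipid_fraction = 0.05, liver_fraction = 0.015))  # ~12.3
#' @export
hepatic_blood_flow <- function(phys, qc_a = 0.23, qc_b = 0.78,
                               mass_ref_g = 500, mass_exp = -0.1) {
  phys <- as_physiology(phys)
  if (phys$temperature < 0 || phys$temperature > 35) {
    stop_config("temperature outside the validated 0-35 degC range")
  }
  qc <- (qc_a * phys$temperature - qc_b) *
    (phys$body_mass * 1000 / mass_ref_g)^mass_exp
  if (qc <= 0) {
    stop_config("cardiac-output relation is non-positive at this temperature")
  }
  phys$hepatic_flow_fraction * qc * 24
}

#' Well-stirred liver model
#'
#' `CL_H = Q_H * fu * CL_int / (Q_H + fu * CL_int)`: hepatic clearance is
#' intrinsic-clearance-limited when binding-corrected intrinsic clearance
#' is small and saturates at liver blood flow when it is large.
#'
#' @param cl_in_vivo_int Whole-body in vivo intrinsic clearance (L/d/kg).
#' @param fu Fraction unbound (unitless).
#' @param q_h Hepatic blood flow (L/d/kg).
#' @return Hepatic clearance CL_H (L/d/kg).
#' @examples
#' well_stirred_clearance(62.3, 0.01, 20)
#' @export
well_stirred_clearance <- function(cl_in_vivo_int, fu, q_h) {
  check_number(cl_in_vivo_int, "cl_in_vivo_int", 0)
  check_number(fu, "fu", 0)
  check_number(q_h, "q_h", 0, strict_min = TRUE)
  num <- q_h * fu * cl_in_vivo_int
  if (num == 0) return(0)
  num / (q_h + fu * cl_in_vivo_int)
}

#' Apparent volume of distribution referenced to blood
#'
#' `V_D = lipid_fraction * Kow / P_BW` (L/kg), treating whole-body storage
#' as lipid-dominated octanol-like partitioning and referencing it to blood
#' through the blood-water partition coefficient.
#'
#' @inheritParams fraction_unbound
#' @param phys A [fish_physiology()] object.
#' @return V_D (L/kg).
#' @export
volume_of_distribution <- function(phys, chem, binding = binding_model()) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  p_bw <- blood_water_partition(chem$log_kow, binding)
  vd <- phys$lipid_fraction * 10^chem$log_kow / p_bw
  if (!is.finite(vd) || vd <= 0) stop_config("volume of distribution must be > 0")
  vd
}

#' Whole-body biotransformation rate constant from hepatic clearance
#'
#' `kB = CL_H / V_D` (1/d).
#'
#' @param cl_h Hepatic clearance (L/d/kg).
#' @param phys A [fish_physiology()] object.
#' @param chem A [chemical_props()] object.
#' @param binding A [binding_model()] (used for the blood referencing of
#'   V_D).
#' @return kB (1/d).
#' @export
kb_from_clearance <- function(cl_h, phys, chem, binding = binding_model()) {
  check_number(cl_h, "cl_h", 0)
  cl_h / volume_of_distribution(phys, chem, binding)
}

#' Full IVIVE chain: in vitro intrinsic clearance to kB
#'
#' Runs liver scaling, binding correction, hepatic blood flow, the
#' well-stirred liver model and the volume-of-distribution referencing in
#' one call, returning every intermediate for audit.
#'
#' @param clint In vitro intrinsic clearance (mL/h/10^6 cells).
#' @param phys A [fish_physiology()] object or built-in set name.
#' @param chem A [chemical_props()] object or built-in chemical name.
#' @param binding A [binding_model()]; use
#'   `binding_model("unity")` for the fu = 1 variant.
#' @param ... Passed to [hepatic_blood_flow()].
#' @return An object of class `kb_estimate`: list with `cl_in_vivo_int`,
#'   `fu`, `q_h`, `cl_h`, `v_d`, `kb` plus the resolved inputs.
#' @examples
#' ivive_kb(0.287, "carp_study", "MXC")
#' @export
ivive_kb <- function(clint, phys, chem, binding = binding_model(), ...) {
  phys <- as_physiology(phys)
  chem <- as_chemical(chem)
  cl_int <- scale_to_whole_liver(clint, phys)
  fu <- fraction_unbound(chem, binding)
  q_h <- hepatic_blood_flow(phys, ...)
  cl_h <- well_stirred_clearance(cl_int, fu, q_h)
  v_d <- volume_of_distribution(phys, chem, binding)
  structure(list(
    clint = clint,
    species = phys$species,
    chemical = chem$name,
    fu_mode = binding$mode,
    cl_in_vivo_int = cl_int,
    fu = fu,
    q_h = q_h,
    cl_h = cl_h,
    v_d = v_d,
    kb = cl_h / v_d
  ), class = "kb_estimate")
}

#' @export
print.kb_estimate <- function(x, ...) {
  cat(sprintf("IVIVE kB estimate: %s / %s (fu mode %s)\n",
              x$species, x$chemical, x$fu_mode))
  cat(sprintf("  CL_in vitro,int  %.4g mL/h/10^6 cells\n", x$clint))
  cat(sprintf("  CL_in vivo,int   %.4g L/d/kg\n", x$cl_in_vivo_int))
  cat(sprintf("  fu               %.4g\n", x$fu))
  cat(sprintf("  Q_H              %.4g L/d/kg\n", x$q_h))
  cat(sprintf("  CL_H             %.4g L/d/kg\n", x$cl_h))
  cat(sprintf("  V_D              %.4g L/kg\n", x$v_d))
  cat(sprintf("  kB               %.4g 1/d\n", x$kb))
  invisible(x)
}
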