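## CSV readers/writers and the end-to-end pipeline.
##
## All unit conversions happen once, at the reader boundary: minutes to
## hours for in vitro sampling times, grams to kilograms for body masses.
## Everything downstream works in hours (in vitro), days (in vivo), kg,
## L/d/kg and 1/d.

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s: missing required column(s): %s", basename(path),
                        paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad) > 0L) {
        stop_schema(sprintf("%s: non-numeric value in column '%s' at data row %d",
                            basename(path), col, bad[1]))
      }
      df[[col]] <- as.numeric(v)
    }
  }
  df
}

#' Read an in vitro depletion CSV
#'
#' Schema (strict): `run_id`, `species`, `chemical`, `cell_state`,
#' `condition`, `replicate`, `time_min`, `concentration`.  Sampling times
#' are converted from minutes to hours into a `time_h` column; duplicate
#' (run, condition, replicate, time) keys are rejected.
#'
#' @param path Path to a UTF-8 CSV with '.' decimal separator.
#' @return Data frame in the long depletion schema used by
#'   [estimate_clint()].
#' @export
read_depletion_csv <- function(path) {
  req <- c("run_id", "species", "chemical", "cell_state", "condition",
           "replicate", "time_min", "concentration")
  df <- read_checked_csv(path, req, c("replicate", "time_min", "concentration"))
  key <- paste(df$run_id, df$condition, df$replicate, df$time_min)
  if (anyDuplicated(key)) {
    stop_schema(sprintf("%s: duplicate (run, condition, replicate, time) key at data row %d",
                        basename(path), which(duplicated(key))[1]))
  }
  df$time_h <- df$time_min / 60
  df
}

#' Write an in vitro depletion CSV
#'
#' Inverse of [read_depletion_csv()]; accepts data with a `time_h` column
#' (e.g. from [simulate_depletion()]) and writes times in minutes.
#' @param data Long-format depletion data.
#' @param path Output path.
#' @export
write_depletion_csv <- function(data, path) {
  out <- data
  if (!"time_min" %in% names(out)) out$time_min <- out$time_h * 60
  cols <- c("run_id", "species", "chemical", "cell_state", "condition",
            "replicate", "time_min", "concentration")
  out <- out[, cols]
  # 17 significant digits so finite doubles round-trip bit-exactly
  out$time_min <- sprintf("%.17g", out$time_min)
  out$concentration <- sprintf("%.17g", out$concentration)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TG 305 water-concentration CSV
#'
#' Schema (strict): `sample_date_day`, `phase`, `conc_ng_L`.
#' @param path Path to a UTF-8 CSV.
#' @return Data frame usable by [twa_concentration()] / [tg305_analyze()].
#' @export
read_water_csv <- function(path) {
  read_checked_csv(path, c("sample_date_day", "phase", "conc_ng_L"),
                   c("sample_date_day", "conc_ng_L"))
}

#' Read a TG 305 fish CSV
#'
#' Schema (strict): `day`, `phase`, `fish_id`, `conc_ng_kg`, `weight_g`.
#' Depuration-phase `day` counts from transfer to clean water.
#' @param path Path to a UTF-8 CSV.
#' @return Data frame usable by [tg305_analyze()].
#' @export
read_fish_csv <- function(path) {
  read_checked_csv(path, c("day", "phase", "fish_id", "conc_ng_kg", "weight_g"),
                   c("day", "conc_ng_kg", "weight_g"))
}

#' Run the in vitro to BCF pipeline
#'
#' Executes the full chain for one species/chemical scenario: intrinsic
#' clearance (given directly or estimated from a depletion CSV), IVIVE to
#' kB, mass-balance rate constants, and BCF with and without
#' biotransformation.  The report embeds every intermediate quantity with
#' units plus the resolved parameter set, and is deterministic for a given
#' configuration.
#'
#' @param species A [fish_physiology()] object or built-in set name.
#' @param chemical A [chemical_props()] object or built-in chemical name.
#' @param clint In vitro intrinsic clearance (mL/h/10^6 cells); omit when
#'   `depletion_csv` is given.
#' @param depletion_csv Optional path to a depletion CSV; the run(s) are
#'   fitted with [estimate_clint()] and the mean clint used.
#' @param fu_mode `"qsar"` or `"unity"`.
#' @param suite A [rate_constant_suite()].
#' @param select_window,cell_density Passed to [estimate_clint()].
#' @param out Optional path; the report is written there as JSON.
#' @return An object of class `fishbcf_report` (a nested list).
#' @examples
#' run_pipeline("carp_study", "MXC", clint = 0.287)
#' @export
run_pipeline <- function(species, chemical, clint = NULL,
                         depletion_csv = NULL, fu_mode = c("qsar", "unity"),
                         suite = rate_constant_suite(),
                         select_window = FALSE, cell_density = 2e6,
                         out = NULL) {
  fu_mode <- match.arg(fu_mode)
  phys <- as_physiology(species)
  chem <- as_chemical(chemical)
  clint_runs <- NULL
  if (is.null(clint)) {
    if (is.null(depletion_csv)) {
      stop_config("supply either `clint` or `depletion_csv`")
    }
    df <- read_depletion_csv(depletion_csv)
    runs <- lapply(split(df, df$run_id), estimate_clint,
                   cell_density = cell_density, select_window = select_window)
    clint_runs <- summarize_runs(vapply(runs, function(r) r$clint, numeric(1)))
    clint <- clint_runs$mean_clint
  }
  kb_est <- ivive_kb(clint, phys, chem, binding = binding_model(fu_mode))
  rates0 <- rate_constants(phys, chem, suite, kb = 0)
  rates_kb <- rate_constants(phys, chem, suite, kb = kb_est$kb)
  report <- structure(list(
    package_version = as.character(utils::packageVersion("fishbcf")),
    scenario = list(species = phys$species, chemical = chem$name,
                    fu_mode = fu_mode),
    parameters = list(physiology = unclass(phys),
                      chemical = unclass(chem),
                      rate_suite = unclass(suite)),
    clint_summary = clint_runs,
    ivive = list(
      clint_mL_h_1e6cells = clint,
      cl_in_vivo_int_L_d_kg = kb_est$cl_in_vivo_int,
      fu = kb_est$fu,
      q_h_L_d_kg = kb_est$q_h,
      cl_h_L_d_kg = kb_est$cl_h,
      v_d_L_kg = kb_est$v_d,
      kb_per_d = kb_est$kb),
    rate_constants_per_d = list(k1_L_kg_d = rates0$k1, k2 = rates0$k2,
                                kE = rates0$kE, kG = rates0$kG,
                                kB = kb_est$kb),
    bcf = list(without_biotransformation_L_kg = predict_bcf(rates0)$bcf,
               with_biotransformation_L_kg = predict_bcf(rates_kb)$bcf)
  ), class = "fishbcf_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.fishbcf_report <- function(x, ...) {
  cat(sprintf("fishbcf pipeline report (%s / %s, fu mode %s)\n",
              x$scenario$species, x$scenario$chemical, x$scenario$fu_mode))
  cat(sprintf("  CL_in vitro,int %.4g mL/h/10^6 cells -> kB %.4g 1/d\n",
              x$ivive$clint_mL_h_1e6cells, x$ivive$kb_per_d))
  cat(sprintf("  BCF without kB: %.0f L/kg; with kB: %.0f L/kg\n",
              x$bcf$without_biotransformation_L_kg,
              x$bcf$with_biotransformation_L_kg))
  invisible(x)
}
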