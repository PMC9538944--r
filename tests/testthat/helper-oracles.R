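# Independent oracle arithmetic used to freeze expected values.
# Each oracle evaluates the stated correlation directly, step by step,
# without calling the package's composed functions.

oracle_k1 <- function(mass_kg, temp, sat, log_kow) {
  kow <- 10^log_kow
  e_w <- 1 / (1.85 + 155 / kow)
  c_ox <- sat * 468 / (31.6 + temp)
  g_v <- 1400 * mass_kg^0.65 / c_ox
  e_w * g_v / mass_kg
}

oracle_kE <- function(mass_kg, temp, log_kow) {
  kow <- 10^log_kow
  g_d <- 0.022 * mass_kg^0.85 * exp(0.06 * temp)
  e_d <- 1 / (3e-07 * kow + 2)
  0.125 * e_d * g_d / mass_kg
}

oracle_fu <- function(log_kow, vr = 0.005) {
  p_bw <- 0.16 * 10^(0.73 * log_kow) + 0.84
  fu_inc <- 1 / (1 + 125 * vr *
                   10^(0.072 * log_kow^2 + 0.067 * log_kow - 1.126))
  (1 / p_bw) / fu_inc
}

# Dense-grid numeric TWA oracle for a piecewise-linear water series.
oracle_twa_dense <- function(days, conc, n = 200001) {
  grid <- seq(min(days), max(days), length.out = n)
  vals <- stats::approx(days, conc, xout = grid)$y
  mean(vals[-1] + vals[-n]) / 2 * (grid[2] - grid[1]) * (n - 1) /
    (max(days) - min(days))
}

# Study-condition fixtures used across tests.
study_cases <- function() {
  expand.grid(species = c("carp_study", "trout_study"),
              chemical = c("MXC", "BaP"),
              stringsAsFactors = FALSE)
}
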