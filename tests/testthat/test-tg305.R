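test_that("TWA water concentration is the trapezoidal mean", {
  expect_equal(twa_concentration(c(0, 10, 35), c(5, 5, 5)), 5)
  # step sampling: 4 ng/L over the first week, 8 over the second
  expect_equal(twa_concentration(c(0, 7, 7, 14), c(4, 4, 8, 8)), 6)
  expect_equal(twa_concentration(3, 7.5), 7.5)
  expect_equal(twa_concentration(c(0, 7, 14), c(4, 4, 8), window = c(0, 7)), 4)
  expect_error(twa_concentration(c(0, 7), c(4, 4), window = c(20, 30)),
               class = "fishbcf_insufficient_data")
  expect_error(twa_concentration(c(7, 0), c(4, 4)),
               class = "fishbcf_invalid_input")
})

test_that("TWA is invariant under refinement of a piecewise-linear grid", {
  days <- c(0, 3, 7.5, 14, 20, 28, 35)
  conc <- c(6.2, 7.9, 5.1, 6.6, 8.4, 5.9, 7.2)
  twa <- twa_concentration(days, conc)
  # refine: insert the midpoint of every interval (linear interpolation)
  mid <- (days[-1] + days[-length(days)]) / 2
  refined_days <- sort(c(days, mid))
  refined_conc <- stats::approx(days, conc, xout = refined_days)$y
  expect_equal(twa_concentration(refined_days, refined_conc), twa,
               tolerance = 1e-12)
  expect_equal(oracle_twa_dense(days, conc), twa, tolerance = 1e-8)
})

test_that("steady-state BCF divides plateau fish means by TWA", {
  fish <- data.frame(day = rep(c(28, 31, 35), each = 2), phase = "uptake",
                     fish_id = rep(1:2, 3),
                     conc_ng_kg = c(138, 142, 140, 140, 139, 141),
                     weight_g = 30)
  res <- steady_state_bcf(fish, twa = 1, plateau_days = c(28, 31, 35))
  expect_equal(res$bcf_ss, 140)
  expect_equal(res$cf_ss_mean, 140)
  # identical fish and constant water give exactly c/w
  const <- data.frame(day = c(28, 31, 35), phase = "uptake", fish_id = 1,
                      conc_ng_kg = 70, weight_g = 30)
  expect_equal(steady_state_bcf(const, twa = 7,
                                plateau_days = c(28, 31, 35))$bcf_ss, 10)
  expect_error(steady_state_bcf(const, twa = 0, plateau_days = 35),
               class = "fishbcf_invalid_input")
})

test_that("a noiseless synthetic study returns its true BCF", {
  sim <- simulate_tg305(k1 = 300, kT = 0.3, water_mean = 5, water_cv = 0,
                        fish_noise_cv = 0, seed = 1)
  twa <- twa_concentration(sim$water$sample_date_day, sim$water$conc_ng_L)
  expect_equal(twa, 5, tolerance = 1e-12)
  res <- steady_state_bcf(sim$fish, twa, plateau_days = c(28, 31, 35))
  expect_equal(res$bcf_ss, 1000, tolerance = 1e-3)  # k1/kT, plateau reached
})

test_that("depuration fits are exact on noiseless exponentials", {
  days <- c(4, 10, 21, 35)
  fish <- data.frame(day = rep(days, each = 4), phase = "depuration",
                     fish_id = rep(1:4, 4),
                     conc_ng_kg = rep(1000 * exp(-0.1 * days), each = 4),
                     weight_g = 30)
  fit <- fit_depuration(fish)
  expect_equal(fit$kT, 0.1, tolerance = 1e-10)
  expect_equal(fit$cf0, 1000, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # unit invariance: ng/kg vs ug/kg changes cf0 but not kT
  fish2 <- fish
  fish2$conc_ng_kg <- fish2$conc_ng_kg / 1000
  expect_equal(fit_depuration(fish2)$kT, fit$kT, tolerance = 1e-12)
  # no depuration: zero slope
  flat <- fish
  flat$conc_ng_kg <- 500
  expect_equal(fit_depuration(flat)$kT, 0)
  expect_error(fit_depuration(fish[fish$day < 10, ]),
               class = "fishbcf_insufficient_data")
  # non-positive concentrations are excluded with a warning
  mixed <- fish
  mixed$conc_ng_kg[1] <- 0
  expect_warning(fit_depuration(mixed), "non-positive")
})

test_that("growth rate is the log-linear slope of weights", {
  fish <- data.frame(day = c(0, 35), weight_g = c(20, 40))
  expect_equal(growth_rate(fish), log(2) / 35)
  expect_equal(growth_rate(data.frame(day = c(0, 10, 35), weight_g = 25)), 0)
  expect_error(growth_rate(data.frame(day = 0, weight_g = 20)),
               class = "fishbcf_insufficient_data")
})

test_that("plateau detection keeps trailing days without a trend", {
  sim <- simulate_tg305(k1 = 300, kT = 0.3, water_mean = 5, water_cv = 0,
                        fish_noise_cv = 0.05, seed = 42)
  up <- sim$fish[sim$fish$phase == "uptake", ]
  plateau <- detect_plateau(up)
  expect_gte(length(plateau), 3)
  expect_true(all(plateau %in% c(14, 21, 28, 31, 35)))
  expect_true(all(c(31, 35) %in% plateau))
  # a strongly rising series keeps only the minimum three days
  rising <- data.frame(day = rep(c(0, 7, 14, 21, 28, 31, 35), each = 4),
                       conc_ng_kg = rep(exp(0.2 * c(0, 7, 14, 21, 28, 31, 35)),
                                        each = 4) *
                         rep(c(0.98, 1.01, 0.99, 1.02), 7))
  expect_equal(detect_plateau(rising), c(28, 31, 35))
})

test_that("full TG 305 evaluation recovers the generating kinetics", {
  rates <- rate_constants("carp_study", "MXC", kb = 0.2)
  sim <- simulate_tg305(k1 = rates$k1, k2 = rates$k2, kE = rates$kE,
                        kG = rates$kG, kB = rates$kB, water_mean = 6.94,
                        water_cv = 0, fish_noise_cv = 0, kg_weight = rates$kG,
                        seed = 7)
  res <- tg305_analyze(sim$water, sim$fish, "carp_study", "MXC",
                       plateau_days = c(28, 31, 35),
                       use_measured_growth = FALSE)
  expect_equal(res$depuration$kT, sim$truth$kT, tolerance = 1e-10)
  expect_equal(res$kb_in_vivo$kb, 0.2, tolerance = 1e-9)
  # small residual approach-to-plateau truncation at day 28-35
  expect_equal(res$bcf$bcf_ss, sim$truth$bcf_ss, tolerance = 2e-3)
  # measured growth from the simulated weights matches the generating rate
  expect_equal(growth_rate(sim$fish[sim$fish$phase == "uptake", ]),
               rates$kG, tolerance = 1e-9)
})
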