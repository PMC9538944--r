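test_that("dissolved oxygen follows the solubility relation", {
  expect_equal(dissolved_oxygen(21, 0.77), 0.77 * 468 / (31.6 + 21))
  expect_equal(dissolved_oxygen(21, 0.77), 6.85, tolerance = 1e-3)
  expect_equal(dissolved_oxygen(31.6, 1), 468 / 63.2)
  # linear in saturation
  expect_equal(dissolved_oxygen(15, 0.5), 0.5 * dissolved_oxygen(15, 1))
  expect_error(dissolved_oxygen(-2, 0.8), class = "fishbcf_config_error")
  expect_error(dissolved_oxygen(40, 0.8), class = "fishbcf_config_error")
})

test_that("gill uptake k1 matches the stepwise oracle", {
  expect_equal(gill_uptake_k1("carp_study", "MXC"),
               oracle_k1(0.0446, 21, 0.77, 5.08), tolerance = 1e-12)
  expect_equal(gill_uptake_k1("carp_study", "MXC"), 326, tolerance = 0.01)
  # uptake efficiency saturates at 1/a for very hydrophobic chemicals
  k1_hi <- gill_uptake_k1("carp_study", chemical_props("x", 12))
  c_ox <- dissolved_oxygen(21, 0.77)
  g_v <- 1400 * 0.0446^0.65 / c_ox
  expect_equal(k1_hi, (1 / 1.85) * g_v / 0.0446, tolerance = 1e-6)
  # k1 decreases with body mass (ventilation exponent 0.65 < 1)
  masses <- c(0.01, 0.05, 0.2, 1)
  k1s <- vapply(masses, function(w) {
    gill_uptake_k1(fish_physiology("f", body_mass = w, temperature = 21,
                                   lipid_fraction = 0.1, liver_fraction = 0.017,
                                   do_saturation = 0.77), "MXC")
  }, numeric(1))
  expect_true(all(diff(k1s) < 0))
})

test_that("k2 is k1 over the fish-water partition coefficient", {
  expect_equal(partition_k2(325, "carp_study", "MXC"),
               325 / (0.0957 * 10^5.08))
  expect_equal(partition_k2(325, "carp_study", "MXC"), 0.0283,
               tolerance = 2e-3)
  expect_equal(partition_k2(0, "carp_study", "MXC"), 0)
  # doubling lipid halves k2
  lean <- fish_physiology("f", body_mass = 0.0446, temperature = 21,
                          lipid_fraction = 0.05, liver_fraction = 0.0174)
  fat <- fish_physiology("f", body_mass = 0.0446, temperature = 21,
                         lipid_fraction = 0.10, liver_fraction = 0.0174)
  expect_equal(partition_k2(325, lean, "MXC"),
               2 * partition_k2(325, fat, "MXC"))
  # optional non-lipid organic matter term lowers k2
  suite_nl <- rate_constant_suite(nonlipid_fraction = 0.2)
  expect_lt(partition_k2(325, "carp_study", "MXC", suite_nl),
            partition_k2(325, "carp_study", "MXC"))
})

test_that("egestion and growth-dilution constants match their oracles", {
  expect_equal(egestion_kE("carp_study", "MXC"), oracle_kE(0.0446, 21, 5.08),
               tolerance = 1e-12)
  expect_equal(egestion_kE("carp_study", "MXC"), 0.0076, tolerance = 0.005)
  expect_equal(growth_kG("trout_study"), 5e-4 * 0.0185^-0.2)
  expect_equal(growth_kG("trout_study"), 0.0011, tolerance = 0.005)
  # the warm-water coefficient exceeds the cold-water one at equal mass
  expect_gt(growth_kG("trout_study", regime = "warm"),
            growth_kG("trout_study", regime = "cold"))
})

test_that("steady-state BCF is uptake over total elimination", {
  rates <- rate_constants("carp_study", "MXC")
  expect_equal(predict_bcf(rates)$bcf,
               rates$k1 / (rates$k2 + rates$kE + rates$kG))
  # strictly decreasing in kB, with the exact elimination ratio
  kbs <- c(0, 0.02, 0.05, 0.1, 0.5)
  bcfs <- vapply(kbs, function(kb) {
    predict_bcf(rate_constants("carp_study", "MXC", kb = kb))$bcf
  }, numeric(1))
  expect_true(all(diff(bcfs) < 0))
  base <- rates$k2 + rates$kE + rates$kG
  expect_equal(bcfs[1] / bcfs[4], (base + 0.1) / base)
  expect_error(predict_bcf(list(k1 = 1, k2 = 0, kE = 0, kG = 0, kB = 0)),
               class = "fishbcf_invalid_input")
})

test_that("in vivo kB back-calculation subtracts the non-metabolic losses", {
  res <- kb_from_depuration(0.5, 0.05, 0.03, 0.02)
  expect_equal(res$kb, 0.40)
  expect_true(res$distinguishable_from_zero)
  zero <- kb_from_depuration(0.1, 0.05, 0.03, 0.02)
  expect_equal(zero$kb, 0)
  expect_false(zero$distinguishable_from_zero)
  neg <- kb_from_depuration(0.05, 0.05, 0.03, 0.02)
  expect_equal(neg$kb, -0.05)
  expect_false(neg$distinguishable_from_zero)
})

test_that("prediction and back-calculation round trip", {
  rates <- rate_constants("trout_study", "BaP", kb = 0.03)
  kT <- rates$k2 + rates$kE + rates$kG + rates$kB
  expect_equal(predict_bcf(rates)$bcf, rates$k1 / kT)
  back <- kb_from_depuration(kT, rates$k2, rates$kE, rates$kG)
  expect_equal(back$kb, 0.03, tolerance = 1e-12)
})

test_that("kB uncertainty intervals are multiplicative", {
  expect_equal(kb_uncertainty(0.40, 3),
               c(lower = 0.40 / 3, upper = 1.2))
  expect_equal(kb_uncertainty(0.48, 3),
               c(lower = 0.16, upper = 1.44))
  expect_equal(kb_uncertainty(0.2, 1), c(lower = 0.2, upper = 0.2))
  expect_error(kb_uncertainty(0.2, 0.5), class = "fishbcf_invalid_input")
  expect_error(kb_uncertainty(0, 3), class = "fishbcf_invalid_input")
})

test_that("rate constants vary continuously with mass and temperature", {
  masses <- seq(0.02, 0.5, length.out = 60)
  k1s <- vapply(masses, function(w) {
    gill_uptake_k1(fish_physiology("f", body_mass = w, temperature = 15,
                                   lipid_fraction = 0.08,
                                   liver_fraction = 0.015,
                                   do_saturation = 0.9), "MXC")
  }, numeric(1))
  expect_true(all(abs(diff(k1s) / k1s[-1]) < 0.25))
  temps <- seq(5, 30, length.out = 40)
  kes <- vapply(temps, function(tt) {
    egestion_kE(fish_physiology("f", body_mass = 0.05, temperature = tt,
                                lipid_fraction = 0.08, liver_fraction = 0.015),
                "MXC")
  }, numeric(1))
  expect_true(all(abs(diff(kes) / kes[-1]) < 0.25))
})
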