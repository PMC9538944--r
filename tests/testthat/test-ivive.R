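test_that("liver scaling follows the unit chain to L/d/kg", {
  # 0.250 mL/h/1e6 cells * 510e6 cells/g liver * 0.015 g/g * 24 h/d
  expect_equal(scale_to_whole_liver(0.250, fish_physiology("trout_study")),
               0.250 * 510 * 0.015 * 24)
  expect_equal(scale_to_whole_liver(0.287, fish_physiology("carp_study")),
               0.287 * 510 * 0.0174 * 24)
  expect_equal(scale_to_whole_liver(0.287, "carp_study"), 61.1,
               tolerance = 1e-3)
  expect_equal(scale_to_whole_liver(0, "carp_study"), 0)
  # homogeneity: the scaling is linear in clint
  expect_equal(scale_to_whole_liver(3 * 0.1, "carp_study"),
               3 * scale_to_whole_liver(0.1, "carp_study"))
})

test_that("fraction unbound matches the binding QSAR", {
  expect_identical(fraction_unbound("MXC", binding_model("unity")), 1)
  expect_equal(fraction_unbound("MXC"), oracle_fu(5.08), tolerance = 1e-12)
  expect_equal(fraction_unbound("MXC"), 0.010, tolerance = 0.03)
  expect_equal(fraction_unbound("BaP"), oracle_fu(5.99), tolerance = 1e-12)
  # hydrophobicity dependence: fu falls steeply through the low-Kow range
  # (blood binding dominates), then rises slightly once incubation binding
  # catches up; both branches checked by grid scan
  lo <- vapply(seq(2, 4, by = 0.25),
               function(l) fraction_unbound(chemical_props("x", l)), numeric(1))
  hi <- vapply(seq(6, 8, by = 0.25),
               function(l) fraction_unbound(chemical_props("x", l)), numeric(1))
  expect_true(all(diff(lo) < 0))
  expect_true(all(diff(hi) > 0))
  expect_true(all(c(lo, hi) > 0))
})

test_that("hepatic blood flow follows the cardiac-output relation", {
  phys500 <- fish_physiology("f", body_mass = 0.5, temperature = 12,
                             lipid_fraction = 0.05, liver_fraction = 0.015)
  expect_equal(hepatic_blood_flow(phys500), 0.259 * (0.23 * 12 - 0.78) * 24)
  expect_equal(hepatic_blood_flow(phys500), 12.3, tolerance = 1e-3)
  # linear in the hepatic flow fraction
  phys2 <- fish_physiology("f", body_mass = 0.5, temperature = 12,
                           lipid_fraction = 0.05, liver_fraction = 0.015,
                           hepatic_flow_fraction = 2 * 0.259)
  expect_equal(hepatic_blood_flow(phys2), 2 * hepatic_blood_flow(phys500))
  # the relation turns non-positive at low temperature
  cold <- fish_physiology("f", body_mass = 0.5, temperature = 3,
                          lipid_fraction = 0.05, liver_fraction = 0.015)
  expect_error(hepatic_blood_flow(cold), class = "fishbcf_config_error")
  hot <- fish_physiology("f", body_mass = 0.5, temperature = 36,
                         lipid_fraction = 0.05, liver_fraction = 0.015)
  expect_error(hepatic_blood_flow(hot), class = "fishbcf_config_error")
})

test_that("well-stirred clearance interpolates between its limits", {
  expect_equal(well_stirred_clearance(62.3, 0.01, 20),
               20 * 0.623 / (20 + 0.623))
  expect_equal(well_stirred_clearance(62.3, 0.01, 20), 0.604,
               tolerance = 1e-3)
  expect_equal(well_stirred_clearance(0, 0.5, 20), 0)
  expect_equal(well_stirred_clearance(10, 0, 20), 0)
  # perfusion limit: CL_H -> Q_H as fu*CL_int grows
  expect_equal(well_stirred_clearance(1e9, 1, 20), 20, tolerance = 1e-6)
  # clearance limit: CL_H ~ fu*CL_int within 5% when the ratio is < 0.05
  expect_equal(well_stirred_clearance(0.9, 1, 20), 0.9, tolerance = 0.05)
})

test_that("kB combines hepatic clearance and volume of distribution", {
  carp <- fish_physiology("carp_study")
  mxc <- chemical_props("MXC")
  v_d <- volume_of_distribution(carp, mxc)
  expect_equal(v_d, 0.0957 * 10^5.08 / (0.16 * 10^(0.73 * 5.08) + 0.84))
  expect_equal(v_d, 14.1, tolerance = 5e-3)
  expect_equal(kb_from_clearance(0.604, carp, mxc), 0.604 / v_d)
  expect_equal(0.604 / 14.1, 0.0428, tolerance = 1e-3)
  expect_equal(kb_from_clearance(0, carp, mxc), 0)
})

test_that("the IVIVE chain is internally consistent and monotone", {
  est <- ivive_kb(0.287, "carp_study", "MXC")
  expect_equal(est$kb, est$cl_h / est$v_d)
  expect_equal(est$cl_h,
               well_stirred_clearance(est$cl_in_vivo_int, est$fu, est$q_h))
  # kB is non-decreasing in clint
  kbs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                function(cl) ivive_kb(cl, "carp_study", "MXC")$kb, numeric(1))
  expect_true(all(diff(kbs) > 0))
  # CL_H is sub-linear in clint (well-stirred saturation)
  cl1 <- ivive_kb(0.1, "carp_study", "MXC")$cl_h
  cl10 <- ivive_kb(1.0, "carp_study", "MXC")$cl_h
  expect_lt(cl10, 10 * cl1)
  expect_gt(cl10, cl1)
})

test_that("unity fu gives at least the QSAR-fu biotransformation rate", {
  for (i in seq_len(nrow(study_cases()))) {
    case <- study_cases()[i, ]
    qsar <- ivive_kb(0.25, case$species, case$chemical)
    unity <- ivive_kb(0.25, case$species, case$chemical,
                      binding = binding_model("unity"))
    expect_lte(qsar$fu, 1)
    expect_gte(unity$kb, qsar$kb)
  }
})

test_that("species parameter sets act as pure data", {
  a <- ivive_kb(0.25, "carp_study", "MXC")
  b <- ivive_kb(0.25, "trout_study", "MXC")
  expect_false(isTRUE(all.equal(a$kb, b$kb)))
  expect_equal(ivive_kb(0.25, "carp_study", "MXC")$kb, a$kb)
})
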