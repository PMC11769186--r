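# expected power-law values frozen from direct evaluation of
# C * lambda^-k (independent of the package's log-space path)
test_that("melanin and baseline power laws match direct evaluation", {
  expect_equal(melanin_mua(660), 6.6e10 * 660^-3.33, tolerance = 1e-12)
  expect_equal(melanin_mua(660), 26.944035, tolerance = 1e-6)
  expect_equal(melanin_mua(940), 8.299046, tolerance = 1e-6)
  expect_equal(skin_baseline_mua(660), 0.0520840, tolerance = 1e-5)
  expect_equal(skin_baseline_mua(940), 0.0164734, tolerance = 1e-5)
  expect_error(melanin_mua(0), "positive")
  expect_error(skin_baseline_mua(-660), "positive")
})

test_that("power laws decrease with wavelength", {
  lams <- sort(runif(25, 300, 1200))
  expect_true(all(diff(melanin_mua(lams)) < 0))
  expect_true(all(diff(skin_baseline_mua(lams)) < 0))
})

test_that("chromophore table loads, validates, and refuses absent wavelengths", {
  tab <- chromophore_table()
  expect_s3_class(tab, "chromophore_table")
  expect_setequal(tab$wavelength_nm, c(660, 940))
  mu <- mua_lookup(tab, 660)
  expect_gt(mu$mu_a_hhb, mu$mu_a_hbo2)    # red: deoxy absorbs more
  mu9 <- mua_lookup(tab, 940)
  expect_gt(mu9$mu_a_hbo2, mu9$mu_a_hhb)  # infrared: oxy absorbs more
  expect_error(mua_lookup(tab, 800), "not in chromophore table")
  # opt-in log-linear interpolation stays within the bracketing values
  mu8 <- mua_lookup(tab, 800, interpolate = TRUE)
  expect_gt(mu8$mu_a_hbo2, mu$mu_a_hbo2)
  expect_lt(mu8$mu_a_hbo2, mu9$mu_a_hbo2)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = 660, mu_a_hbo2_mm = -1,
                       mu_a_hhb_mm = 1, mu_a_water_mm = 0), bad,
            row.names = FALSE)
  expect_error(chromophore_table(bad), "non-negative")
})

test_that("epidermal mu_a composes melanin, water and baseline", {
  tab <- chromophore_table()
  # degenerate composition collapses to the baseline power law
  expect_equal(epidermis_mua(660, epidermis_composition(0, 0), tab),
               skin_baseline_mua(660))
  # hand-computed: vmel*mel + (1 - vmel)*baseline, water-free
  expect_equal(epidermis_mua(660, epidermis_composition(0.0255, 0), tab),
               0.737828, tolerance = 1e-5)
  expect_equal(epidermis_mua(660, epidermis_composition(0.305, 0), tab),
               8.254129, tolerance = 1e-5)
  expect_error(epidermis_composition(0.7, 0.5), "vmel")
  expect_error(epidermis_composition(-0.1, 0), "vmel")
})

test_that("perfused-layer mu_a composes blood, water and residual baseline", {
  tab <- chromophore_table()
  # bloodless, dry limit
  expect_equal(blood_layer_mua(660, blood_composition(0, 0, 0, 0.98), tab),
               skin_baseline_mua(660))
  # stated placeholder spectra, term-by-term hand computation:
  # 0.0042 + 0.00555 + 0.000234 + 0.33*baseline(660) = 0.027172
  ptab <- placeholder_table()
  comp <- blood_composition(0.01, 0.01, 0.65, sat_art = 0.8, sat_ven = 0.7)
  expect_equal(blood_layer_mua(660, comp, ptab), 0.027172, tolerance = 1e-4)
  # fully oxygenated arterial-only blood: deoxy term vanishes
  comp2 <- blood_composition(0.01, 0, 0.65, sat_art = 1, sat_ven = 0.9)
  expect_equal(blood_layer_mua(660, comp2, ptab),
               0.15 * 0.01 + 0.65 * 0.00036 + 0.34 * skin_baseline_mua(660),
               tolerance = 1e-12)
  expect_error(blood_composition(0.5, 0.5, 0.5, 0.98), "<= 1")
})

test_that("venous saturation is 10 points below arterial", {
  expect_equal(venous_sat(1.00), 0.90)
  expect_equal(venous_sat(0.70), 0.60)
  expect_error(venous_sat(0.05), "0.10")
})

test_that("composed mu_a is non-negative and monotone in its drivers", {
  tab <- chromophore_table()
  set.seed(11)
  for (i in 1:50) {
    vmel <- runif(1, 0, 0.5); vw <- runif(1, 0, 1 - vmel)
    expect_gte(epidermis_mua(sample(c(660, 940), 1),
                             epidermis_composition(vmel, vw), tab), 0)
    f <- runif(3); f <- f / sum(f) * runif(1, 0, 1)
    s <- runif(1, 0.10, 1)
    expect_gte(blood_layer_mua(sample(c(660, 940), 1),
                               blood_composition(f[1], f[2], f[3], s), tab), 0)
  }
  # strictly increasing in melanosome fraction at both operating wavelengths
  for (lam in c(660, 940)) {
    mus <- vapply(c(0.0255, 0.155, 0.305), function(v)
      epidermis_mua(lam, epidermis_composition(v, 0.2), tab), 0)
    expect_true(all(diff(mus) > 0))
  }
  # red mu_a falls, infrared mu_a rises with arterial saturation
  sat <- seq(0.70, 1.00, by = 0.05)
  mua660 <- vapply(sat, function(s)
    blood_layer_mua(660, blood_composition(0.02, 0.02, 0.6, s), tab), 0)
  mua940 <- vapply(sat, function(s)
    blood_layer_mua(940, blood_composition(0.02, 0.02, 0.6, s), tab), 0)
  expect_true(all(diff(mua660) < 0))
  expect_true(all(diff(mua940) > 0))
})
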