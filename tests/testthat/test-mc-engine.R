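test_that("free-path sampling follows the exponential distribution", {
  s <- sample_step(2e5, mu_t = 4, seed = 9)
  expect_true(all(s >= 0))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 4), 3 * se)
})

test_that("Henyey-Greenstein sampling has the right limits and mean", {
  iso <- hg_cos_theta(1e5, g = 0, seed = 2)
  ks <- suppressWarnings(ks.test(iso, "punif", -1, 1))
  expect_gt(ks$p.value, 0.001)
  for (g in c(0.5, 0.9)) {
    ct <- hg_cos_theta(1e5, g = g, seed = 3)
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
    expect_true(all(ct >= -1 & ct <= 1))
  }
  dirs <- scatter_direction(c(0, 0, 1), g = 0.9, n = 2e4, seed = 5)
  norms <- sqrt(rowSums(dirs^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  se <- sd(dirs[, 3]) / sqrt(nrow(dirs))
  expect_lt(abs(mean(dirs[, 3]) - 0.9), 3 * se)
  # deflection is relative to the incoming direction, whatever it is
  d2 <- scatter_direction(c(1, 0, 0), g = 0.9, n = 2e4, seed = 5)
  se2 <- sd(d2[, 1]) / sqrt(nrow(d2))
  expect_lt(abs(mean(d2[, 1]) - 0.9), 3 * se2)
})

test_that("Fresnel reflectance matches the closed form", {
  expect_equal(fresnel_reflectance(1, 1.4, 1.4), 0)
  expect_equal(fresnel_reflectance(1, 1.0, 1.4), ((1.4 - 1) / (1.4 + 1))^2,
               tolerance = 1e-12)
  # beyond the critical angle (n1 > n2): certain reflection
  expect_equal(fresnel_reflectance(0.1, 1.4, 1.0), 1)
  # independent evaluation from Snell + amplitude coefficients
  oracle <- function(ci, n1, n2) {
    ai <- acos(ci); at <- asin(min(1, n1 / n2 * sin(ai)))
    0.5 * ((sin(ai - at) / sin(ai + at))^2 + (tan(ai - at) / tan(ai + at))^2)
  }
  for (ci in c(0.3, 0.6, 0.9)) {
    expect_equal(fresnel_reflectance(ci, 1.0, 1.4), oracle(ci, 1.0, 1.4),
                 tolerance = 1e-9)
    expect_equal(fresnel_reflectance(ci, 1.4, 1.33), oracle(ci, 1.4, 1.33),
                 tolerance = 1e-9)
  }
})

test_that("roulette conserves expected weight and never touches heavy packets", {
  w <- rep(0.2, 10)
  expect_identical(roulette(w, threshold = 1e-4), w)
  w0 <- 5e-5
  out <- roulette(rep(w0, 2e5), threshold = 1e-4, p_survive = 0.1, seed = 8)
  expect_true(all(out %in% c(0, w0 / 0.1)))
  se <- sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - w0), 3 * se)
})

test_that("ballistic transmission through an absorbing slab is Beer-Lambert", {
  st <- slab_stack(mu_a = 2, mu_s = 0, g = 0, n = 1.0, thickness = 1)
  res <- transport(st, settings = engine_settings(launched = 1e5), seed = 12)
  expect_equal(res$transmittance, exp(-2), tolerance = 0.01)
})

test_that("every run conserves energy and keeps fractions in bounds", {
  runs <- list(
    transport(slab_stack(0.1, 10, 0.8, n = 1.4), detector_spec(),
              engine_settings(launched = 2e4), seed = 1),
    transport(build_stack(tissue_config("light"), 660,
                          physiological_state(0.95)),
              settings = engine_settings(detected = 2e3), seed = 2))
  for (r in runs) {
    total <- r$specular_weight + r$diffuse_reflected_weight +
      r$transmitted_weight + r$absorbed_weight
    expect_lt(abs(total - r$launched_weight) / r$launched_weight, 1e-6)
    expect_gte(r$reflectance, 0); expect_lte(r$reflectance, 1)
    expect_gte(r$transmittance, 0); expect_lte(r$transmittance, 1)
    expect_lte(r$detected_weight, r$diffuse_reflected_weight)
  }
  # no absorption sink: reflected + transmitted account for everything
  st0 <- slab_stack(mu_a = 0, mu_s = 5, g = 0.5, n = 1.0, thickness = 2)
  r0 <- transport(st0, settings = engine_settings(launched = 2e4), seed = 3)
  expect_equal(r0$diffuse_reflected_weight + r0$transmitted_weight,
               r0$launched_weight, tolerance = 1e-12)
  expect_equal(r0$absorbed_weight, 0)
})

test_that("same seed is bit-identical; different seeds agree statistically", {
  st <- build_stack(tissue_config("light"), 940, physiological_state(0.9))
  a <- transport(st, settings = engine_settings(detected = 2e3), seed = 77)
  b <- transport(st, settings = engine_settings(detected = 2e3), seed = 77)
  expect_identical(unclass(a), unclass(b))
  c_ <- transport(st, settings = engine_settings(detected = 2e3), seed = 78)
  expect_false(identical(a$reflectance, c_$reflectance))
  # binomial-scale agreement on the annulus-hit fraction
  p <- a$detected_count / a$launched_count
  se <- sqrt(p * (1 - p) / a$launched_count) * 4
  expect_lt(abs(p - c_$detected_count / c_$launched_count), 4 * se)
})

test_that("detector arc-coverage integrates to the disc area", {
  d <- 3; a <- 1
  r <- seq(d - a, d + a, length.out = 4001)
  f <- detector_arc_fraction(r, d, a)
  expect_true(all(f >= 0 & f <= 1))
  area <- sum(f * 2 * pi * r) * (r[2] - r[1])
  expect_equal(area, pi * a^2, tolerance = 1e-3)
  # off-overlap exits never count
  expect_equal(detector_arc_fraction(c(0.5, 10), d, a), c(0, 0))
})

test_that("launch weight loses the normal-incidence specular fraction", {
  st <- slab_stack(mu_a = 1, mu_s = 0, g = 0, n = 1.4, thickness = 50)
  r <- transport(st, settings = engine_settings(launched = 5000), seed = 4)
  expect_equal(r$specular_weight / r$launched_weight, 0.0277778,
               tolerance = 1e-6)
  matched <- transport(slab_stack(1, 0, 0, n = 1.0, thickness = 50),
                       settings = engine_settings(launched = 5000), seed = 4)
  expect_equal(matched$specular_weight, 0)
})

test_that("an empirical boundary estimate reproduces the Fresnel probability", {
  # straight-through geometry: a matched non-interacting layer above an
  # index step to n = 1.4; packets reflect at the step with probability R.
  # The lower medium is strongly absorbing so transmitted packets never
  # return to contaminate the top-exit tally.
  cfg <- list(ambient_n = 1.0, layers = list(
    list(name = "top", thickness_mm = 1, n = 1.0,
         mu_s_mm = list("660" = 0), g = list("660" = 0),
         composition = list(type = "fixed", mu_a_mm = list("660" = 0))),
    list(name = "sink", thickness_mm = 1, n = 1.4,
         mu_s_mm = list("660" = 0), g = list("660" = 0),
         composition = list(type = "fixed", mu_a_mm = list("660" = 20)))),
    bone = NULL)
  st <- build_stack(pulseoxmc:::validate_tissue_config(cfg), 660,
                    physiological_state(0.95))
  n <- 1e5
  r <- transport(st, settings = engine_settings(launched = n), seed = 21)
  p_true <- 0.0277778
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(r$diffuse_reflected_weight / n - p_true), 3 * se)
})

test_that("melanin ordering: darker presets detect less red light", {
  refl <- vapply(c("light", "moderate", "dark"), function(s) {
    st <- build_stack(tissue_config(s), 660, physiological_state(0.95))
    transport(st, settings = engine_settings(detected = 5e3), seed = 31)$reflectance
  }, 0)
  expect_true(all(diff(refl) < 0))
})
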