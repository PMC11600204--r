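test_that("stress and strain follow the cross-section and gauge formulas", {
  rec <- structure(
    data.frame(time_s = c(0, 0.2, 0.4), Lm_um = c(0, 500, 500),
               x_px = c(0, 0, 50), x_um = c(0, 0, 50),
               Fs_uN = c(0, 8.32, 8.32), stim = 0L, medium = "solution"),
    class = c("recording", "data.frame"))
  ss <- stress_strain(rec, d0 = 110e-6, L0 = 5e-3)
  expect_equal(ss$sigma_Pa[2], 4 * 8.32e-6 / (pi * 110e-6^2))
  expect_equal(ss$sigma_Pa[2], 875.6, tolerance = 1e-3)
  expect_equal(ss$epsilon[2], 0.1)                 # Lm 0.5 mm, x 0
  expect_equal(ss$epsilon[3], (500 - 50) * 1e-6 / 5e-3)  # 9%
  # L_m = x: zero strain
  rec$x_um <- rec$Lm_um; rec$x_px <- rec$Lm_um
  expect_equal(stress_strain(rec, 110e-6, 5e-3)$epsilon, c(0, 0, 0))
  expect_error(stress_strain(data.frame(time_s = 1)), "columns")
})

test_that("spectral extraction recovers constructed sinusoids exactly", {
  t <- seq(0, 50 - 0.2, by = 0.2)   # 5 full periods at 0.1 Hz
  sigma <- 100 * sin(2 * pi * 0.1 * t + 0.3805)
  eps <- 0.1 * sin(2 * pi * 0.1 * t)
  vs <- extract_viscoelasticity(sigma, eps, t, 0.1)
  expect_equal(vs$E_star, 1000, tolerance = 1e-6)
  expect_equal(vs$tan_delta, tan(0.3805), tolerance = 1e-6)
  expect_equal(vs$tan_delta, 0.4, tolerance = 1e-3)
  # zero phase difference
  vs0 <- extract_viscoelasticity(2000 * eps, eps, t, 0.1)
  expect_equal(vs0$tan_delta, 0)
  expect_error(extract_viscoelasticity(sigma[1:50], eps[1:50], t[1:50], 0.1),
               "3 full periods")
  expect_error(extract_viscoelasticity(sigma, eps * 0, t, 0.1),
               "excitation")
})

test_that("simulated Kelvin-Voigt fixture is recovered within 1%", {
  kv <- kv_params()
  vs <- measure_visco(kv)
  expect_equal(vs$E_star / 1e3, 3.2311, tolerance = 0.01)
  expect_equal(vs$tan_delta, 0.4, tolerance = 0.01)
})

test_that("Lissajous modulus equals the amplitude ratio and uses the final loop", {
  t <- seq(0, 50 - 0.2, by = 0.2)
  eps <- 0.1 * sin(2 * pi * 0.1 * t)
  expect_equal(lissajous_modulus(3e3 * eps, eps, t, 0.1), 3e3)
  # decaying transient: only the final loop gives the steady amplitude
  sigma_tr <- 3e3 * eps * (1 + exp(-t / 5))
  E_last <- lissajous_modulus(sigma_tr, eps, t, 0.1)
  expect_equal(E_last, 3e3, tolerance = 0.01)
  E_all <- (max(sigma_tr) - min(sigma_tr)) / (max(eps) - min(eps))
  expect_gt(E_all, 1.2 * E_last)
  expect_error(lissajous_modulus(eps * 3e3, eps * 0, t, 0.1), "strain")
  # linear viscoelastic steady state: equals |E*| within 2%
  vs <- measure_visco(kv_params())
  expect_equal(vs$E_lissajous, vs$E_star, tolerance = 0.02)
})

test_that("doubling the diameter quarters stress and modulus estimates", {
  rec <- run_oscillation(default_core_params(), short_probe, seed = 4,
                         noise_px = 0, quantize = FALSE)
  v1 <- analyze_recording(rec)
  v2 <- analyze_recording(rec, d0 = 2 * attr(rec, "params")$diameter)
  expect_equal(v2$E_star, v1$E_star / 4, tolerance = 1e-9)
})

test_that("optimal length extraction recovers the plant's force-length optimum", {
  my <- default_myobundle_params()
  stim <- run_length_sweep(my, long_probe, stimulate = TRUE, seed = 21)
  pas <- run_length_sweep(my, long_probe, stimulate = FALSE, seed = 22)
  cs <- find_optimal_length(stim, pas)
  expect_gte(cs$Lo_strain, 0.04)
  expect_lte(cs$Lo_strain, 0.07)
  expect_equal(cs$Lo_strain, my$optimal_strain, tolerance = 0.2)
  expect_equal(cs$active_peak, my$active_peak, tolerance = 0.1)
  expect_true(cs$cf_generated)
  # F_a = 0 plant: no contraction called
  dead <- default_myobundle_params(); dead$active_peak <- 0
  s2 <- run_length_sweep(dead, long_probe, stimulate = TRUE, seed = 23)
  p2 <- run_length_sweep(dead, long_probe, stimulate = FALSE, seed = 24)
  cs2 <- find_optimal_length(s2, p2)
  expect_false(cs2$cf_generated)
  expect_lt(abs(cs2$active_peak), 0.5e-6)
})

test_that("contractile-force criterion compares against the group baseline", {
  cv <- cf_criterion_value(10e-6, c(6e-6, 6.5e-6, 7e-6))
  expect_equal(cv$cf_diff, 10e-6 - 6.5e-6)
  expect_true(cv$cf_generated)
  expect_false(cf_criterion_value(8.5e-6, c(6e-6, 6.5e-6, 7e-6))$cf_generated)
  # exactly the worked thresholds: 3.5 uN passes, 2.0 uN fails
  expect_true(cf_criterion_value(3.5e-6, 0)$cf_generated)
  expect_false(cf_criterion_value(2.0e-6, 0)$cf_generated)
  expect_match(cf_criterion_value(5e-6, 1e-6)$flags, "singleton")
})
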