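test_that("cross-section inertia follows the hollow-tube formula", {
  sp <- probe_spec(0.3e-3, 0.1e-3, 50e-3, 45e-3, 1.1e-6)
  expect_equal(moment_of_inertia(sp), pi / 64 * (0.3e-3^4 - 0.1e-3^4))
  expect_equal(moment_of_inertia(sp), 3.927e-16, tolerance = 1e-3)
  solid <- probe_spec(0.3e-3, 0, 50e-3, 45e-3, 1.1e-6)
  expect_gt(moment_of_inertia(solid), moment_of_inertia(sp))
  expect_error(probe_spec(0.3e-3, 0.3e-3, 50e-3, 45e-3, 1.1e-6),
               "geometry")
})

test_that("tip stiffness matches the closed form and its length scaling", {
  sp <- probe_spec(0.3e-3, 0.1e-3, 50e-3, 45e-3, 1.1e-6,
                   material_modulus = 72e9)
  k <- probe_stiffness(sp)
  k_expected <- 6 * 72e9 * moment_of_inertia(sp) /
    (45e-3^2 * (3 * 50e-3 - 45e-3))
  expect_equal(k, k_expected)
  expect_equal(k, 0.798, tolerance = 1e-3)
  doubled <- probe_spec(0.3e-3, 0.1e-3, 100e-3, 90e-3, 1.1e-6,
                        material_modulus = 72e9)
  expect_equal(probe_stiffness(doubled), k / 8)
  expect_error(probe_spec(0.3e-3, 0.1e-3, 50e-3, 60e-3, 1.1e-6),
               "mount_position")
})

test_that("tip deflection matches numerical beam integration within 0.1%", {
  sp <- probe_spec(0.3e-3, 0.1e-3, 50e-3, 45e-3, 1.1e-6)
  EI <- sp$material_modulus * moment_of_inertia(sp)
  F <- 1e-5  # small load: tip deflection well under 1% of L_p
  # oracle: integrate curvature y'' = M/EI twice; M = F (l - P) up to the
  # load point, zero beyond (free overhang stays straight)
  P <- seq(0, sp$probe_length, length.out = 20001)
  M <- ifelse(P <= sp$mount_position, F * (sp$mount_position - P), 0)
  ypp <- M / EI
  h <- P[2] - P[1]
  yp <- cumsum((ypp + c(ypp[1], ypp[-length(ypp)])) / 2) * h - ypp[1] * h / 2
  y <- cumsum((yp + c(0, yp[-length(yp)])) / 2) * h
  tip_numeric <- y[length(y)]
  tip_closed <- F / probe_stiffness(sp)
  expect_equal(tip_numeric, tip_closed, tolerance = 1e-3)
  expect_lt(tip_closed / sp$probe_length, 0.01)
})

test_that("pixel readout is quantized and exactly linear", {
  sp <- probe_preset("short")
  fpp <- force_per_pixel(sp)
  expect_equal(fpp * 1e6, 0.88, tolerance = 0.01)
  expect_equal(force_from_deflection(sp, 0), 0)
  expect_equal(force_from_deflection(sp, 5), 5 * fpp)
  expect_error(force_from_deflection(sp, -1), "negative")
  expect_error(force_from_deflection(sp, 1.5), "integer")
  # linearity over random specs
  for (s in 1:5) {
    set.seed(s)
    L <- runif(1, 0.03, 0.1)
    spr <- probe_spec(runif(1, 2e-4, 1e-3), runif(1, 0, 1e-4),
                      L, 0.9 * L, 1e-6)
    expect_gt(probe_stiffness(spr), 0)
    n <- sample(0:50, 5)
    expect_equal(force_from_deflection(spr, n),
                 n * force_per_pixel(spr))
  }
  expect_equal(quantize_deflection(sp, 3.9 * sp$pixel_size), 3)
  expect_equal(quantize_deflection(sp, -3.9 * sp$pixel_size), -3)
})

test_that("resolution rescaling follows the inverse-cube law and composes", {
  expect_equal(resolution_after_rescale(0.11, 1 / 2), 0.88)
  expect_equal(resolution_after_rescale(0.88, 2), 0.11)
  expect_equal(resolution_after_rescale(0.5, 1), 0.5)
  lp <- probe_preset("long")
  halved <- resolution_after_rescale(lp, 1 / 2)
  expect_equal(force_per_pixel(halved), force_per_pixel(lp) * 8)
  # composition
  a <- 0.7; b <- 1.9
  expect_equal(
    force_per_pixel(resolution_after_rescale(
      resolution_after_rescale(lp, a), b)),
    force_per_pixel(resolution_after_rescale(lp, a * b)))
  expect_error(resolution_after_rescale(lp, 0), "length_scale")
})

test_that("probe presets reproduce the two reported per-pixel resolutions", {
  expect_equal(force_per_pixel(probe_preset("short")) * 1e6, 0.88,
               tolerance = 0.01)
  expect_equal(force_per_pixel(probe_preset("long")) * 1e6, 0.11,
               tolerance = 0.01)
  expect_equal(probe_preset("long")$probe_length,
               2 * probe_preset("short")$probe_length)
})
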