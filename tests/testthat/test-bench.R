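test_that("series force balance hits its limiting cases", {
  # rigid sample: probe absorbs all displacement
  rigid <- plant_params(1e9, diameter = 300e-6)
  rec <- run_oscillation(rigid, short_probe, amplitude_strain = 1e-4,
                         pre_strain = 0, noise_px = 0, quantize = FALSE,
                         seed = 1)
  sub <- attr(rec, "x_subpixel_um")
  expect_equal(max(sub), max(rec$Lm_um), tolerance = 1e-2)
  # limp sample: probe barely moves
  limp <- plant_params(1e-3, diameter = 300e-6)
  rec2 <- run_oscillation(limp, short_probe, noise_px = 0,
                          quantize = FALSE, seed = 1)
  expect_lt(max(abs(attr(rec2, "x_subpixel_um"))), 1e-3)
})

test_that("recorded force equals stiffness times quantized deflection", {
  rec <- run_oscillation(default_core_params(), short_probe, seed = 2)
  k <- probe_stiffness(short_probe)
  expect_equal(rec$Fs_uN, k * rec$x_um, tolerance = 1e-12)
  expect_true(all(rec$x_px == round(rec$x_px)))
  expect_true(all(abs(diff(diff(rec$time_s))) < 1e-9))
})

test_that("pre-quantization force balance residual is below 1e-9 N", {
  # static elastic case solved independently with uniroot
  k <- probe_stiffness(short_probe)
  pe <- plant_params(3e3, diameter = 300e-6)
  step2 <- microDMA:::make_stepper(pe, short_probe, "solution")
  x_static <- step2(Inf, 1e-4, 0)
  A0 <- cross_section_area(pe)
  f <- function(x) k * x - A0 * 3e3 * (1e-4 - x) / pe$rest_length
  x_or <- uniroot(f, c(0, 1e-4), tol = 1e-15)$root
  expect_lt(abs(f(x_static)), 1e-9)
  expect_equal(x_static, x_or, tolerance = 1e-9)
  # nonlinear static case (passive stiffening + active force), same oracle
  pn <- plant_params(3e3, passive_stiffening = 1.2, active_peak = 4e-6,
                     diameter = 300e-6)
  stn <- microDMA:::make_stepper(pn, short_probe, "solution")
  xn <- stn(Inf, 3e-4, 1)
  A0 <- cross_section_area(pn)
  k <- probe_stiffness(short_probe)
  fn <- function(x) {
    eps <- (3e-4 - x) / pn$rest_length
    k * x - A0 * (3e3 * eps + 3e3 * 1.2 * (exp(1.2 * eps) - 1)) -
      4e-6 * exp(-((eps - pn$optimal_strain) / pn$active_width)^2)
  }
  expect_lt(abs(fn(xn)), 1e-9)
  expect_equal(xn, uniroot(fn, c(0, 3e-4), tol = 1e-15)$root,
               tolerance = 1e-8)
})

test_that("cycle energy is dissipated by lossy plants and conserved by elastic ones", {
  loop_area <- function(params, medium) {
    rec <- run_oscillation(params, short_probe, medium = medium,
                           noise_px = 0, quantize = FALSE, seed = 1)
    ss <- stress_strain(rec)
    i <- ss$time_s >= max(ss$time_s) - 10  # final 0.1 Hz cycle
    sigma <- ss$sigma_Pa[i]; eps <- ss$epsilon[i]
    sum(diff(eps) * (sigma[-1] + sigma[-length(sigma)]) / 2)
  }
  expect_gt(loop_area(kv_params(), "solution"), 0)
  elastic <- plant_params(3e3, diameter = 300e-6)
  expect_lt(abs(loop_area(elastic, "air")),
            1e-3 * abs(loop_area(kv_params(), "solution")))
})

test_that("overloading the liquid bridge raises a fixation failure", {
  stiff <- plant_params(60e3, diameter = 300e-6)
  expect_error(run_oscillation(stiff, short_probe, amplitude_strain = 0.25,
                               noise_px = 0, seed = 1),
               class = "fixation_failure")
})

test_that("length sweeps show the tetanic bump only under stimulation", {
  my <- default_myobundle_params()
  pas <- run_length_sweep(my, long_probe, seed = 1, noise_px = 0,
                          quantize = FALSE)
  stim <- run_length_sweep(my, long_probe, stimulate = TRUE, seed = 1,
                           noise_px = 0, quantize = FALSE)
  # passive-only ramp of an acellular fiber is monotone
  ac <- plant_params(3e3, passive_stiffening = 1, diameter = 300e-6)
  pr <- run_length_sweep(ac, short_probe, seed = 1, noise_px = 0,
                         quantize = FALSE)
  expect_true(all(diff(pr$Fs_uN) > -1e-9))
  # stimulated minus passive recovers the Gaussian active term
  act <- stim$Fs_uN - pas$Fs_uN
  expect_equal(max(act) * 1e-6, my$active_peak, tolerance = 0.05)
  expect_error(run_length_sweep(my, long_probe, max_strain = 0.5),
               "max_strain")
})

test_that("stimulation protocols twitch at 1 Hz and fuse at 5 Hz", {
  my <- default_myobundle_params()
  r1 <- run_stimulation(my, long_probe, pulse_frequency = 1, duration = 8,
                        seed = 1, noise_px = 0, quantize = FALSE)
  r5 <- run_stimulation(my, long_probe, pulse_frequency = 5, duration = 8,
                        seed = 1, noise_px = 0, quantize = FALSE)
  s1 <- summarize_stimulation(r1)
  s5 <- summarize_stimulation(r5)
  expect_gt(s5$fluctuation_peak, s1$fluctuation_peak)
  # dead sample: flat trace
  dead <- default_myobundle_params(); dead$active_peak <- 0
  rd <- run_stimulation(dead, long_probe, pulse_frequency = 5,
                        duration = 8, seed = 1, noise_px = 0,
                        quantize = FALSE)
  expect_lt(diff(range(rd$Fs_uN)), 1e-3)
  expect_error(run_stimulation(my, long_probe, medium = "air"), "air")
})

test_that("populations are reproducible and match the study layout", {
  g <- condition_grid("bioink54")
  expect_equal(nrow(g), 54)
  pop <- generate_population(g[1:6, ], 3, seed = 9)
  expect_equal(nrow(pop$manifest), 18)
  expect_equal(length(pop$recordings), 18)
  pop2 <- generate_population(g[1:6, ], 3, seed = 9)
  expect_identical(pop$manifest, pop2$manifest)
  expect_identical(pop$recordings[[1]]$Fs_uN, pop2$recordings[[1]]$Fs_uN)
  # spheres are listed but produce no recordings
  gg <- condition_grid("gelma12")
  popg <- generate_population(gg[1:4, ], 2, seed = 1, stage = "cultured")
  expect_equal(nrow(popg$manifest), 8)
  expect_equal(sum(popg$manifest$measurable), 2)  # only combination 4
  expect_equal(length(popg$recordings), 2)
})

test_that("the full bioink grid with study replication yields 432 recordings", {
  pop <- generate_population(condition_grid("bioink54"), 8, seed = 3)
  expect_equal(nrow(pop$manifest), 432)
  expect_equal(length(pop$recordings), 432)
})
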