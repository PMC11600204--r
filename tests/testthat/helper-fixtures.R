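# Shared fixtures: probes, reference plants, and a fast oscillation runner.

short_probe <- probe_preset("short")
long_probe <- probe_preset("long")

# Kelvin-Voigt reference: pure spring 3 kPa plus viscous loss 1.2 kPa at
# 0.1 Hz (tan delta exactly 0.4 in solution)
kv_params <- function() {
  w <- 2 * pi * 0.1
  plant_params(equilibrium_modulus = 3e3,
               drag_coefficient = 1.2e3 / w,
               diameter = 300e-6, rest_length = 5e-3,
               label = "kelvin_voigt")
}

# noise-free, unquantized oscillation + analysis shortcut
measure_visco <- function(params, probe = short_probe, frequency = 0.1,
                          medium = "solution", noise_px = 0,
                          quantize = FALSE, seed = 1, ...) {
  rec <- run_oscillation(params, probe, frequency = frequency,
                         medium = medium, noise_px = noise_px,
                         quantize = quantize, seed = seed, ...)
  analyze_recording(rec)
}

# random linear plants from the calibrated pre-culture family
random_core <- function(seed) {
  set.seed(seed)
  E_t <- stats::runif(1, 1.0e3, 4.0e3)
  t_t <- stats::runif(1, 0.5, 1.0)
  params_from_targets(E_t, t_t, diameter = 300e-6)
}
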