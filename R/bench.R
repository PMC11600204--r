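# Synthetic two-probe bench: integrates the fiber plant, the sensing probe
# and the camera into time-domain recordings of the loading protocols.

CAMERA_DT <- 0.2          # s, 5 Hz top-view camera
FIXATION_LIMIT <- 120e-6  # N, liquid-bridge adhesion

# Step the quasi-static force balance over a fine time grid.
#
# At every step the sample force at strain eps = (L_m - x)/L_0 must equal
# the probe restoring force k x. The Maxwell arm is advanced with an
# exponential integrator (exact for strain linear within the step); the
# resulting scalar balance is solved by damped Newton (exact in one step
# for the linear plant).
#
# Returns list(x, force) on the fine grid (pre-noise, pre-quantization).
integrate_balance <- function(params, probe, times, Lm, activation = NULL,
                              medium = "solution") {
  n <- length(times)
  stopifnot(length(Lm) == n)
  if (is.null(activation)) activation <- numeric(n)
  step <- make_stepper(params, probe, medium)
  x <- numeric(n)
  for (i in seq_len(n)) {
    dt <- if (i == 1) Inf else times[i] - times[i - 1]
    x[i] <- step(dt, Lm[i], activation[i])
  }
  list(x = x, force = probe_stiffness(probe) * x)
}

# Stateful single-step solver of the probe/sample force balance. Returns a
# function(dt, Lm, activation) -> tip deflection x; closure state carries
# the Maxwell-arm stress and previous strain. dt = Inf gives the static
# (relaxed-arm, no-rate) solution used for the first sample.
make_stepper <- function(params, probe, medium = "solution") {
  k <- probe_stiffness(probe)
  A0 <- cross_section_area(params)
  L0 <- params$rest_length
  Ee <- params$equilibrium_modulus
  E1 <- params$arm_modulus
  gam <- if (medium == "solution") params$drag_coefficient else 0
  cp <- params$passive_stiffening
  Fa <- params$active_peak
  lo <- params$optimal_strain
  wd <- params$active_width
  tau1 <- if (E1 > 0 && params$arm_viscosity > 0)
    params$arm_viscosity / E1 else Inf

  eps_prev <- 0
  eps_prev2 <- NA_real_
  dt_prev <- NA_real_
  sig_arm <- 0
  x_prev <- 0
  function(dt, Lmi, act = 0) {
    if (is.finite(tau1) && is.finite(dt)) {
      e_fac <- exp(-dt / tau1)
      beta <- E1 * (tau1 / dt) * (1 - e_fac)
      arm0 <- sig_arm * e_fac
    } else { # first step (static) or purely elastic arm
      e_fac <- 0; beta <- 0; arm0 <- 0
    }
    # strain rate by BDF2 on a uniform grid (BDF1 on the first step):
    # rate = (c0 eps_n + c_hist) / dt, second-order accurate at the endpoint
    if (is.finite(dt) && !is.na(eps_prev2) && is.finite(dt_prev) &&
        abs(dt_prev - dt) < 1e-12) {
      c0 <- 1.5; c_hist <- -2 * eps_prev + 0.5 * eps_prev2
    } else {
      c0 <- 1; c_hist <- -eps_prev
    }
    g_dt <- if (is.finite(dt)) gam / dt else 0
    # sample force and its derivative w.r.t. strain
    samp <- function(eps) {
      sig <- Ee * eps + arm0 + beta * (eps - eps_prev) +
        g_dt * (c0 * eps + c_hist)
      if (cp > 0) sig <- sig + Ee * cp * (exp(cp * eps) - 1)
      f <- A0 * sig
      if (act > 0 && Fa > 0)
        f <- f + act * Fa * exp(-((eps - lo) / wd)^2)
      f
    }
    dsamp <- function(eps) {
      d <- Ee + beta + g_dt * c0
      if (cp > 0) d <- d + Ee * cp^2 * exp(cp * eps)
      d <- A0 * d
      if (act > 0 && Fa > 0)
        d <- d + act * Fa * exp(-((eps - lo) / wd)^2) *
          (-2 * (eps - lo) / wd^2)
      d
    }
    xi <- x_prev
    for (it in 1:60) {
      eps <- (Lmi - xi) / L0
      r <- k * xi - samp(eps)
      dr <- k + dsamp(eps) / L0
      step <- r / dr
      xi <- xi - step
      if (abs(r) < 1e-12) break
    }
    eps <- (Lmi - xi) / L0
    r <- k * xi - samp(eps)
    if (abs(r) > 1e-9) { # Newton struggled (strong nonlinearity): bisect
      froot <- function(xx) k * xx - samp((Lmi - xx) / L0)
      xi <- stats::uniroot(froot, lower = -abs(Lmi) - L0 * 0.5,
                           upper = abs(Lmi) + L0 * 0.5, tol = 1e-15)$root
      eps <- (Lmi - xi) / L0
    }
    sig_arm <<- arm0 + beta * (eps - eps_prev)
    eps_prev2 <<- eps_prev
    eps_prev <<- eps
    dt_prev <<- dt
    x_prev <<- xi
    xi
  }
}

# Assemble a recording data.frame from fine-grid simulation output.
camera_readout <- function(params, probe, times_fine, Lm_fine, x_fine,
                           stim_fine, medium, protocol,
                           noise_px = 0.3, quantize = TRUE,
                           Fcmd_fine = NULL, extra_meta = list()) {
  sub <- attr(times_fine, "sub") %||% 1L
  idx <- seq(1L, length(times_fine), by = sub)
  t_s <- times_fine[idx]
  x_true <- x_fine[idx]
  if (any(abs(x_fine * probe_stiffness(probe)) > FIXATION_LIMIT)) {
    cond <- structure(
      class = c("fixation_failure", "error", "condition"),
      list(message = sprintf(
        "fixation failure: instantaneous F_s %.1f uN exceeds the %.0f uN liquid-bridge limit",
        max(abs(x_fine)) * probe_stiffness(probe) * 1e6,
        FIXATION_LIMIT * 1e6), call = NULL))
    stop(cond)
  }
  x_noisy <- x_true + noise_px * probe$pixel_size *
    stats::rnorm(length(x_true))
  x_px <- if (quantize) quantize_deflection(probe, x_noisy)
          else x_noisy / probe$pixel_size
  x_q <- x_px * probe$pixel_size
  Fs <- probe_stiffness(probe) * x_q
  rec <- data.frame(
    time_s = t_s,
    Lm_um = Lm_fine[idx] * 1e6,
    x_px = x_px,
    x_um = x_q * 1e6,
    Fs_uN = Fs * 1e6,
    stim = as.integer(stim_fine[idx] > 0),
    medium = medium)
  if (!is.null(Fcmd_fine)) rec$Fcmd_uN <- Fcmd_fine[idx] * 1e6
  attr(rec, "probe") <- probe
  attr(rec, "params") <- params
  attr(rec, "protocol") <- protocol
  attr(rec, "x_subpixel_um") <- x_noisy * 1e6
  for (nm in names(extra_meta)) attr(rec, nm) <- extra_meta[[nm]]
  class(rec) <- c("recording", "data.frame")
  rec
}

fine_grid <- function(t_end, min_substeps = 1, feature_time = Inf,
                      camera_dt = CAMERA_DT) {
  sub <- max(min_substeps, ceiling(camera_dt / (feature_time / 100)))
  n_cam <- round(t_end / camera_dt)
  dt <- camera_dt / sub
  times <- (0:(n_cam * sub)) * dt
  attr(times, "sub") <- as.integer(sub)
  times
}

#' Simulate an oscillatory stretching run
#'
#' Drives the moving probe sinusoidally (strain cycling between 0 and
#' `amplitude_strain`), solves the quasi-static force balance against the
#' sensing probe at each step, and returns the camera-rate recording with
#' Gaussian deflection noise and integer-pixel quantization. With
#' `controlled = TRUE` the displacement is shaped by the model-predictive
#' force controller instead (see [run_closed_loop()]).
#'
#' A settling cycle precedes the `n_cycles` analysis cycles; analysis
#' functions drop it via the `settle_s` attribute.
#'
#' @param params A [plant_params()].
#' @param probe A [probe_spec()].
#' @param amplitude_strain Peak nominal strain (default 0.10).
#' @param frequency Loading frequency (Hz), typically 0.01--1.
#' @param n_cycles Number of analysis cycles (>= 3 for spectral analysis).
#' @param controlled Use the MPC force controller to shape `L_m`.
#' @param medium `"solution"` or `"air"`.
#' @param noise_px Deflection noise SD in pixels before quantization.
#' @param quantize Quantize the readout to integer pixels.
#' @param seed Optional integer seed for the measurement noise.
#' @param settle_cycles Cycles excluded from analysis (default 1).
#' @param pre_strain Static pre-strain applied (ramped in during settling)
#'   so the fiber stays in tension over the whole cycle; standard tensile
#'   dynamic-mechanical practice (default 0.05). Ignored when
#'   `controlled = TRUE` (the force command stays non-negative by
#'   construction).
#' @param ... Passed to [run_closed_loop()] when `controlled = TRUE`.
#' @return A `recording` data.frame (columns `time_s, Lm_um, x_px, x_um,
#'   Fs_uN, stim, medium`).
#' @export
run_oscillation <- function(params, probe, amplitude_strain = 0.10,
                            frequency = 0.1, n_cycles = 5,
                            controlled = FALSE,
                            medium = c("solution", "air"),
                            noise_px = 0.3, quantize = TRUE, seed = NULL,
                            settle_cycles = 1, pre_strain = 0.05, ...) {
  medium <- match.arg(medium)
  if (n_cycles < 3) stop("need n_cycles >= 3")
  settle_cycles_eff <- max(settle_cycles, 0.5)
  if (controlled) {
    cm <- complex_modulus(params, frequency, medium)
    peak <- min(cm$E_star * amplitude_strain * cross_section_area(params),
                FIXATION_LIMIT)
    return(run_closed_loop(params, probe, command_peak = peak,
                           frequency = frequency, n_cycles = n_cycles,
                           medium = medium, noise_px = noise_px,
                           quantize = quantize, seed = seed,
                           settle_cycles = settle_cycles, ...))
  }
  with_seed(seed, {
    period <- 1 / frequency
    t_end <- (n_cycles + settle_cycles) * period
    times <- fine_grid(t_end, feature_time = period)
    L0 <- params$rest_length
    # static pre-strain keeps the liquid-bridge contact loaded in tension
    # throughout the cycle (the dynamic stress of lossy fibers would
    # otherwise swing the force through zero)
    ramp <- pmin(times * frequency / settle_cycles_eff, 1)
    Lm <- L0 * (pre_strain * ramp +
                  amplitude_strain * (1 - cos(2 * pi * frequency * times)) / 2)
    sim <- integrate_balance(params, probe, times, Lm, medium = medium)
    camera_readout(params, probe, times, Lm, sim$x,
                   stim_fine = numeric(length(times)), medium = medium,
                   protocol = "oscillation", noise_px = noise_px,
                   quantize = quantize,
                   extra_meta = list(frequency = frequency,
                                     amplitude_strain = amplitude_strain,
                                     settle_s = settle_cycles * period,
                                     seed = seed))
  })
}

#' Simulate a slow length sweep (force--length protocol)
#'
#' Ramps the moving probe so the nominal strain rises linearly to
#' `max_strain`, optionally under sustained tetanic stimulation (5 Hz
#' train, fused activation). The strain--force curve recorded here is the
#' input for optimal-length and contractile-force extraction.
#'
#' @inheritParams run_oscillation
#' @param max_strain Final nominal strain (<= 0.3; the stretch is kept
#'   below 30%).
#' @param stimulate Apply a fused tetanic stimulation train during the ramp.
#' @param strain_rate Nominal strain rate of the ramp (1/s).
#' @return A `recording`.
#' @export
run_length_sweep <- function(params, probe, max_strain = 0.15,
                             stimulate = FALSE,
                             medium = c("solution", "air"),
                             strain_rate = 1e-3, noise_px = 0.3,
                             quantize = TRUE, seed = NULL) {
  medium <- match.arg(medium)
  if (max_strain > 0.3) stop("max_strain must be <= 0.3")
  if (stimulate && medium == "air")
    stop("stimulation requires the solution medium")
  with_seed(seed, {
    t_end <- max_strain / strain_rate
    times <- fine_grid(t_end, feature_time = if (stimulate)
      params$twitch_time * 10 else Inf)
    L0 <- params$rest_length
    Lm <- L0 * strain_rate * times
    act <- if (stimulate)
      activation_from_stimulus(pulse_train(5, t_end), times,
                               params$twitch_time)
    else numeric(length(times))
    sim <- integrate_balance(params, probe, times, Lm, activation = act,
                             medium = medium)
    camera_readout(params, probe, times, Lm, sim$x, stim_fine = act,
                   medium = medium, protocol = "ramp",
                   noise_px = noise_px, quantize = quantize,
                   extra_meta = list(max_strain = max_strain,
                                     strain_rate = strain_rate,
                                     stimulated = stimulate, seed = seed))
  })
}

#' Simulate electrical stimulation at fixed length
#'
#' Holds the moving probe at `hold_strain` and applies a square-wave pulse
#' train; twitches (1 Hz) or a fused tetanic plateau (5 Hz) appear as force
#' fluctuations on the sensing probe. Stimulation requires the solution
#' medium (the bath transmits the field).
#'
#' @inheritParams run_oscillation
#' @param hold_strain Nominal holding strain.
#' @param pulse_frequency Stimulation rate (Hz), 1--5 typical.
#' @param duration Train duration (s).
#' @return A `recording`.
#' @export
run_stimulation <- function(params, probe, hold_strain = 0.05,
                            pulse_frequency = 1, duration = 10,
                            medium = c("solution", "air"),
                            noise_px = 0.3, quantize = TRUE, seed = NULL) {
  medium <- match.arg(medium)
  if (medium == "air")
    stop("stimulation in air is not possible: the solution transmits the field")
  with_seed(seed, {
    times <- fine_grid(duration + 1,
                       feature_time = params$twitch_time * 10)
    L0 <- params$rest_length
    Lm <- rep(hold_strain * L0, length(times))
    act <- activation_from_stimulus(pulse_train(pulse_frequency, duration,
                                                start = 0.5),
                                    times, params$twitch_time)
    sim <- integrate_balance(params, probe, times, Lm, activation = act,
                             medium = medium)
    camera_readout(params, probe, times, Lm, sim$x, stim_fine = act,
                   medium = medium, protocol = "stimulation",
                   noise_px = noise_px, quantize = quantize,
                   extra_meta = list(pulse_frequency = pulse_frequency,
                                     hold_strain = hold_strain, seed = seed))
  })
}

#' Generate a seeded population of recordings over a condition grid
#'
#' Per-condition replicates with independent sub-seeds. Protocols:
#' `"oscillation"` (viscoelasticity, one recording per sample),
#' `"cf"` (paired passive + stimulated length sweeps) or `"both"`.
#' Non-measurable samples (cell spheres: no fiber to suspend) are listed in
#' the manifest but produce no recordings.
#'
#' @param grid A data.frame of conditions from [condition_grid()] (or of the
#'   same shape).
#' @param n_replicates Replicates per condition.
#' @param protocol `"oscillation"`, `"cf"` or `"both"`.
#' @param seed Integer master seed; replicate sub-seeds derive from it.
#' @param stage,culture_period Passed to [condition_to_params()].
#' @param probe A [probe_spec()] (default short preset).
#' @param medium Measurement medium.
#' @param ... Further arguments to the protocol runners (e.g. `noise_px`).
#' @return List with `recordings` (named list; for `"cf"` each element is a
#'   list of `passive` and `stimulated` recordings) and `manifest`
#'   (data.frame: sample_id, condition fields, seed, protocol, label,
#'   measurable).
#' @export
generate_population <- function(grid, n_replicates, protocol = "oscillation",
                                seed = 1, stage = NULL,
                                culture_period = "optimized",
                                probe = probe_preset("short"),
                                medium = "solution", ...) {
  protocol <- match.arg(protocol, c("oscillation", "cf", "both"))
  recs <- list()
  rows <- list()
  sid <- 0L
  for (ci in seq_len(nrow(grid))) {
    cond <- as.list(grid[ci, , drop = FALSE])
    for (r in seq_len(n_replicates)) {
      sid <- sid + 1L
      sub_seed <- (seed + 7919 * sid) %% .Machine$integer.max
      st <- condition_to_params(cond, seed = sub_seed, stage = stage,
                                culture_period = culture_period)
      id <- sprintf("s%04d", sid)
      rows[[sid]] <- data.frame(sample_id = id,
                                as.data.frame(cond[setdiff(names(cond), "grid")]),
                                grid = cond$grid, replicate = r,
                                seed = sub_seed, protocol = protocol,
                                label = st$label,
                                measurable = st$measurable)
      if (!st$measurable) next
      out <- list()
      if (protocol %in% c("oscillation", "both"))
        out$oscillation <- run_oscillation(st$params, probe,
                                           medium = medium,
                                           seed = sub_seed + 1, ...)
      if (protocol %in% c("cf", "both")) {
        # 10% ramp: past the optimal length but below the fixation limit
        # even for the stiffest, widest fibers
        out$passive <- run_length_sweep(st$params, probe, stimulate = FALSE,
                                        max_strain = 0.10, medium = medium,
                                        seed = sub_seed + 2, ...)
        out$stimulated <- run_length_sweep(st$params, probe,
                                           stimulate = TRUE,
                                           max_strain = 0.10, medium = medium,
                                           seed = sub_seed + 3, ...)
      }
      recs[[id]] <- if (length(out) == 1) out[[1]] else out
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest)
}
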