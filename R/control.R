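# Model-predictive force control of the moving probe.
#
# The supplementary design of the original instrument's controller is not
# public; this is a conventional receding-horizon reconstruction: a
# first-order-plus-gain discrete model identified from a calibration
# staircase, a quadratic program over a 10-step horizon with a hard bound
# keeping the probe force inside the liquid-bridge fixation window, and a
# 0.2 um actuator move quantum. Control runs at the 5 Hz camera rate, the
# feedback being the vision-derived (sub-pixel) deflection estimate.

#' Controller configuration
#'
#' @param horizon Prediction horizon in control steps (>= 1).
#' @param tracking_weight Weight on squared force-tracking error
#'   (per uN^2).
#' @param move_weight Weight on squared probe moves (per um^2). Useful
#'   moves are tens of um per step while tracking errors live at the uN
#'   scale, so the default 0.01 damps the per-step feedback without
#'   paralyzing the actuator.
#' @param force_limit Hard bound on the predicted probe force (N); the
#'   default 120 uN is the liquid-bridge adhesion, so the peak-to-peak
#'   force can never exceed it (force stays in [0, force_limit]).
#' @param step_time Control/camera period (s).
#' @param move_quantum Actuator minimum incremental movement (m),
#'   default 0.2 um.
#' @return A list of class `mpc_config`.
#' @export
mpc_config <- function(horizon = 10, tracking_weight = 1,
                       move_weight = 0.01, force_limit = 120e-6,
                       step_time = CAMERA_DT, move_quantum = 0.2e-6) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (tracking_weight <= 0 || move_weight <= 0) stop("weights must be > 0")
  if (force_limit <= 0) stop("force_limit must be > 0")
  structure(list(horizon = as.integer(horizon),
                 tracking_weight = tracking_weight,
                 move_weight = move_weight,
                 force_limit = force_limit,
                 step_time = step_time,
                 move_quantum = move_quantum),
            class = "mpc_config")
}

#' Identify a discrete control model from a calibration recording
#'
#' Least-squares fit of the first-order-plus-gain model
#' `F[k+1] = a F[k] + b dL_m[k]` to a small-amplitude calibration
#' recording. A purely elastic sample holds its force between moves, so
#' the fit recovers the integrator `a = 1` with `b` equal to the series
#' stiffness of probe and sample; viscous samples pull `a` below 1 and
#' inflate `b` with the step-rate drag response.
#'
#' @param probe A [probe_spec()] (kept for provenance; the fit works on the
#'   recorded force directly).
#' @param calibration_recording A `recording` with non-trivial probe moves.
#' @return List of class `plant_model` with `a`, `b` (N/m), residual SD
#'   `sigma` and the number of fitted steps.
#' @export
identify_plant <- function(probe, calibration_recording) {
  rec <- calibration_recording
  F <- rec$Fs_uN * 1e-6
  Lm <- rec$Lm_um * 1e-6
  n <- length(F)
  if (n < 5) stop("calibration recording too short")
  dL <- diff(Lm)
  if (all(abs(dL) < 1e-12))
    stop("rank-deficient calibration data: probe never moved")
  X <- cbind(F[-n], dL)
  y <- F[-1]
  qr_X <- qr(X)
  if (qr_X$rank < 2)
    stop("rank-deficient calibration data: cannot identify both coefficients")
  coef <- qr.coef(qr_X, y)
  res <- y - X %*% coef
  structure(list(a = unname(coef[1]), b = unname(coef[2]),
                 sigma = stats::sd(res), n = n - 1),
            class = "plant_model")
}

#' Run a small-amplitude calibration staircase
#'
#' Steps the moving probe through a short random staircase (sub-pixel
#' readout, noise configurable) to excite the plant for [identify_plant()].
#'
#' @param params A [plant_params()].
#' @param probe A [probe_spec()].
#' @param n_steps Number of staircase moves.
#' @param step_um Basic staircase step (um).
#' @param medium Measurement medium.
#' @param noise_px Deflection noise SD (px).
#' @param seed RNG seed.
#' @return A `recording`.
#' @export
run_calibration <- function(params, probe, n_steps = 60, step_um = 20,
                            medium = "solution", noise_px = 0, seed = NULL) {
  with_seed(seed, {
    moves <- sample(c(-1, 0, 1, 1, 2), n_steps, replace = TRUE) *
      step_um * 1e-6
    # small-amplitude excitation: keep the excursion within a 10-step band
    # so even stiff samples stay far below the fixation limit
    Lm <- pmin(pmax(cumsum(c(0, moves)), 0), 10 * step_um * 1e-6)
    times <- (seq_along(Lm) - 1) * CAMERA_DT
    attr(times, "sub") <- 1L
    sim <- integrate_balance(params, probe, times, Lm, medium = medium)
    camera_readout(params, probe, times, Lm, sim$x,
                   stim_fine = numeric(length(times)), medium = medium,
                   protocol = "calibration", noise_px = noise_px,
                   quantize = FALSE,
                   extra_meta = list(seed = seed))
  })
}

# Prediction matrices for F_hat = phi * F_now + Gamma %*% u over the horizon.
mpc_matrices <- function(a, b, H) {
  phi <- a^(seq_len(H))
  Gam <- matrix(0, H, H)
  for (i in seq_len(H))
    for (j in seq_len(i))
      Gam[i, j] <- a^(i - j) * b
  list(phi = phi, Gamma = Gam)
}

#' One receding-horizon control step
#'
#' Solves the quadratic program
#' `min sum w_t (F_hat - F_cmd)^2 + w_m dL^2` over the horizon subject to
#' `0 <= F_hat <= force_limit`, and returns the first move quantized to the
#' actuator granularity. An infeasible program falls back to a zero move
#' with a flag.
#'
#' @param config An [mpc_config()].
#' @param plant A `plant_model` from [identify_plant()].
#' @param F_now Current model-consistent force state (N); with offset-free
#'   correction this is the measurement minus the current disturbance
#'   estimate.
#' @param cmd Command window: forces (N) for the next `horizon` steps
#'   (recycled if shorter).
#' @param disturbance Output-disturbance estimate added to the predictions
#'   over the horizon (N; scalar or length `horizon`).
#' @param u_plan Optional planned feedforward moves over the horizon (m);
#'   the program optimizes a correction around them and the constraints
#'   apply to the total.
#' @return List with `move` (total first move, m, integer multiple of the
#'   move quantum) and `feasible` (logical).
#' @export
mpc_step <- function(config, plant, F_now, cmd, disturbance = 0,
                     u_plan = NULL) {
  H <- config$horizon
  cmd <- rep_len(cmd, H)
  dvec <- rep_len(disturbance, H)
  u_plan <- if (is.null(u_plan)) numeric(H) else rep_len(u_plan, H)
  M <- mpc_matrices(plant$a, plant$b, H)
  Fs <- 1e-6   # natural scales: uN and um
  us <- 1e-6
  wt <- config$tracking_weight / Fs^2
  wm <- config$move_weight / us^2
  # predicted output with the planned moves and no correction
  free <- M$phi * F_now + dvec + as.numeric(M$Gamma %*% u_plan)
  Hmat <- 2 * (wt * crossprod(M$Gamma) + wm * diag(H))
  fvec <- 2 * wt * crossprod(M$Gamma, free - cmd)
  u <- tryCatch(-solve(Hmat, fvec), error = function(e) NULL)
  feasible <- TRUE
  lim <- config$force_limit
  ok <- function(u) {
    Fh <- free + M$Gamma %*% u
    all(Fh <= lim + 1e-12) && all(Fh >= -1e-12)
  }
  if (is.null(u) || !ok(u)) {
    A <- rbind(M$Gamma, -M$Gamma)
    bvec <- c(rep(lim, H) - free, free)
    u <- tryCatch(
      pracma::quadprog(Hmat, as.numeric(fvec), A = A, b = bvec)$xmin,
      error = function(e) NULL)
    if (is.null(u)) {
      u <- numeric(H)
      feasible <- FALSE
    }
  }
  move <- round((u_plan[1] + u[1]) / config$move_quantum) *
    config$move_quantum
  list(move = move, feasible = feasible)
}

#' Closed-loop force-tracked cyclic loading
#'
#' Tracks a sinusoidal force command with peak `command_peak` (midline at
#' half peak, starting at the peak so camera samples land on command
#' maxima). Tracking authority lives in a per-cycle harmonic adaptation of
#' the probe displacement waveform (the adaptive sinusoidal force control
#' used by commercial dynamic mechanical analyzers); the receding-horizon
#' program acts as the constraint governor around the planned moves, with
#' its plant model identified from an automatic calibration staircase
#' unless supplied. Commands are clipped below the fixation limit (5%
#' guard band) before tracking; settling cycles (frequency-dependent,
#' `max(6, 15 f)`) are flagged via the `settle_s` attribute and excluded
#' from analysis.
#'
#' @param ilc_gain Per-cycle Newton-step gain of the waveform adaptation
#'   (0 < gain <= 1).
#'
#' @inheritParams run_oscillation
#' @param command_peak Peak command force (N).
#' @param config An [mpc_config()].
#' @param plant_model Optional pre-identified `plant_model`.
#' @return A `recording` with an extra `Fcmd_uN` column.
#' @export
run_closed_loop <- function(params, probe, command_peak, frequency,
                            n_cycles = 5, medium = c("solution", "air"),
                            noise_px = 0.3, quantize = TRUE, seed = NULL,
                            settle_cycles = NULL, config = mpc_config(),
                            plant_model = NULL, ilc_gain = 0.8) {
  # waveform adaptation needs a fixed wall-clock allowance (~15 s of
  # updates), so fast commands get more settling cycles
  settle_cycles <- settle_cycles %||% max(6, ceiling(15 * frequency))
  medium <- match.arg(medium)
  with_seed(seed, {
    if (is.null(plant_model)) {
      cal <- run_calibration(params, probe, medium = medium,
                             noise_px = noise_px)
      plant_model <- identify_plant(probe, cal)
    }
    period <- 1 / frequency
    t_end <- (n_cycles + settle_cycles) * period
    dt_c <- config$step_time
    n_ctrl <- round(t_end / dt_c)
    t_cam <- (0:n_ctrl) * dt_c
    cmd_fun <- function(t) {
      # guard band below the hard limit absorbs quantization and observer
      # transients so the recorded peak-to-peak never exceeds the limit
      pk <- min(command_peak, 0.95 * config$force_limit)
      pk / 2 * (1 + cos(2 * pi * frequency * t))
    }
    sub <- max(1L, ceiling(dt_c / (period / 100)))
    k_probe <- probe_stiffness(probe)
    stepper <- make_stepper(params, probe, medium)
    # within-cycle tracking corrections through the mismatched first-order
    # model destabilize slow commands (the true plant integrates moves);
    # tracking authority therefore lives in the per-cycle waveform
    # adaptation below, and the receding-horizon program acts as the
    # constraint governor around the planned moves
    cfg_gov <- config
    cfg_gov$tracking_weight <- config$tracking_weight * 1e-8

    Lm_now <- 0
    x_cam <- numeric(n_ctrl + 1)
    Lm_cam <- numeric(n_ctrl + 1)
    feasible <- logical(n_ctrl + 1)
    x_now <- stepper(Inf, 0, 0)
    noise <- noise_px * probe$pixel_size * stats::rnorm(n_ctrl + 1)
    x_cam[1] <- x_now + noise[1]
    Lm_cam[1] <- 0
    feasible[1] <- TRUE
    # Outer loop: per-cycle harmonic adaptation of the displacement
    # waveform. The command is a single tone, so the steady-state probe
    # motion is parametrized as Lm(t) = m + Re(A e^{iwt}); after every
    # completed cycle the measured mean/fundamental phasors of force and
    # displacement give the operating-point gain, and a Newton step moves
    # the waveform toward the command (this is the adaptive sinusoidal
    # force control scheme of commercial dynamic mechanical analyzers).
    # The inner receding-horizon program adds damped feedback around the
    # plan and enforces the hard fixation bound on the total move.
    per_steps <- period / dt_c
    n_bins <- if (abs(per_steps - round(per_steps)) < 1e-6)
      max(1L, as.integer(round(per_steps))) else 1L
    w <- 2 * pi * frequency
    m_tgt <- 0; A_tgt <- 0 + 0i          # adapted waveform parameters
    m_cur <- 0; A_cur <- 0 + 0i          # smoothed (applied) parameters
    blend <- 2 / n_bins                  # per-step approach rate: updates
    adapt_on <- FALSE                    # spread over about half a cycle
    F_hist <- numeric(n_bins); Lm_hist <- numeric(n_bins)
    F0p <- NA_real_; F1p <- NA_complex_; Lm0p <- NA_real_; Lm1p <- NA_complex_
    G1 <- complex(real = plant_model$b)  # initial gain guesses
    G0 <- plant_model$b
    lm_target <- function(t) m_cur + Re(A_cur * exp(1i * w * t))
    for (kk in seq_len(n_ctrl)) {
      F_meas <- k_probe * (x_now + noise[kk])
      b_now <- (kk - 1L) %% n_bins + 1L
      F_hist[b_now] <- F_meas
      Lm_hist[b_now] <- Lm_now
      # adapt once per block; a block spans enough cycles (>= 2 s) that
      # the phasors of its final cycle are free of the previous update's
      # viscoelastic transient
      block_cycles <- max(1, ceiling(2 * frequency))
      cycle_idx <- (kk - 1L) %/% n_bins + 1L
      # the waveform is frozen once settling ends so the analysis cycles
      # are stationary
      at_update <- b_now == n_bins && n_bins >= 4L &&
        cycle_idx %% block_cycles == 0L &&
        cycle_idx <= settle_cycles - block_cycles + 1L
      if (at_update) {
        tb <- t_cam[(kk - n_bins + 1):kk]
        ph <- exp(-1i * w * tb)
        F0 <- mean(F_hist); F1 <- 2 * mean(F_hist * ph)
        Lm0 <- mean(Lm_hist); Lm1 <- 2 * mean(Lm_hist * ph)
        if (!is.na(F0p)) {  # refine gains from the operating-point change
          if (Mod(Lm1 - Lm1p) > 1e-9) G1 <- (F1 - F1p) / (Lm1 - Lm1p)
          if (abs(Lm0 - Lm0p) > 1e-9) G0 <- (F0 - F0p) / (Lm0 - Lm0p)
        }
        pk <- min(command_peak, 0.95 * config$force_limit)
        m_tgt <- Lm0 + ilc_gain * (pk / 2 - F0) / G0
        A_tgt <- Lm1 + ilc_gain * (pk / 2 - F1) / G1
        F0p <- F0; F1p <- F1; Lm0p <- Lm0; Lm1p <- Lm1
        adapt_on <- TRUE
      }
      if (adapt_on) {
        m_cur <- m_cur + blend * (m_tgt - m_cur)
        A_cur <- A_cur + blend * (A_tgt - A_cur)
      }
      tt <- t_cam[kk] + dt_c * (0:config$horizon)
      u_plan <- if (adapt_on) {
        plan_pos <- lm_target(tt[-1])
        diff(c(Lm_now, plan_pos))
      } else NULL
      cmd <- cmd_fun(tt[-1])
      st <- mpc_step(cfg_gov, plant_model, F_meas, cmd, u_plan = u_plan)
      # actuator ramps linearly to the new position over the interval
      for (s in seq_len(sub)) {
        Lm_s <- Lm_now + st$move * s / sub
        x_now <- stepper(dt_c / sub, Lm_s, 0)
      }
      Lm_now <- Lm_now + st$move
      x_cam[kk + 1] <- x_now + noise[kk + 1]
      Lm_cam[kk + 1] <- Lm_now
      feasible[kk + 1] <- st$feasible
    }
    if (any(abs(k_probe * x_cam) > FIXATION_LIMIT + 1e-9))
      stop(structure(class = c("fixation_failure", "error", "condition"),
                     list(message = "fixation failure under closed loop",
                          call = NULL)))
    x_px <- if (quantize) quantize_deflection(probe, x_cam)
            else x_cam / probe$pixel_size
    x_q <- x_px * probe$pixel_size
    rec <- data.frame(time_s = t_cam,
                      Lm_um = Lm_cam * 1e6,
                      x_px = x_px,
                      x_um = x_q * 1e6,
                      Fs_uN = k_probe * x_q * 1e6,
                      stim = 0L,
                      medium = medium,
                      Fcmd_uN = cmd_fun(t_cam) * 1e6)
    attr(rec, "probe") <- probe
    attr(rec, "params") <- params
    attr(rec, "protocol") <- "oscillation_controlled"
    attr(rec, "frequency") <- frequency
    attr(rec, "settle_s") <- settle_cycles * period
    attr(rec, "seed") <- seed
    attr(rec, "plant_model") <- plant_model
    attr(rec, "x_subpixel_um") <- x_cam * 1e6
    attr(rec, "all_feasible") <- all(feasible)
    class(rec) <- c("recording", "data.frame")
    rec
  })
}

#' Open-loop (uncontrolled) cyclic loading sized from the static gain
#'
#' Applies the naive sinusoidal displacement that would produce
#' `amplitude_force` on a purely elastic sample (static series stiffness of
#' probe and equilibrium spring). On a viscoelastic plant the rate-dependent
#' stress makes the achieved force overshoot the intended amplitude and
#' distorts the waveform -- the motivation for force control.
#'
#' @inheritParams run_oscillation
#' @param amplitude_force Intended peak force (N).
#' @return A `recording`.
#' @export
run_open_loop <- function(params, probe, amplitude_force, frequency,
                          n_cycles = 5, medium = c("solution", "air"),
                          noise_px = 0.3, quantize = TRUE, seed = NULL,
                          settle_cycles = 1) {
  medium <- match.arg(medium)
  k <- probe_stiffness(probe)
  k_s0 <- cross_section_area(params) * params$equilibrium_modulus /
    params$rest_length
  k_series <- k * k_s0 / (k + k_s0)
  Lm_peak <- amplitude_force / k_series
  with_seed(seed, {
    period <- 1 / frequency
    t_end <- (n_cycles + settle_cycles) * period
    times <- fine_grid(t_end, feature_time = period)
    Lm <- Lm_peak * (1 - cos(2 * pi * frequency * times)) / 2
    sim <- integrate_balance(params, probe, times, Lm, medium = medium)
    camera_readout(params, probe, times, Lm, sim$x,
                   stim_fine = numeric(length(times)), medium = medium,
                   protocol = "oscillation_open_loop",
                   noise_px = noise_px, quantize = quantize,
                   extra_meta = list(frequency = frequency,
                                     settle_s = settle_cycles * period,
                                     seed = seed))
  })
}
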