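# Measurement pipeline: stress/strain construction, single-frequency
# spectral extraction of E* and tan-delta, Lissajous modulus, and
# contractile-force summaries.

#' Stress and strain time series from a recording
#'
#' `sigma_s = 4 F_s / (pi d_0^2)` and `eps_s = (L_m - x) / L_0`: the
#' imposed stress over the initial core cross-section and the core strain
#' (probe motion minus probe deflection over the initial length). `d_0` is
#' the initial core diameter throughout; it is not re-measured.
#'
#' @param recording A `recording`.
#' @param d0 Initial core diameter (m); defaults to the generating plant's.
#' @param L0 Initial core length (m); defaults likewise.
#' @return data.frame with `time_s`, `sigma_Pa`, `epsilon`.
#' @export
stress_strain <- function(recording, d0 = NULL, L0 = NULL) {
  need <- c("time_s", "Lm_um", "x_um", "Fs_uN")
  miss <- setdiff(need, names(recording))
  if (length(miss))
    stop("recording lacks required columns: ", paste(miss, collapse = ", "))
  p <- attr(recording, "params")
  d0 <- d0 %||% p$diameter
  L0 <- L0 %||% p$rest_length
  if (is.null(d0) || is.null(L0) || d0 <= 0 || L0 <= 0)
    stop("need positive d0 and L0 (not recoverable from this recording)")
  data.frame(
    time_s = recording$time_s,
    sigma_Pa = 4 * recording$Fs_uN * 1e-6 / (pi * d0^2),
    epsilon = (recording$Lm_um - recording$x_um) * 1e-6 / L0)
}

# Single-bin discrete Fourier projection at exactly f over t (uniform).
project_tone <- function(y, t, f) {
  ph <- exp(-2i * pi * f * t)
  z <- 2 * sum((y - mean(y)) * ph) / length(y)
  list(amplitude = Mod(z), phase = Arg(z))
}

#' Extract complex modulus and loss factor at the analysis frequency
#'
#' Projects stress and strain onto the single tone at exactly `f_m` (not
#' the nearest FFT grid bin) over an integer number of periods, after mean
#' removal; partial trailing cycles are dropped (leakage flag set when any
#' samples had to be discarded). `E* = A_sigma / A_eps`;
#' `tan delta = tan(phi_sigma - phi_eps)` with the phase difference wrapped
#' into `[0, pi/2)` -- a negative raw difference (possible under noise for
#' nearly elastic samples) is clamped to zero and flagged.
#'
#' @param sigma Stress series (Pa).
#' @param epsilon Strain series (dimensionless).
#' @param time Uniform time grid (s).
#' @param f_m Analysis frequency (Hz), default 0.1 (the cell
#'   mechanosensing frequency).
#' @return List of class `visco_summary`: `E_star` (Pa), `tan_delta`,
#'   `f_m`, `A_sigma`, `A_eps`, `phi_sigma`, `phi_eps`, `flags`.
#' @export
extract_viscoelasticity <- function(sigma, epsilon, time, f_m = 0.1) {
  n <- length(time)
  stopifnot(length(sigma) == n, length(epsilon) == n)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("time grid must be uniform")
  dt <- dt[1]
  period <- 1 / f_m
  n_per <- floor((n * dt) / period + 1e-9)
  if (n_per < 3) stop("record must cover at least 3 full periods of f_m")
  n_keep <- round(n_per * period / dt)
  flags <- character()
  if (n_keep < n - 0.5) flags <- c(flags, "leakage_trimmed")
  idx <- seq_len(min(n_keep, n))
  ps <- project_tone(sigma[idx], time[idx], f_m)
  pe <- project_tone(epsilon[idx], time[idx], f_m)
  if (pe$amplitude < 1e-6 * max(abs(epsilon - mean(epsilon)), 1e-12) ||
      pe$amplitude == 0)
    stop("no strain excitation at f_m")
  dphi <- ps$phase - pe$phase
  dphi <- atan2(sin(dphi), cos(dphi))   # wrap to (-pi, pi]
  if (dphi < 0) { dphi <- 0; flags <- c(flags, "negative_phase_clamped") }
  if (dphi >= pi / 2) { dphi <- pi / 2 * 0.999; flags <- c(flags, "phase_clipped") }
  structure(list(E_star = ps$amplitude / pe$amplitude,
                 tan_delta = tan(dphi),
                 f_m = f_m,
                 A_sigma = ps$amplitude, A_eps = pe$amplitude,
                 phi_sigma = ps$phase, phi_eps = pe$phase,
                 flags = flags),
            class = "visco_summary")
}

#' Lissajous (hysteresis-loop) modulus
#'
#' Amplitude-ratio modulus from the final steady-state loop of the
#' stress--strain curve: `E = (sigma_max - sigma_min) / (eps_max -
#' eps_min)` over the last full period. For a linear viscoelastic steady
#' state it equals `|E*|`.
#'
#' @inheritParams extract_viscoelasticity
#' @return Modulus in Pa.
#' @export
lissajous_modulus <- function(sigma, epsilon, time, f_m = 0.1) {
  t_end <- time[length(time)]
  idx <- which(time >= t_end - 1 / f_m - 1e-9)
  if (length(idx) < 4) stop("need at least one complete cycle")
  de <- max(epsilon[idx]) - min(epsilon[idx])
  if (de <= 0) stop("constant strain: Lissajous modulus undefined")
  (max(sigma[idx]) - min(sigma[idx])) / de
}

# Drop the settling portion of a recording (attribute settle_s).
drop_settle <- function(recording) {
  s <- attr(recording, "settle_s")
  if (is.null(s) || s <= 0) return(recording)
  keep <- recording$time_s >= s - 1e-9
  out <- recording[keep, , drop = FALSE]
  for (a in c("probe", "params", "protocol", "frequency", "settle_s"))
    attr(out, a) <- attr(recording, a)
  class(out) <- class(recording)
  out
}

#' Full viscoelasticity analysis of one oscillation recording
#'
#' Drops the settling cycle, builds stress/strain, and extracts `E*`,
#' `tan delta` and the Lissajous modulus at `f_m`.
#'
#' @param recording A `recording` from [run_oscillation()] (or closed-loop
#'   equivalent).
#' @param f_m Analysis frequency (Hz); defaults to the recording's loading
#'   frequency, falling back to 0.1.
#' @param d0,L0 Geometry overrides (m).
#' @return A `visco_summary` with an extra `E_lissajous` field.
#' @export
analyze_recording <- function(recording, f_m = NULL, d0 = NULL, L0 = NULL) {
  f_m <- f_m %||% attr(recording, "frequency") %||% 0.1
  rec <- drop_settle(recording)
  ss <- stress_strain(rec, d0 = d0, L0 = L0)
  vs <- extract_viscoelasticity(ss$sigma_Pa, ss$epsilon, ss$time_s, f_m)
  vs$E_lissajous <- lissajous_modulus(ss$sigma_Pa, ss$epsilon, ss$time_s, f_m)
  vs
}

#' Optimal length and contractile-force summary from paired ramps
#'
#' Subtracts the passive (unstimulated) force--strain curve from the
#' stimulated one; the optimal length `L_o` is the strain maximizing the
#' active difference, `F_s_at_Lo` the stimulated force there, and `F_pmax`
#' the maximal passive force. Mismatched strain grids are linearly
#' interpolated (flagged).
#'
#' @param stimulated,passive `recording`s from [run_length_sweep()] over
#'   the same strain ramp, with and without stimulation.
#' @param d0,L0 Geometry overrides (m).
#' @param smooth_window Moving-average window (samples) applied to the
#'   active difference before the argmax (odd; default 25).
#' @return List of class `contraction_summary`: `Lo_strain`, `Fs_at_Lo`
#'   (N), `passive_at_Lo` (N), `F_pmax` (N), `active_peak` (N),
#'   `cf_generated` (provisional: active peak > 0 within noise), `flags`.
#' @export
find_optimal_length <- function(stimulated, passive, d0 = NULL, L0 = NULL,
                                smooth_window = 25) {
  p <- attr(stimulated, "params")
  L0 <- L0 %||% p$rest_length
  eps_s <- (stimulated$Lm_um - stimulated$x_um) * 1e-6 / L0
  eps_p <- (passive$Lm_um - passive$x_um) * 1e-6 / L0
  F_s <- stimulated$Fs_uN * 1e-6
  F_p <- passive$Fs_uN * 1e-6
  flags <- character()
  if (length(eps_p) != length(eps_s) ||
      max(abs(range(eps_p) - range(eps_s))) > 0.005)
    flags <- c(flags, "grid_interpolated")
  F_p_on_s <- stats::approx(eps_p, F_p, xout = eps_s, rule = 2)$y
  active <- F_s - F_p_on_s
  if (smooth_window > 1) {
    w <- min(smooth_window, length(active))
    if (w %% 2 == 0) w <- w - 1
    sm <- stats::filter(active, rep(1 / w, w), sides = 2)
    active_sm <- as.numeric(sm)
    active_sm[is.na(active_sm)] <- active[is.na(active_sm)]
  } else active_sm <- active
  # ignore the near-zero-strain start where both curves are flat
  valid <- eps_s > 0.005
  i_max <- which(valid)[which.max(active_sm[valid])]
  structure(list(Lo_strain = eps_s[i_max],
                 Fs_at_Lo = F_s[i_max],
                 passive_at_Lo = F_p_on_s[i_max],
                 F_pmax = max(F_p),
                 active_peak = active_sm[i_max],
                 cf_generated = active_sm[i_max] > 0.5e-6,
                 flags = flags),
            class = "contraction_summary")
}

#' Contractile-force criterion value against a diameter-matched baseline
#'
#' The screening criterion subtracts the average passive tension `F_sa` of
#' same-diameter samples from the force at optimal length; contraction is
#' called when the difference exceeds the threshold (default 3 uN).
#'
#' @param Fs_at_Lo Force at optimal length of the sample (N).
#' @param group_passive Passive forces (at their optimal lengths) of the
#'   same-diameter group (N); when only the sample itself is available its
#'   own passive value is used and a flag is set.
#' @param threshold Criterion threshold (N), default 3 uN.
#' @return List with `cf_diff` (N), `cf_generated`, `Fsa` (N), `flags`.
#' @export
cf_criterion_value <- function(Fs_at_Lo, group_passive, threshold = 3e-6) {
  flags <- character()
  if (length(group_passive) < 2) flags <- c(flags, "singleton_group")
  Fsa <- mean(group_passive)
  diff <- Fs_at_Lo - Fsa
  list(cf_diff = diff, cf_generated = diff > threshold, Fsa = Fsa,
       flags = flags)
}

#' Twitch / tetanus summary of a stimulation recording
#'
#' @param recording A `recording` from [run_stimulation()].
#' @return List with `baseline` (N), `peak` (N) and `fluctuation_peak`
#'   (peak minus baseline, N).
#' @export
summarize_stimulation <- function(recording) {
  F <- recording$Fs_uN * 1e-6
  pre <- which(recording$stim == 0 & recording$time_s <
                 min(recording$time_s[recording$stim > 0], Inf))
  baseline <- if (length(pre)) mean(F[pre]) else min(F)
  list(baseline = baseline, peak = max(F),
       fluctuation_peak = max(F) - baseline)
}

#' Per-sample summary table of a generated population
#'
#' Runs the analysis pipeline over each measurable sample of a
#' [generate_population()] result: viscoelasticity for oscillation
#' recordings, optimal-length / contractile-force extraction for paired
#' sweeps, and the diameter-grouped CF criterion difference.
#'
#' @param population A list with `recordings` and `manifest`.
#' @param f_m Analysis frequency (Hz).
#' @param cf_threshold CF criterion threshold (N).
#' @return data.frame: one row per sample with columns `sample_id`,
#'   condition fields, `E_star_kPa`, `tan_delta`, `E_lissajous_kPa`,
#'   `Lo_strain`, `Fs_at_Lo_uN`, `Fsa_uN`, `cf_diff_uN`, `cf_generated`,
#'   `flags`.
#' @export
analyze_population <- function(population, f_m = 0.1, cf_threshold = 3e-6) {
  man <- population$manifest
  out <- list()
  cf_rows <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$sample_id[i]
    row <- man[i, , drop = FALSE]
    row$E_star_kPa <- NA_real_
    row$tan_delta <- NA_real_
    row$E_lissajous_kPa <- NA_real_
    row$Lo_strain <- NA_real_
    row$Fs_at_Lo_uN <- NA_real_
    row$passive_at_Lo_uN <- NA_real_
    row$diameter_grp_um <- NA_real_
    row$flags <- ""
    rec <- population$recordings[[id]]
    if (!is.null(rec) && man$measurable[i]) {
      recs <- if (inherits(rec, "recording")) list(oscillation = rec) else rec
      if (!is.null(recs$oscillation)) {
        vs <- analyze_recording(recs$oscillation, f_m = f_m)
        row$E_star_kPa <- vs$E_star / 1e3
        row$tan_delta <- vs$tan_delta
        row$E_lissajous_kPa <- vs$E_lissajous / 1e3
        row$flags <- paste(vs$flags, collapse = ";")
      }
      if (!is.null(recs$stimulated) && !is.null(recs$passive)) {
        cs <- find_optimal_length(recs$stimulated, recs$passive)
        row$Lo_strain <- cs$Lo_strain
        row$Fs_at_Lo_uN <- cs$Fs_at_Lo * 1e6
        row$passive_at_Lo_uN <- cs$passive_at_Lo * 1e6
        p <- attr(recs$stimulated, "params")
        row$diameter_grp_um <- round(p$diameter * 1e6)
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # diameter-grouped CF criterion
  res$Fsa_uN <- NA_real_
  res$cf_diff_uN <- NA_real_
  res$cf_generated <- NA
  has_cf <- !is.na(res$Fs_at_Lo_uN)
  for (g in unique(res$diameter_grp_um[has_cf])) {
    sel <- which(has_cf & res$diameter_grp_um == g)
    grp_passive <- res$passive_at_Lo_uN[sel] * 1e-6
    for (j in sel) {
      cv <- cf_criterion_value(res$Fs_at_Lo_uN[j] * 1e-6, grp_passive,
                               threshold = cf_threshold)
      res$Fsa_uN[j] <- cv$Fsa * 1e6
      res$cf_diff_uN[j] <- cv$cf_diff * 1e6
      res$cf_generated[j] <- cv$cf_generated
      if (length(cv$flags))
        res$flags[j] <- paste(c(res$flags[j], cv$flags), collapse = ";")
    }
  }
  res
}
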