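# e0/ms expressed in microamps
.E0_PER_MS_UA <- 1.602176634e-10

#' Acquisition noise model for synthetic recordings
#'
#' @param gaussian_sd standard deviation of additive white Gaussian noise,
#'   as a fraction of the unquenched intensity `F0` (>= 0).
#' @param drift_slope linear baseline drift, fraction of `F0` per second.
#' @param bleach_rate slow photobleaching rate (1/s, >= 0), applied as a
#'   multiplicative exponential decay.
#' @param seed integer seed; sweep-level seeds are derived as `seed + sweep
#'   index` by the generators.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 0, drift_slope = 0, bleach_rate = 0,
                        seed = 1L) {
  if (gaussian_sd < 0) stop("gaussian_sd must be >= 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(list(gaussian_sd = gaussian_sd, drift_slope = drift_slope,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Default noise model for a preset
#'
#' The per-sweep Gaussian noise standard deviation defaults to 10% of the
#' preset's pulse-response amplitude (so four-sweep averaging halves it, as
#' in acquisition practice), with a small linear drift and slow
#' photobleaching.
#'
#' @param preset a [make_preset()] result.
#' @param seed integer master seed.
#' @return a [noise_model()].
#' @export
default_noise_model <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "construct_preset"))
  amp_frac <- abs(preset$target_dFF0_at_80mV) / 100
  noise_model(gaussian_sd = 0.1 * amp_frac,
              drift_slope = 1e-4,
              bleach_rate = 0.01,
              seed = seed)
}

#' Generate one synthetic sweep recording from a preset
#'
#' Forward-simulates the occupancies under the protocol (starting from the
#' steady state at the protocol's holding potential), forms the recorded
#' intensity as background plus the channel-coupled ensemble fluorescence,
#' `F0 * (b + (1 - b) * sum_i P_i(t) g_i)`, adds the fast voltage-independent
#' residual step for "no effect" presets, applies photobleaching
#' (multiplicative `exp(-rate t)`), linear drift and additive Gaussian
#' noise, and computes the gating current from the same occupancy solution.
#' Deterministic given the noise seed.
#'
#' @param preset a [make_preset()] result.
#' @param protocol a [voltage_protocol()].
#' @param noise a [noise_model()]; default [default_noise_model()] of the
#'   preset.
#' @param n_channels number of channels contributing gating current
#'   (default 1e9, giving sub-microamp currents).
#' @return a [sweep_recording()] with fluorescence and gating current.
#' @export
generate_sweep <- function(preset, protocol,
                           noise = default_noise_model(preset),
                           n_channels = 1e9) {
  stopifnot(inherits(preset, "construct_preset"),
            inherits(protocol, "voltage_protocol"),
            inherits(noise, "noise_model"))
  occ <- solve_occupancies(preset$scheme, protocol)
  t <- occ$times
  g <- quench_factor(abs(preset$positions - preset$geometry$x_w),
                     preset$geometry$lambda_half)
  F0 <- preset$geometry$F0
  b <- preset$background_fraction
  f <- F0 * (b + (1 - b) * as.numeric(occ$probabilities %*% g))
  if (!is.null(preset$residual)) {
    onset <- pulse_onset(protocol)
    r <- preset$residual$amplitude_percent / 100 * f[1]
    on <- t >= onset
    f[on] <- f[on] + r * (1 - exp(-(t[on] - onset) / preset$residual$tau_ms))
  }
  f <- f * exp(-noise$bleach_rate * t / 1000)
  f <- f + noise$drift_slope * (t / 1000) * F0
  f <- .with_seed(noise$seed,
                  f + stats::rnorm(length(f), 0, noise$gaussian_sd * F0))
  ig <- gating_current(occ, preset$scheme, n_channels)$I_g * .E0_PER_MS_UA
  sweep_recording(protocol, f, gating_current = ig, n_averaged = 1L,
                  construct_label = preset$label,
                  meta = list(seed = noise$seed,
                              preset = preset$label,
                              noise_free = noise$gaussian_sd == 0 &&
                                noise$drift_slope == 0 &&
                                noise$bleach_rate == 0))
}

#' Generate a set of consecutively acquired sweeps
#'
#' Repeats [generate_sweep()] with per-sweep seeds `noise$seed + i`,
#' emulating consecutive acquisition of `n_sweeps` traces for averaging.
#'
#' @inheritParams generate_sweep
#' @param n_sweeps number of sweeps (default 4, the usual averaging depth).
#' @return list of [sweep_recording()]s.
#' @export
generate_sweep_set <- function(preset, protocol,
                               noise = default_noise_model(preset),
                               n_sweeps = 4L, n_channels = 1e9) {
  lapply(seq_len(n_sweeps), function(i) {
    ni <- noise; ni$seed <- noise$seed + i
    generate_sweep(preset, protocol, ni, n_channels)
  })
}

#' Generate a family of activation or deactivation protocols
#'
#' Activation: holding baseline, test pulse, return to holding.
#' Deactivation: holding baseline, a fixed conditioning depolarization,
#' test pulse, return to holding. One protocol per test voltage.
#'
#' @param kind "activation" or "deactivation".
#' @param voltages test potentials (mV), e.g. `seq(-160, 80, by = 40)`.
#' @param holding holding potential (mV), default -120.
#' @param pulse_ms test-pulse duration (ms).
#' @param baseline_ms pre-pulse holding duration (ms), default 600.
#' @param tail_ms post-pulse holding duration (ms), default 100.
#' @param conditioning_mV,conditioning_ms conditioning depolarization for
#'   deactivation families (default +80 mV, 50 ms).
#' @param sample_interval sampling interval (ms); default 0.02 (50 kHz).
#' @return named list of [voltage_protocol()]s (names are the voltages).
#' @export
generate_protocol_family <- function(kind = c("activation", "deactivation"),
                                     voltages, holding = -120,
                                     pulse_ms = 100, baseline_ms = 600,
                                     tail_ms = 100, conditioning_mV = 80,
                                     conditioning_ms = 50,
                                     sample_interval = 0.02) {
  kind <- match.arg(kind)
  if (length(voltages) < 1L) stop("need at least one test voltage")
  out <- lapply(voltages, function(v) {
    seg <- if (kind == "activation") {
      data.frame(duration_ms = c(baseline_ms, pulse_ms, tail_ms),
                 voltage_mV = c(holding, v, holding))
    } else {
      data.frame(duration_ms = c(baseline_ms, conditioning_ms, pulse_ms, tail_ms),
                 voltage_mV = c(holding, conditioning_mV, v, holding))
    }
    voltage_protocol(seg, holding_voltage = holding,
                     sample_interval = sample_interval)
  })
  names(out) <- as.character(voltages)
  out
}

#' Generate grouped recordings for a Cole-Moore prepulse experiment
#'
#' One group of sweeps per prepulse duration, all sharing an identical test
#' pulse: holding baseline, hyperpolarizing prepulse of variable duration,
#' test pulse, return to holding. Seeds are fixed per group
#' (`noise$seed + 1000 * group + sweep`).
#'
#' @param preset a [make_preset()] result; a scheme with a deep closed
#'   state (e.g. the `"deep-closed"` preset) is required for an actual
#'   Cole-Moore slowing.
#' @param prepulse_voltage prepulse potential (mV), default -160.
#' @param durations prepulse durations in ms, default `c(80, 1000, 5000)`.
#' @param test_voltage,test_ms test pulse (default +80 mV, 100 ms).
#' @param holding holding potential (mV), default -120.
#' @param baseline_ms,tail_ms holding segments around the pulses.
#' @param noise a [noise_model()].
#' @param n_sweeps sweeps per group (default 4).
#' @param sample_interval sampling interval (ms), default 0.1.
#' @return object of class `cole_moore_set`: named list `groups` (one list
#'   of sweeps per duration) plus the condition parameters.
#' @export
generate_cole_moore_set <- function(preset, prepulse_voltage = -160,
                                    durations = c(80, 1000, 5000),
                                    test_voltage = 80, test_ms = 100,
                                    holding = -120, baseline_ms = 600,
                                    tail_ms = 100,
                                    noise = default_noise_model(preset),
                                    n_sweeps = 4L, sample_interval = 0.1) {
  stopifnot(inherits(preset, "construct_preset"))
  if (length(durations) < 1L) stop("need at least one prepulse duration")
  groups <- lapply(seq_along(durations), function(gi) {
    d <- durations[gi]
    seg <- if (d > 0) {
      data.frame(duration_ms = c(baseline_ms, d, test_ms, tail_ms),
                 voltage_mV = c(holding, prepulse_voltage, test_voltage, holding))
    } else {  # zero-duration prepulse collapses to a no-prepulse control
      data.frame(duration_ms = c(baseline_ms, test_ms, tail_ms),
                 voltage_mV = c(holding, test_voltage, holding))
    }
    prot <- voltage_protocol(seg, holding_voltage = holding,
                             sample_interval = sample_interval)
    lapply(seq_len(n_sweeps), function(i) {
      ni <- noise; ni$seed <- noise$seed + 1000L * gi + i
      generate_sweep(preset, prot, ni)
    })
  })
  names(groups) <- paste0(durations, "ms")
  structure(list(groups = groups, prepulse_voltage = prepulse_voltage,
                 durations = durations, test_voltage = test_voltage,
                 test_ms = test_ms, holding = holding),
            class = "cole_moore_set")
}
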