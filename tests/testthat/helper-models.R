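# shared builders for small test models

# symmetric two-state scheme with voltage-independent rates
sym2 <- function(k = 1) {
  kinetic_scheme(positions = c(0, 10), charges = c(0, 1),
                 transitions = data.frame(from = c(1, 2), to = c(2, 1),
                                          rate0 = c(k, k), z = c(0, 0)))
}

# single-segment constant-voltage protocol
const_protocol <- function(duration = 10, voltage = 0, dt = 0.1,
                           holding = voltage) {
  voltage_protocol(data.frame(duration_ms = duration, voltage_mV = voltage),
                   holding_voltage = holding, sample_interval = dt)
}

# holding -> step protocol
step_protocol <- function(hold_ms = 5, step_ms = 20, holding = -120,
                          step_mV = 80, dt = 0.1, tail_ms = 0) {
  seg <- data.frame(duration_ms = c(hold_ms, step_ms),
                    voltage_mV = c(holding, step_mV))
  if (tail_ms > 0)
    seg <- rbind(seg, data.frame(duration_ms = tail_ms, voltage_mV = holding))
  voltage_protocol(seg, holding_voltage = holding, sample_interval = dt)
}

# random connected linear-chain scheme with mixed voltage sensitivities
random_chain_scheme <- function(n, seed, rate_range = c(0.05, 1),
                                z_range = c(-1, 1)) {
  set.seed(seed)
  kinetic_scheme(
    positions = sort(stats::runif(n, 0, 12)),
    charges = seq(0, 1, length.out = n),
    transitions = data.frame(
      from = c(seq_len(n - 1), seq(2, n)),
      to = c(seq(2, n), seq_len(n - 1)),
      rate0 = stats::runif(2 * (n - 1), rate_range[1], rate_range[2]),
      z = stats::runif(2 * (n - 1), z_range[1], z_range[2])))
}

# explicit-Euler master-equation integrator (independent oracle)
euler_occupancies <- function(scheme, protocol, initial, dt_fine = 1e-4) {
  times <- protocol_times(protocol)
  p <- initial / sum(initial)
  out <- matrix(NA_real_, length(times), scheme$n_states)
  out[1, ] <- p
  tcur <- 0
  for (k in 2:length(times)) {
    while (tcur < times[k] - 1e-12) {
      h <- min(dt_fine, times[k] - tcur)
      Q <- rate_matrix(scheme, protocol_voltage(protocol, tcur))
      p <- p + h * as.numeric(p %*% Q)
      tcur <- tcur + h
    }
    out[k, ] <- p
  }
  out
}

# noiseless synthetic step sweep with known fractional change (percent)
manual_step_sweep <- function(dff0_percent, F0 = 1000, hold_ms = 50,
                              step_ms = 20, dt = 0.5, drift = 0,
                              noise_sd = 0, seed = NULL) {
  prot <- step_protocol(hold_ms, step_ms, dt = dt)
  t <- protocol_times(prot)
  f <- rep(F0, length(t))
  f[t >= hold_ms] <- F0 * (1 + dff0_percent / 100)
  f <- f + drift * t
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + stats::rnorm(length(f), 0, noise_sd)
  }
  sweep_recording(prot, f, construct_label = "manual")
}
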