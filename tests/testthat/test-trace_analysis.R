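test_that("Bessel filter passes DC, attenuates above cutoff, reduces noise", {
  x <- rep(3.7, 2000)
  y <- bessel_lowpass(x, sample_rate = 50, cutoff = 1)
  expect_lt(max(abs(utils::tail(y, 500) - 3.7)), 1e-9)
  # sinusoid at 10x cutoff attenuated by at least 30 dB
  t <- seq(0, 100, by = 0.02)          # 50 kHz, 100 ms
  s <- sin(2 * pi * 10 * t)            # 10 kHz = 10x the 1 kHz cutoff
  ys <- bessel_lowpass(s, 50, 1)
  expect_lt(max(abs(utils::tail(ys, 2000))), 10^(-30 / 20))
  set.seed(4)
  w <- stats::rnorm(5000)
  expect_lt(stats::var(bessel_lowpass(w, 50, 1)), stats::var(w))
  expect_error(bessel_lowpass(w, 10, 5), "Nyquist")
})

test_that("sweep averaging pools traces and errors on mismatches", {
  s1 <- manual_step_sweep(-0.5, noise_sd = 2, seed = 1)
  expect_equal(average_sweeps(list(s1, s1))$fluorescence, s1$fluorescence)
  expect_equal(average_sweeps(list(s1, s1))$n_averaged, 2L)
  # noise SD of a 4-sweep mean is half the per-sweep SD
  sd1 <- replicate(200, {
    stats::sd(manual_step_sweep(0, noise_sd = 2)$fluorescence)
  })
  sd4 <- replicate(200, {
    sw <- lapply(1:4, function(i) manual_step_sweep(0, noise_sd = 2))
    stats::sd(average_sweeps(sw)$fluorescence)
  })
  expect_equal(mean(sd4) / mean(sd1), 0.5, tolerance = 0.05)
  s2 <- manual_step_sweep(-0.5, dt = 0.25)
  expect_error(average_sweeps(list(s1, s2)), "identical protocol")
})

test_that("fractional fluorescence change is exact on noiseless steps", {
  sw <- manual_step_sweep(-0.5)
  expect_equal(compute_dFF0(sw)$dFF0_percent, -0.5, tolerance = 1e-10)
  # pure linear drift with no pulse response -> 0
  sw_drift <- manual_step_sweep(0, drift = 0.8)
  expect_lt(abs(compute_dFF0(sw_drift)$dFF0_percent), 1e-9)
  # scaling the fluorescence leaves dF/F0 unchanged (pipeline linearity)
  sw3 <- sw; sw3$fluorescence <- 17 * sw3$fluorescence
  expect_equal(compute_dFF0(sw3)$dFF0_percent,
               compute_dFF0(sw)$dFF0_percent, tolerance = 1e-10)
  expect_error(compute_dFF0(sw, baseline_window = c(0, 60)), "precede")
  expect_error(compute_dFF0(sw, baseline_window = c(10, 10.4)), "degenerate")
})

test_that("dF/F0 error shrinks with sweep averaging", {
  errs <- vapply(c(4, 16, 64), function(n) {
    reps <- vapply(1:30, function(r) {
      sw <- lapply(1:n, function(i)
        manual_step_sweep(-0.5, noise_sd = 0.5, seed = 1000 * n + 30 * r + i))
      compute_dFF0(average_sweeps(sw))$dFF0_percent + 0.5
    }, numeric(1))
    sqrt(mean(reps^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("charge integration subtracts baselines and integrates exactly", {
  rate <- 2                           # kHz
  t <- seq(0, 100, by = 1 / rate)
  ig <- ifelse(t >= 40 & t <= 60, 5, 0)
  q <- integrate_charge(ig, rate, list(c(0, 30), c(70, 100)), c(40, 60))
  expect_equal(q, 5 * 20, tolerance = 1e-10)
  # with a linear baseline riding on it
  q2 <- integrate_charge(ig + 0.3 + 0.01 * t, rate,
                         list(c(0, 30), c(70, 100)), c(40, 60))
  expect_equal(q2, 100, tolerance = 1e-8)
  # noise-only trace integrates to ~0 within the statistical bound
  set.seed(9)
  qn <- replicate(100, {
    integrate_charge(stats::rnorm(length(t), 0, 0.5), rate,
                     list(c(0, 30), c(70, 100)), c(40, 60))
  })
  expect_lt(abs(mean(qn)), 3 * 0.5 * sqrt(20 / rate))
  expect_error(integrate_charge(ig, rate, list(c(0, 30)), c(40, 200)),
               "outside")
})

test_that("exponential fits recover known kinetics and weighted tau", {
  t <- seq(0, 100, by = 0.25)
  y <- 2 + 5 * exp(-t / 10)
  fit <- fit_exponential(y, t, order = 1L)
  expect_equal(fit$taus, 10, tolerance = 1e-6)
  expect_equal(fit$weighted_tau, fit$taus)
  # equal-amplitude double exponential: weighted tau is the midpoint
  y2 <- 1 + 3 * exp(-t / 2) + 3 * exp(-t / 8)
  fit2 <- fit_exponential(y2, t, order = 2L)
  expect_equal(sort(fit2$taus), c(2, 8), tolerance = 1e-4)
  expect_equal(weighted_tau(fit2), 5, tolerance = 1e-4)
  # a 2-exponential fit of single-exponential truth collapses to one tau
  fit12 <- fit_exponential(y, t, order = 2L)
  expect_equal(weighted_tau(fit12), 10, tolerance = 1e-3)
  # noisy recovery: median relative error < 5% at SNR 10
  relerr <- vapply(1:200, function(s) {
    set.seed(s)
    yn <- y + stats::rnorm(length(t), 0, 0.5)
    abs(fit_exponential(yn, t, order = 1L)$taus - 10) / 10
  }, numeric(1))
  expect_lt(stats::median(relerr), 0.05)
  expect_error(fit_exponential(y[1:5], t[1:5]), "at least 10")
  expect_error(fit_exponential(y, t, order = 3), "order")
})

test_that("voltage curves normalize per recording and pool with SEM", {
  d <- data.frame(voltage_mV = c(-80, -40, 0, 40), value = c(0, 1, 2, 4))
  vc <- build_voltage_curve(d, "QV")
  expect_equal(vc$points$value, c(0, 0.25, 0.5, 1))
  # two recordings differing by a pure scale factor normalize identically
  d2 <- rbind(cbind(d, recording_id = "a"),
              data.frame(voltage_mV = d$voltage_mV, value = 3 * d$value,
                         recording_id = "b"))
  vc2 <- build_voltage_curve(d2, "QV")
  expect_equal(vc2$points$value, c(0, 0.25, 0.5, 1))
  expect_equal(vc2$points$sem, rep(0, 4))
  expect_equal(vc2$points$n, rep(2L, 4))
  fv <- build_voltage_curve(data.frame(voltage_mV = c(-80, 0, 80),
                                       value = c(0.1, -0.2, -0.5)), "FV")
  expect_true(all(abs(fv$points$value) <= 1))
  expect_error(build_voltage_curve(
    data.frame(voltage_mV = c(-80, 0), value = c(1, 1)), "QV"), "zero span")
})

test_that("Boltzmann fits round-trip QV parameters", {
  v <- seq(-120, 40, by = 20)
  q <- 1 / (1 + exp(-2 * (v + 40) / 25.4))
  fit <- boltzmann_fit(data.frame(voltage_mV = v, value = q))
  expect_equal(fit$V_half, -40, tolerance = 0.1 / 40)
  expect_equal(fit$z, 2, tolerance = 0.01 / 2)
  # leftward-shifted data give a strictly smaller V_half
  q_sh <- 1 / (1 + exp(-2 * (v + 70) / 25.4))
  expect_lt(boltzmann_fit(data.frame(voltage_mV = v, value = q_sh))$V_half,
            fit$V_half)
  expect_error(boltzmann_fit(data.frame(voltage_mV = v[1:3], value = q[1:3])),
               "at least 4")
  # full round trip through the model's own QV (wide span so the min/max
  # normalization is negligible)
  qv <- charge_voltage_curve(two_state_scheme(), seq(-200, 120, by = 20))
  names(qv)[2] <- "value"
  rt <- boltzmann_fit(qv)
  expect_equal(rt$V_half, -40, tolerance = 0.01)
  expect_equal(rt$z, 2, tolerance = 0.01)
})

test_that("deactivation FV of an asymmetric sensor is left-shifted", {
  # backward rate carries more voltage sensitivity than forward: deactivation
  # equilibria shift leftward relative to activation measured transiently
  preset <- make_preset("R1C-qBBr:W454A;E247W")
  volt <- seq(-160, 40, by = 40)
  fam_act <- generate_protocol_family("activation", volt, pulse_ms = 60,
                                      baseline_ms = 150, sample_interval = 0.1)
  fam_dea <- generate_protocol_family("deactivation", volt, pulse_ms = 60,
                                      baseline_ms = 150, conditioning_ms = 25,
                                      sample_interval = 0.1)
  expect_length(fam_act, length(volt))
  sapply(fam_dea, function(p) {
    expect_equal(p$segments$voltage_mV[2], 80)
    expect_equal(p$segments$duration_ms[2], 25)
  })
  nz <- noise_model(0, 0, 0, 1)
  measure <- function(prot, win) {
    sw <- generate_sweep(preset, prot, nz)
    compute_dFF0(sw, response_window = win)$dFF0_percent
  }
  fv_act <- vapply(fam_act, function(p) {
    measure(p, c(150 + 48, 150 + 60))
  }, numeric(1))
  # deactivation: measure at the end of the test pulse after conditioning
  fv_dea <- vapply(fam_dea, function(p) {
    measure(p, c(175 + 48, 175 + 60))
  }, numeric(1))
  # midpoint voltage of each normalized FV; starting from the active state
  # (deactivation) the finite test pulse leaves more fluorescence at mid
  # voltages, shifting the apparent midpoint leftward
  act_mid <- stats::approx(fv_act / max(abs(fv_act)), volt, xout = 0.5)$y
  dea_mid <- stats::approx(fv_dea / max(abs(fv_dea)), volt, xout = 0.5)$y
  expect_lt(dea_mid, act_mid)
})
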