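test_that("voltage protocol lookup is piecewise constant and left-closed", {
  p <- voltage_protocol(data.frame(duration_ms = c(10, 50, 20),
                                   voltage_mV = c(-120, 80, -120)),
                        holding_voltage = -90, sample_interval = 0.1)
  expect_equal(protocol_duration(p), 80)
  expect_equal(protocol_voltage(p, c(-5, 0, 9.999, 10, 59.999, 60, 80)),
               c(-90, -120, -120, 80, 80, -120, -120))
  expect_equal(pulse_onset(p), 10)
  expect_error(voltage_protocol(data.frame(duration_ms = c(1, 0),
                                           voltage_mV = c(0, 0)), 0, 0.1),
               "positive")
  expect_error(voltage_protocol(data.frame(duration_ms = 1, voltage_mV = 0),
                                0, -0.1), "sample_interval")
})

test_that("rate matrix follows the exponential rate law with zero row sums", {
  expect_equal(rate_matrix(sym2(1), 40), matrix(c(-1, 1, 1, -1), 2),
               tolerance = 1e-15)
  # k = k0 exp(z V / kT): k0 = 1, z = 1 e0, kT = 25 mV, V = 25 mV -> e
  sch <- kinetic_scheme(c(0, 10), c(0, 1),
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   rate0 = c(1, 1), z = c(1, 0)),
                        kT_mV = 25)
  expect_equal(rate_matrix(sch, 25)[1, 2], exp(1), tolerance = 1e-12)
  for (seed in 1:5) {
    sch <- random_chain_scheme(sample(3:5, 1), seed)
    Q <- rate_matrix(sch, stats::runif(1, -160, 80))
    expect_equal(rowSums(Q), rep(0, nrow(Q)), tolerance = 1e-13)
    ev <- eigen(Q, only.values = TRUE)$values
    expect_equal(sum(abs(Re(ev)) < 1e-9), 1)      # exactly one zero eigenvalue
    expect_true(all(Re(ev) < 1e-9))               # remaining n-1 non-positive
  }
  expect_error(rate_matrix(sym2(), NA), "finite")
  big <- kinetic_scheme(c(0, 1), c(0, 1),
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   rate0 = c(1, 1), z = c(40, 0)))
  expect_error(rate_matrix(big, 1e6), "overflow|non-finite")
})

test_that("occupancy propagation matches closed forms and a fine-step Euler oracle", {
  # symmetric two-state: P0(t) = (1 + exp(-2kt))/2
  o <- solve_occupancies(sym2(1), const_protocol(5, dt = 0.05), initial = c(1, 0))
  expect_equal(o$probabilities[, 1], 0.5 * (1 + exp(-2 * o$times)),
               tolerance = 1e-12)
  expect_lt(max(abs(rowSums(o$probabilities) - 1)), 1e-9)
  # long-time limit is the generator's null vector
  sch <- two_state_scheme()
  o2 <- solve_occupancies(sch, const_protocol(2000, -40, dt = 10))
  expect_equal(o2$probabilities[nrow(o2$probabilities), ],
               steady_state(sch, -40), tolerance = 1e-9)
  # 3-state chain with mixed rates and a voltage step vs explicit Euler
  # (rates of order 0.1/ms keep the first-order oracle below 1e-6 error)
  sch3 <- random_chain_scheme(3, seed = 42, rate_range = c(0.02, 0.15),
                              z_range = c(-0.5, 0.5))
  prot <- step_protocol(hold_ms = 0.5, step_ms = 1.5, holding = -40,
                        step_mV = 20, dt = 0.05)
  init <- c(1, 0, 0)
  ours <- solve_occupancies(sch3, prot, init)$probabilities
  oracle <- euler_occupancies(sch3, prot, init, dt_fine = 1e-5)
  expect_lt(max(abs(ours - oracle)), 1e-6)
  expect_error(solve_occupancies(sch3, prot, c(0.7, 0.1, 0.1)), "sum to 1")
})

test_that("steady states obey symmetry, rate ratios and detailed balance", {
  expect_equal(steady_state(sym2(), 0), c(0.5, 0.5), tolerance = 1e-12)
  sch <- kinetic_scheme(c(0, 1), c(0, 1),
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   rate0 = c(3, 1), z = c(0, 0)))
  expect_equal(steady_state(sch, 0), c(0.25, 0.75), tolerance = 1e-12)
  # detailed-balance chain: compare to brute-force long-time occupancies
  sch3 <- random_chain_scheme(4, seed = 7)
  long <- solve_occupancies(sch3, const_protocol(5000, -20, dt = 25))
  expect_equal(steady_state(sch3, -20),
               long$probabilities[nrow(long$probabilities), ],
               tolerance = 1e-8)
  disc <- kinetic_scheme(c(0, 1), c(0, 1),
                         data.frame(from = c(1, 2), to = c(2, 1),
                                    rate0 = c(1, 1), z = c(0, 0)))
  disc$transitions$rate0 <- c(0, 0)   # sever the chain after construction
  expect_error(steady_state(disc, 0), "disconnected")
})

test_that("gating current integrates to the occupancy charge difference", {
  sch <- two_state_scheme()
  prot <- step_protocol(hold_ms = 5, step_ms = 40, dt = 0.02)
  occ <- solve_occupancies(sch, prot)
  ig <- gating_current(occ, sch, n_channels = 3)
  # steady state at holding -> current ~0 before the pulse
  expect_lt(max(abs(ig$I_g[occ$times < 4.5])), 1e-6)
  # time integral equals n_channels * charge moved
  qbar <- as.numeric(occ$probabilities %*% sch$charges)
  trapz <- sum(diff(ig$time_ms) * (ig$I_g[-1] + ig$I_g[-nrow(ig)]) / 2)
  expect_equal(trapz, 3 * (qbar[length(qbar)] - qbar[1]), tolerance = 1e-4)
  # two-state step response relaxes with rate k12(V) + k21(V)
  Q <- rate_matrix(sch, 80)
  sel <- occ$times >= 5.1 & occ$times <= 10
  fit <- fit_exponential(ig$I_g[sel], occ$times[sel], order = 1L)
  expect_equal(1 / fit$taus, Q[1, 2] + Q[2, 1], tolerance = 1e-3)
  occ_bad <- occupancy_trajectory(c(0, 1), matrix(c(0.5, 0.5, 0.3, 0.3, 0.2, 0.2),
                                                  2, 3))
  expect_error(gating_current(occ_bad, sch), "mismatch")
})

test_that("QV curve is the normalized Boltzmann of a two-state sensor", {
  sch <- two_state_scheme()       # z_total = 2 e0
  v <- seq(-160, 80, by = 10)
  qv <- charge_voltage_curve(sch, v)
  expect_true(all(qv$Q >= 0 & qv$Q <= 1))
  v_half <- 25.4 / 2 * log(0.00214 / 0.05)   # where k_on(V) = k_off(V)
  boltz <- 1 / (1 + exp(-2 * (v - v_half) / 25.4))
  expect_equal(qv$Q, (boltz - min(boltz)) / (max(boltz) - min(boltz)),
               tolerance = 1e-6)
  # monotone non-decreasing for a monotone-charge chain
  sch3 <- kinetic_scheme(c(0, 5, 10), c(0, 0.5, 1),
                         data.frame(from = c(1, 2, 2, 3),
                                    to = c(2, 1, 3, 2),
                                    rate0 = c(0.05, 0.01, 0.05, 0.01),
                                    z = c(1, -1, 1, -1)))
  expect_true(all(diff(charge_voltage_curve(sch3, v)$Q) >= -1e-9))
  # a deep closed state entered at very negative V pulls the mean charge
  # below the two-state Boltzmann prediction (shallow QV foot)
  deep <- make_preset("deep-closed")$scheme
  q_deep_160 <- sum(steady_state(deep, -160) * deep$charges)
  q_boltz_160 <- 1 / (1 + exp(-2 * (-160 + 40) / 25.4))   # two-state <q>, min 0
  expect_lt(q_deep_160, q_boltz_160)
  expect_lt(q_deep_160, 0)  # deep state carries negative cumulative charge
  expect_error(charge_voltage_curve(sch, -40), "at least 2")
})
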