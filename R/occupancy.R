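#' Construct an occupancy trajectory
#'
#' Time-resolved state probabilities of a kinetic scheme on a sampling grid.
#' Rarely called directly; produced by [solve_occupancies()].
#'
#' @param times strictly increasing numeric vector (ms) starting at 0.
#' @param probabilities numeric matrix, one row per time, one column per
#'   state; each row must sum to 1 within 1e-9 with entries in \[0, 1\].
#' @return an object of class `occupancy_trajectory`.
#' @export
occupancy_trajectory <- function(times, probabilities) {
  times <- as.numeric(times)
  probabilities <- as.matrix(probabilities)
  if (length(times) != nrow(probabilities))
    stop("`times` length must match rows of `probabilities`")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing from 0")
  if (any(probabilities < -1e-9) || any(probabilities > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  s <- rowSums(probabilities)
  if (any(abs(s - 1) > 1e-9))
    stop("each probability vector must sum to 1 within 1e-9")
  structure(list(times = times, probabilities = probabilities),
            class = "occupancy_trajectory")
}

#' @exportS3Method base::print
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf("<occupancy_trajectory> %d states, %d times over %.6g ms\n",
              ncol(x$probabilities), length(x$times), max(x$times)))
  invisible(x)
}

#' Solve state occupancies under a voltage protocol
#'
#' Propagates the master equation `dP/dt = P Q(v(t))` segment by segment:
#' within each piecewise-constant voltage segment the exact propagator is the
#' matrix exponential `expm(Q dt)`, cached per segment for the regular
#' sampling step and evaluated directly for partial steps at segment
#' boundaries. Output is sampled on the protocol's grid. Accumulated
#' round-off in the probability sum is renormalized when it exceeds 1e-12
#' and treated as an error beyond 1e-6.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param initial initial probability vector (length n, sums to 1 within
#'   1e-6). Defaults to the steady state at the holding potential.
#' @return an [occupancy_trajectory()].
#' @examples
#' sch <- two_state_scheme()
#' prot <- voltage_protocol(data.frame(duration_ms = c(5, 50),
#'                                     voltage_mV = c(-120, 80)),
#'                          holding_voltage = -120, sample_interval = 0.1)
#' occ <- solve_occupancies(sch, prot)
#' @export
solve_occupancies <- function(scheme, protocol, initial = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "voltage_protocol"))
  n <- scheme$n_states
  if (is.null(initial)) initial <- steady_state(scheme, protocol$holding_voltage)
  initial <- as.numeric(initial)
  if (length(initial) != n) stop("`initial` must have one entry per state")
  if (abs(sum(initial) - 1) > 1e-6) stop("`initial` must sum to 1 within 1e-6")
  if (any(initial < 0)) stop("`initial` must be non-negative")

  seg <- protocol_segments(protocol)
  dt <- protocol$sample_interval
  times <- protocol_times(protocol)
  nt <- length(times)
  P <- matrix(NA_real_, nt, n)
  p <- initial / sum(initial)
  P[1, ] <- p

  Qs <- lapply(seg$voltage_mV, function(v) rate_matrix(scheme, v))
  Edt <- vector("list", nrow(seg))  # cached full-step propagators
  .prop <- function(Q, h, si) {
    if (abs(h - dt) < 1e-12) {
      if (is.null(Edt[[si]])) Edt[[si]] <<- as.matrix(Matrix::expm(Q * dt))
      Edt[[si]]
    } else as.matrix(Matrix::expm(Q * h))
  }

  cur_t <- 0
  si <- 1L
  tol_end <- 1e-9
  for (k in 2L:nt) {
    target <- times[k]
    while (cur_t < target - tol_end) {
      while (si < nrow(seg) && cur_t >= seg$end_ms[si] - tol_end) si <- si + 1L
      step_end <- min(target, if (si < nrow(seg)) seg$end_ms[si] else target)
      h <- step_end - cur_t
      p <- as.numeric(p %*% .prop(Qs[[si]], h, si))
      cur_t <- step_end
    }
    s <- sum(p)
    if (abs(s - 1) > 1e-6)
      stop("probability drift exceeds 1e-6 during propagation")
    if (abs(s - 1) > 1e-12) p <- p / s
    p[p < 0 & p > -1e-12] <- 0
    P[k, ] <- p
  }
  occupancy_trajectory(times, P)
}

#' Macroscopic gating current from an occupancy trajectory
#'
#' The gating current is the rate of change of the mean cumulative gating
#' charge, `I_g(t) = n_channels * d/dt sum_i q_i P_i(t)`, evaluated by
#' central differences on the occupancy grid (one-sided at the ends).
#'
#' @param occupancy an [occupancy_trajectory()].
#' @param scheme the [kinetic_scheme()] that produced it (supplies `q_i`).
#' @param n_channels number of channels (scales the current).
#' @return data frame with `time_ms` and `I_g` (e0/ms times `n_channels`).
#' @export
gating_current <- function(occupancy, scheme, n_channels = 1) {
  stopifnot(inherits(occupancy, "occupancy_trajectory"),
            inherits(scheme, "kinetic_scheme"))
  if (ncol(occupancy$probabilities) != scheme$n_states)
    stop("state count mismatch between occupancy and scheme")
  qbar <- as.numeric(occupancy$probabilities %*% scheme$charges)
  t <- occupancy$times
  nt <- length(t)
  dq <- numeric(nt)
  if (nt >= 3) {
    dq[2:(nt - 1)] <- (qbar[3:nt] - qbar[1:(nt - 2)]) / (t[3:nt] - t[1:(nt - 2)])
  }
  dq[1] <- (qbar[2] - qbar[1]) / (t[2] - t[1])
  dq[nt] <- (qbar[nt] - qbar[nt - 1]) / (t[nt] - t[nt - 1])
  data.frame(time_ms = t, I_g = n_channels * dq)
}

#' Normalized charge-voltage (QV) curve
#'
#' Steady-state mean gating charge versus voltage, shifted and scaled so the
#' minimum maps to 0 and the maximum to 1.
#'
#' @param scheme a [kinetic_scheme()].
#' @param voltages numeric vector of at least two test potentials (mV).
#' @return data frame with `voltage_mV` and `Q` (normalized to \[0, 1\]).
#' @export
charge_voltage_curve <- function(scheme, voltages) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  voltages <- as.numeric(voltages)
  if (length(voltages) < 2L) stop("need at least 2 voltages")
  q <- vapply(voltages,
              function(v) sum(steady_state(scheme, v) * scheme$charges),
              numeric(1))
  span <- max(q) - min(q)
  if (span <= 0) stop("charge has zero span over the requested voltages")
  data.frame(voltage_mV = voltages, Q = (q - min(q)) / span)
}
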