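# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a single-molecule state path
#'
#' Exact stochastic simulation of one voltage-sensing domain under a
#' piecewise-constant voltage protocol. Within each segment, waiting times
#' are exponential with the current state's total exit rate; when a segment
#' boundary is reached before the next jump, the waiting time is re-drawn
#' under the new segment's rates (valid by memorylessness of the exponential
#' distribution, so this is exact, not an approximation). Identical seeds
#' give identical paths.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param seed integer seed for the path's private RNG stream.
#' @param initial_state starting state index at `t = 0` (default 1).
#' @return an object of class `state_path`: `events` (data frame of
#'   `entry_ms`, `state`, first row at `t = 0`) and `total_duration_ms`.
#' @export
simulate_path <- function(scheme, protocol, seed, initial_state = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "voltage_protocol"))
  n <- scheme$n_states
  initial_state <- as.integer(initial_state)
  if (initial_state < 1L || initial_state > n) stop("initial_state out of range")
  seg <- protocol_segments(protocol)
  Qs <- lapply(seg$voltage_mV, function(v) rate_matrix(scheme, v))
  total <- protocol_duration(protocol)

  .with_seed(seed, {
    t_ent <- numeric(16); st <- integer(16)
    m <- 1L; t_ent[1] <- 0; st[1] <- initial_state
    cur <- initial_state; tcur <- 0; si <- 1L
    nseg <- nrow(seg)
    repeat {
      rates <- Qs[[si]][cur, ]
      rates[cur] <- 0
      rtot <- sum(rates)
      seg_end <- seg$end_ms[si]
      w <- if (rtot > 0) stats::rexp(1, rtot) else Inf
      if (tcur + w >= seg_end) {
        if (si == nseg) break
        tcur <- seg_end
        si <- si + 1L          # re-draw under the new segment's rates
      } else {
        tcur <- tcur + w
        cur <- sample.int(n, 1L, prob = rates)
        m <- m + 1L
        if (m > length(st)) { length(t_ent) <- 2L * m; length(st) <- 2L * m }
        t_ent[m] <- tcur; st[m] <- cur
      }
    }
    structure(list(events = data.frame(entry_ms = t_ent[seq_len(m)],
                                       state = st[seq_len(m)]),
                   total_duration_ms = total),
              class = "state_path")
  })
}

#' @exportS3Method base::print
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path> %d event(s) over %.6g ms\n",
              nrow(x$events), x$total_duration_ms))
  invisible(x)
}

#' Fluorescence of a single-molecule path
#'
#' Piecewise-constant intensity trace `F(t) = F0 * g(|x_state(t) - x_w|)`,
#' right-continuous at transition times: a quencher near the resting
#' position produces a step increase when the fluorophore leaves, a quencher
#' at the final position a sustained step decrease, and a quencher
#' equidistant from both end states a flat trace.
#'
#' @param path a [simulate_path()] result.
#' @param positions per-state trajectory coordinates (Angstrom).
#' @param geometry a [quencher_geometry()].
#' @param times evaluation grid (ms) within `[0, total_duration]`.
#' @return numeric vector of intensities at `times`.
#' @export
path_fluorescence <- function(path, positions, geometry, times) {
  stopifnot(inherits(path, "state_path"), inherits(geometry, "quencher_geometry"))
  positions <- as.numeric(positions)
  if (max(path$events$state) > length(positions))
    stop("path states exceed `positions` length")
  times <- as.numeric(times)
  if (any(times < 0) || any(times > path$total_duration_ms))
    stop("times outside the path duration")
  g <- quench_factor(abs(positions - geometry$x_w), geometry$lambda_half)
  idx <- findInterval(times, path$events$entry_ms)
  geometry$F0 * g[path$events$state[pmax(idx, 1L)]]
}

#' Ensemble average of stochastic single-molecule fluorescence
#'
#' Simulates `n_molecules` independent paths (per-molecule seeds are
#' `seed + molecule index`), evaluates each path's fluorescence on a shared
#' grid, and returns the pointwise mean and standard error. By the law of
#' large numbers the mean converges to the deterministic ensemble observable
#' of [ensemble_fluorescence()].
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param positions per-state trajectory coordinates (Angstrom).
#' @param geometry a [quencher_geometry()].
#' @param n_molecules number of molecules (>= 1).
#' @param seed master integer seed.
#' @param initial_state starting state of every molecule (default 1).
#' @param times evaluation grid (ms); defaults to the protocol grid.
#' @return an object of class `ensemble_result`: `times`, `mean_F`,
#'   `standard_error` (0 where undefined, e.g. `n = 1`), `n_molecules`.
#' @export
ensemble_average <- function(scheme, protocol, positions, geometry,
                             n_molecules, seed, initial_state = 1L,
                             times = protocol_times(protocol)) {
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  acc <- numeric(length(times))
  acc2 <- numeric(length(times))
  for (i in seq_len(n_molecules)) {
    path <- simulate_path(scheme, protocol, seed = seed + i,
                          initial_state = initial_state)
    f <- path_fluorescence(path, positions, geometry, times)
    acc <- acc + f
    acc2 <- acc2 + f * f
  }
  mean_F <- acc / n_molecules
  se <- if (n_molecules > 1L) {
    v <- pmax(acc2 / n_molecules - mean_F^2, 0) * n_molecules / (n_molecules - 1L)
    sqrt(v / n_molecules)
  } else numeric(length(times))
  structure(list(times = times, mean_F = mean_F, standard_error = se,
                 n_molecules = n_molecules),
            class = "ensemble_result")
}

#' @exportS3Method base::print
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d molecules, %d grid points\n",
              x$n_molecules, length(x$times)))
  invisible(x)
}
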