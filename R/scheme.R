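#' Define an n-state kinetic scheme of a voltage-sensing domain
#'
#' The voltage sensor is modelled as a continuous-time Markov chain over `n`
#' discrete conformational states. Each state `i` carries a scalar trajectory
#' coordinate `x_i` (Angstrom) for the tethered fluorophore and a cumulative
#' gating charge `q_i` (elementary charges). Each directed transition
#' `i -> j` has a single-barrier exponential voltage dependence
#' `k_ij(V) = k0_ij * exp(z_ij * V / kT)` with `k0_ij` in 1/ms and the
#' voltage sensitivity `z_ij` in elementary charges.
#'
#' @param positions numeric vector of per-state trajectory coordinates
#'   (Angstrom); its length sets the number of states (>= 2).
#' @param charges numeric vector of per-state cumulative gating charge (e0),
#'   same length as `positions`. Need not be monotone.
#' @param transitions data frame with columns `from`, `to` (1-based state
#'   indices), `rate0` (1/ms, >= 0) and `z` (e0). Connectivity must contain at
#'   least the linear chain 1-2-...-n (each consecutive pair connected in at
#'   least one direction with positive rate).
#' @param kT_mV thermal voltage kT/e0 in mV; default 25.4 (approx. 22 C,
#'   room-temperature recordings).
#' @return an object of class `kinetic_scheme`.
#' @examples
#' two_state_scheme(k_on = 0.05, k_off = 0.00214)
#' @export
kinetic_scheme <- function(positions, charges, transitions, kT_mV = 25.4) {
  positions <- as.numeric(positions)
  charges <- as.numeric(charges)
  n <- length(positions)
  if (n < 2L) stop("a kinetic scheme needs at least 2 states")
  if (length(charges) != n)
    stop("`charges` must have one entry per state")
  if (!all(is.finite(positions)) || !all(is.finite(charges)))
    stop("positions and charges must be finite")
  transitions <- as.data.frame(transitions)
  need <- c("from", "to", "rate0", "z")
  if (!all(need %in% names(transitions)))
    stop("`transitions` needs columns from, to, rate0, z")
  transitions <- transitions[, need]
  if (any(transitions$from < 1 | transitions$from > n |
          transitions$to < 1 | transitions$to > n))
    stop("transition indices out of range")
  if (any(transitions$from == transitions$to))
    stop("self-transitions are not allowed")
  if (any(!is.finite(transitions$rate0)) || any(transitions$rate0 < 0))
    stop("every base rate must be finite and >= 0")
  if (any(!is.finite(transitions$z))) stop("voltage sensitivities must be finite")
  if (!is.finite(kT_mV) || kT_mV <= 0) stop("kT_mV must be > 0")
  # linear-chain connectivity: consecutive states linked with positive rate
  for (i in seq_len(n - 1L)) {
    hit <- (transitions$from == i & transitions$to == i + 1L) |
           (transitions$from == i + 1L & transitions$to == i)
    if (!any(hit & transitions$rate0 > 0))
      stop(sprintf("scheme must connect states %d and %d (linear chain required)",
                   i, i + 1L))
  }
  structure(
    list(n_states = n, positions = positions, charges = charges,
         transitions = transitions, kT_mV = kT_mV),
    class = "kinetic_scheme")
}

#' @exportS3Method base::print
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d states, kT/e0 = %g mV\n", x$n_states, x$kT_mV))
  cat("positions (A):", paste(signif(x$positions, 4), collapse = ", "), "\n")
  cat("charges (e0): ", paste(signif(x$charges, 4), collapse = ", "), "\n")
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Convenience constructor for a two-state voltage sensor
#'
#' A resting/active two-state scheme with forward rate
#' `k_on * exp(z_on V/kT)` and backward rate `k_off * exp(-z_off V/kT)`.
#'
#' @param k_on,k_off base rates at 0 mV (1/ms).
#' @param z_on,z_off voltage sensitivities (e0), both entered as positive
#'   numbers; the backward rate decreases with depolarization.
#' @param positions length-2 trajectory coordinates (Angstrom).
#' @param charges length-2 cumulative gating charges (e0).
#' @param kT_mV thermal voltage (mV).
#' @return a [kinetic_scheme()].
#' @export
two_state_scheme <- function(k_on = 0.05, k_off = 0.00214,
                             z_on = 1, z_off = 1,
                             positions = c(0, 10), charges = c(0, 1),
                             kT_mV = 25.4) {
  kinetic_scheme(
    positions = positions, charges = charges,
    transitions = data.frame(from = c(1, 2), to = c(2, 1),
                             rate0 = c(k_on, k_off), z = c(z_on, -z_off)),
    kT_mV = kT_mV)
}

#' Transition-rate generator matrix at a fixed voltage
#'
#' Builds the n-by-n generator `Q` with off-diagonal entries
#' `Q[i, j] = k0_ij * exp(z_ij * V / kT)` for each declared transition and
#' diagonal entries minus the row sums, so every row sums to zero. Occupancy
#' row vectors evolve as `dP/dt = P Q`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param voltage membrane potential (mV).
#' @return n-by-n numeric generator matrix (1/ms).
#' @export
rate_matrix <- function(scheme, voltage) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(voltage)) stop("voltage must be finite")
  n <- scheme$n_states
  Q <- matrix(0, n, n)
  tr <- scheme$transitions
  k <- tr$rate0 * exp(tr$z * voltage / scheme$kT_mV)
  if (any(!is.finite(k)))
    stop("non-finite transition rate: voltage x sensitivity overflow; ",
         "check z and the voltage range")
  Q[cbind(tr$from, tr$to)] <- k
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary occupancy distribution at a fixed voltage
#'
#' Normalized left null vector of the generator. The scheme must be
#' connected at the given voltage (a single zero eigenvalue); otherwise the
#' components are reported.
#'
#' @param scheme a [kinetic_scheme()].
#' @param voltage membrane potential (mV).
#' @return probability vector of length n (sums to 1, entries >= 0).
#' @export
steady_state <- function(scheme, voltage) {
  Q <- rate_matrix(scheme, voltage)
  comps <- .connected_components(Q)
  if (max(comps) > 1L) {
    parts <- split(seq_along(comps), comps)
    stop("scheme is disconnected at ", voltage, " mV; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  # left null vector: solve t(Q) p = 0 with sum constraint
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) stop("steady state solve produced negative probabilities")
  p / sum(p)
}

# undirected connected components of the positive-rate graph
.connected_components <- function(Q) {
  n <- nrow(Q)
  adj <- (Q > 0) | (t(Q) > 0)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}
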