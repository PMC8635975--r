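#' Quencher geometry for tryptophan-induced quenching
#'
#' Parameters of the distance form of the Stern-Volmer law: the quencher's
#' coordinate on the fluorophore trajectory, the half-quench distance
#' `lambda` (the separation at which half the emission is quenched) and the
#' unquenched intensity `F0`.
#'
#' @param x_w quencher trajectory coordinate (Angstrom).
#' @param lambda_half half-quench distance lambda (Angstrom, > 0).
#'   Default 6: quenching is near-complete at van-der-Waals contact and
#'   falls below ~20% beyond 10 Angstrom, matching the short range of
#'   bimane-tryptophan photoinduced electron transfer.
#' @param F0 unquenched fluorescence intensity (arbitrary units, > 0).
#' @return an object of class `quencher_geometry`.
#' @export
quencher_geometry <- function(x_w, lambda_half = 6, F0 = 1) {
  if (!is.finite(x_w)) stop("x_w must be finite")
  if (!is.finite(lambda_half) || lambda_half <= 0)
    stop("lambda_half must be > 0")
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be > 0")
  structure(list(x_w = x_w, lambda_half = lambda_half, F0 = F0),
            class = "quencher_geometry")
}

#' @exportS3Method base::print
print.quencher_geometry <- function(x, ...) {
  cat(sprintf("<quencher_geometry> x_w = %g A, lambda = %g A, F0 = %g\n",
              x$x_w, x$lambda_half, x$F0))
  invisible(x)
}

#' Fraction of fluorescence remaining at a given quencher distance
#'
#' Distance form of the Stern-Volmer law: the fraction of unquenched
#' emission at separation `d` is `1 / (1 + (lambda/d)^3)`. At `d = lambda`
#' exactly half the fluorescence is quenched; `d = 0` gives complete
#' quenching (0); the fraction increases monotonically with distance
#' towards 1.
#'
#' @param distance separation(s) between fluorophore and quencher
#'   (Angstrom, >= 0); vectorized.
#' @param lambda_half half-quench distance (Angstrom, > 0).
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' quench_factor(6, 6)        # 0.5
#' quench_factor(12, 6)       # 8/9
#' @export
quench_factor <- function(distance, lambda_half) {
  if (any(!is.finite(lambda_half)) || any(lambda_half <= 0))
    stop("lambda_half must be > 0")
  if (any(distance < 0)) stop("distance must be >= 0")
  d3 <- distance^3
  d3 / (d3 + lambda_half^3)   # equals 1/(1 + (lambda/d)^3); d = 0 -> 0
}

#' Convert quencher concentration to an effective distance
#'
#' The mean nearest-neighbour separation in a solution scales as the inverse
#' cube root of concentration, `d = scale * C^(-1/3)`, which links the
#' classical concentration form of the Stern-Volmer relation to the distance
#' form used here.
#'
#' @param concentration quencher concentration (arbitrary units, > 0);
#'   vectorized.
#' @param scale proportionality constant (Angstrom * units^(1/3), > 0).
#' @return distances in Angstrom.
#' @export
distance_from_concentration <- function(concentration, scale) {
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be > 0")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  scale * concentration^(-1/3)
}

#' Two-state fluorescence time course
#'
#' For a fluorophore hopping between a resting coordinate `x0` and an active
#' coordinate `xf` with resting-state probability `P0(t)`, the normalized
#' fluorescence is the affine combination
#' `F(t)/F0 = P0(t) * (g(|x0 - x_w|) - g(|xf - x_w|)) + g(|xf - x_w|)`
#' where `g` is [quench_factor()]. Its normalized time course equals `P0(t)`
#' whenever the amplitude is nonzero, independent of where the quencher sits
#' along the trajectory.
#'
#' @param P0 probability series for the resting state (values in \[0, 1\]).
#' @param x0,xf resting and active fluorophore coordinates (Angstrom).
#' @param x_w quencher coordinate (Angstrom).
#' @param lambda_half half-quench distance (Angstrom).
#' @return numeric vector `F(t)/F0` in \[0, 1\].
#' @export
two_state_fluorescence <- function(P0, x0, xf, x_w, lambda_half) {
  P0 <- as.numeric(P0)
  if (any(P0 < -1e-12 | P0 > 1 + 1e-12)) stop("P0 values must lie in [0, 1]")
  g0 <- quench_factor(abs(x0 - x_w), lambda_half)
  gf <- quench_factor(abs(xf - x_w), lambda_half)
  P0 * (g0 - gf) + gf
}

#' Ensemble fluorescence of an n-state trajectory
#'
#' General deterministic observable: `F(t) = F0 * sum_i P_i(t) g(|x_i - x_w|)`,
#' the occupancy-weighted quench factors of all states. With more than two
#' states the fluorescence time course depends on where the quencher sits
#' along the trajectory and can be multi-exponential or biphasic.
#'
#' @param occupancy an [occupancy_trajectory()].
#' @param positions per-state trajectory coordinates (Angstrom), length equal
#'   to the occupancy's state count.
#' @param geometry a [quencher_geometry()].
#' @return data frame with `time_ms` and `F` (same units as `geometry$F0`,
#'   bounded by \[0, F0\]).
#' @export
ensemble_fluorescence <- function(occupancy, positions, geometry) {
  stopifnot(inherits(occupancy, "occupancy_trajectory"),
            inherits(geometry, "quencher_geometry"))
  positions <- as.numeric(positions)
  if (length(positions) != ncol(occupancy$probabilities))
    stop("`positions` length must equal the occupancy state count")
  g <- quench_factor(abs(positions - geometry$x_w), geometry$lambda_half)
  data.frame(time_ms = occupancy$times,
             F = geometry$F0 * as.numeric(occupancy$probabilities %*% g))
}
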