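#' Fit a single or double exponential to a trace segment
#'
#' Nonlinear least squares of `offset + sum_k A_k * exp(-t/tau_k)` with
#' positive time constants, fitted with Levenberg-Marquardt. Starting
#' values come from the trace's range and a log-linear estimate; if the fit
#' fails to converge, a documented set of restarts perturbs the time
#' constants (factors 1/10, 1/3, 3, 10) before giving up with diagnostics.
#' Times are referenced to the first sample of the window.
#'
#' For a double fit the amplitude-weighted mean time constant
#' `sum(|A_k| tau_k) / sum(|A_k|)` is reported as `weighted_tau` (for a
#' single fit it equals `tau`), the conventional summary of biexponential
#' kinetics.
#'
#' @param samples numeric response values (>= 10 samples).
#' @param times sample times (ms), same length.
#' @param order 1 or 2 exponential components.
#' @return object of class `exponential_fit`: `order`, `amplitudes`,
#'   `taus` (ms, ascending), `offset`, `weighted_tau`, `rss`, `fitted`,
#'   `n_restarts` used.
#' @export
fit_exponential <- function(samples, times, order = 1L) {
  samples <- as.numeric(samples); times <- as.numeric(times)
  if (length(samples) != length(times)) stop("samples/times length mismatch")
  if (length(samples) < 10L) stop("need at least 10 samples in the fit window")
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  t0 <- times[1]
  tt <- times - t0
  span <- max(tt)
  y_end <- mean(samples[tt >= 0.8 * span])
  amp0 <- samples[1] - y_end
  if (amp0 == 0) amp0 <- max(abs(samples - y_end), stats::sd(samples), 1e-12)
  tau_guess <- .tau_loglin(tt, samples, y_end)
  if (!is.finite(tau_guess) || tau_guess <= 0) tau_guess <- span / 5
  tau_guess <- min(tau_guess, span / 2)   # longer is unidentifiable anyway

  model <- function(par) {
    if (order == 1L) par[1] + par[2] * exp(-tt / par[3])
    else par[1] + par[2] * exp(-tt / par[3]) + par[4] * exp(-tt / par[5])
  }
  lower <- if (order == 1L) c(-Inf, -Inf, 1e-9) else c(-Inf, -Inf, 1e-9, -Inf, 1e-9)
  restarts <- c(1, 1 / 10, 1 / 3, 3, 10)
  best <- NULL; last_err <- NULL
  for (r in seq_along(restarts)) {
    tau1 <- tau_guess * restarts[r]
    start <- if (order == 1L) c(y_end, amp0, tau1)
             else c(y_end, amp0 / 2, tau1 / 4, amp0 / 2, tau1 * 2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) samples - model(p),
                         lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { last_err <- fit; next }
    converged <- fit$info %in% 1:4
    if (converged && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
    if (!converged) last_err <- simpleError(fit$message)
    if (!is.null(best) && r >= 2L) break   # keep the better of two starts
  }
  if (is.null(best))
    stop("exponential fit failed to converge after ", length(restarts),
         " starts; last error: ",
         if (is.null(last_err)) "none" else conditionMessage(last_err))
  cf <- best$par
  taus <- if (order == 1L) cf[3] else cf[c(3, 5)]
  amps <- if (order == 1L) cf[2] else cf[c(2, 4)]
  ord <- order(taus)
  taus <- taus[ord]; amps <- amps[ord]
  structure(
    list(order = order, amplitudes = amps, taus = taus, offset = cf[1],
         weighted_tau = sum(abs(amps) * taus) / sum(abs(amps)),
         rss = best$deviance, fitted = model(cf), t0 = t0,
         n_restarts = NA_integer_),
    class = "exponential_fit")
}

# crude log-linear time-constant estimate from the decaying part
.tau_loglin <- function(tt, y, y_end) {
  d <- y - y_end
  s <- sign(d[1])
  ok <- which(s * d > 0.05 * abs(d[1]))
  if (length(ok) < 3) return(NA_real_)
  f <- stats::lm(log(s * d[ok]) ~ tt[ok])
  -1 / stats::coef(f)[2]
}

#' @exportS3Method base::print
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> order %d: tau = %s ms, weighted tau = %.4g ms, rss = %.3g\n",
              x$order, paste(signif(x$taus, 4), collapse = ", "),
              x$weighted_tau, x$rss))
  invisible(x)
}

#' Amplitude-weighted time constant of a fit
#' @param fit an [fit_exponential()] result.
#' @return weighted tau (ms).
#' @export
weighted_tau <- function(fit) {
  stopifnot(inherits(fit, "exponential_fit"))
  fit$weighted_tau
}

#' F-test comparison of single- versus double-exponential fits
#'
#' Fits both model orders to the same window and performs the nested-model
#' F-test on the residual sums of squares (2 extra parameters for the
#' double fit). Used to decide whether a fluorescence relaxation carries a
#' resolvable second kinetic component.
#'
#' @param samples,times as in [fit_exponential()].
#' @return list with `fit1`, `fit2`, `F`, `p_value`.
#' @export
compare_exponential_fits <- function(samples, times) {
  f1 <- fit_exponential(samples, times, order = 1L)
  f2 <- fit_exponential(samples, times, order = 2L)
  n <- length(samples)
  df2 <- n - 5L
  Fstat <- ((f1$rss - f2$rss) / 2) / (f2$rss / df2)
  p <- if (f2$rss <= 0 || !is.finite(Fstat)) 0
       else stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  list(fit1 = f1, fit2 = f2, F = Fstat, p_value = p)
}

#' Boltzmann fit of a normalized charge-voltage curve
#'
#' Least-squares fit of the two-state Boltzmann
#' `Q(V) = 1 / (1 + exp(-z (V - V_half) / kT))`, summarizing a QV curve by
#' its midpoint voltage and effective valence.
#'
#' @param curve a QV [build_voltage_curve()] result, or a data frame with
#'   columns `voltage_mV` and `value` (or `Q`).
#' @param kT_mV thermal voltage (mV), default 25.4.
#' @return list with `V_half` (mV), `z` (e0) and the `nls` fit object.
#' @export
boltzmann_fit <- function(curve, kT_mV = 25.4) {
  if (inherits(curve, "voltage_curve")) {
    if (curve$kind != "QV") stop("boltzmann_fit expects a QV curve")
    d <- curve$points
  } else d <- as.data.frame(curve)
  if (!"value" %in% names(d) && "Q" %in% names(d)) d$value <- d$Q
  if (!all(c("voltage_mV", "value") %in% names(d)))
    stop("need columns voltage_mV and value")
  if (nrow(d) < 4L) stop("need at least 4 points for a Boltzmann fit")
  v0 <- d$voltage_mV[which.min(abs(d$value - 0.5))]
  sl <- stats::coef(stats::lm(value ~ voltage_mV, d))[2]
  z0 <- max(min(4 * kT_mV * sl, 12), 0.1)
  fit <- minpack.lm::nlsLM(
    value ~ 1 / (1 + exp(-z * (voltage_mV - vh) / kT_mV)),
    data = d, start = list(vh = v0, z = z0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(V_half = unname(cf["vh"]), z = unname(cf["z"]), fit = fit)
}
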