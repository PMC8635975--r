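# linear baseline fit over window(s); returns corrected samples, the fitted
# line over the whole sweep, and the lm fit itself.
# windows are half-open [start, end) intervals in ms.
.baseline_correct <- function(times, samples, windows) {
  if (!is.list(windows)) windows <- list(windows)
  sel <- rep(FALSE, length(times))
  for (w in windows) {
    if (length(w) != 2L || w[2] <= w[1]) stop("each window must be (start, end) with end > start")
    if (w[1] < times[1] - 1e-9 || w[2] > times[length(times)] + 1e-9)
      stop("window outside the recording")
    sel <- sel | (times >= w[1] & times < w[2])
  }
  if (sum(sel) < 2L) stop("degenerate baseline window: fewer than 2 samples")
  fit <- stats::lm(y ~ t, data = data.frame(t = times[sel], y = samples[sel]))
  line <- stats::predict(fit, newdata = data.frame(t = times))
  list(corrected = samples - line, line = line, fit = fit)
}

#' Fractional fluorescence change of a sweep
#'
#' Implements the standard voltage-clamp-fluorimetry measurement: a
#' least-squares line is fitted to the fluorescence over a pre-pulse
#' baseline window, extrapolated across the sweep and subtracted; `F0` is
#' the extrapolated baseline value at pulse onset; the fractional change is
#' `100 * mean(corrected fluorescence over the response window) / F0`,
#' signed so that quenching is negative.
#'
#' The default baseline window is the period 6000-1500 ms before the pulse
#' onset (shrunk proportionally when the recording is shorter), and the
#' default response window is the last 20% of the test pulse, where the
#' response has reached steady state.
#'
#' @param sweep a [sweep_recording()].
#' @param baseline_window `(start, end)` in ms, half-open, preceding the
#'   pulse onset; `NULL` for the default above.
#' @param response_window `(start, end)` in ms, half-open; `NULL` for the
#'   default above.
#' @return an object of class `dff0_result` with elements `dFF0_percent`,
#'   `ci` (95% confidence interval, percent), `F0`, `corrected` (baseline
#'   subtracted fluorescence), and the windows used. Prints as a one-line
#'   summary.
#' @export
compute_dFF0 <- function(sweep, baseline_window = NULL, response_window = NULL) {
  stopifnot(inherits(sweep, "sweep_recording"))
  t <- sweep_times(sweep)
  onset <- pulse_onset(sweep$protocol)
  if (is.null(baseline_window)) {
    if (onset >= 7500) baseline_window <- c(onset - 6000, onset - 1500)
    else baseline_window <- c(onset * (1 - 6000 / 7500), onset * (1 - 1500 / 7500))
  }
  if (baseline_window[2] > onset + 1e-9)
    stop("baseline window must precede the pulse onset")
  if (is.null(response_window)) {
    seg <- protocol_segments(sweep$protocol)
    k <- which(seg$start_ms >= onset - 1e-9 &
               seg$voltage_mV != seg$voltage_mV[1])[1]
    if (is.na(k)) stop("protocol has no test pulse")
    response_window <- c(seg$start_ms[k] + 0.8 * (seg$end_ms[k] - seg$start_ms[k]),
                        seg$end_ms[k])
  }
  bc <- .baseline_correct(t, sweep$fluorescence, baseline_window)
  F0 <- unname(stats::predict(bc$fit, newdata = data.frame(t = onset)))
  if (F0 <= 0) stop("F0 <= 0 after baseline correction")
  rsel <- t >= response_window[1] & t < response_window[2]
  if (!any(rsel)) stop("response window contains no samples")
  resp <- bc$corrected[rsel]
  est <- 100 * mean(resp) / F0
  # uncertainty: response-mean standard error plus baseline extrapolation
  se_resp <- if (length(resp) > 1) stats::sd(resp) / sqrt(length(resp)) else 0
  se_line <- unname(stats::predict(bc$fit,
                                   newdata = data.frame(t = mean(t[rsel])),
                                   se.fit = TRUE)$se.fit)
  se <- 100 * sqrt(se_resp^2 + se_line^2) / F0
  df <- max(length(resp) - 1L, 1L)
  ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(dFF0_percent = est, ci = ci, se = se, F0 = unname(F0),
                 corrected = bc$corrected, baseline_window = baseline_window,
                 response_window = response_window, onset_ms = onset),
            class = "dff0_result")
}

#' @exportS3Method base::print
print.dff0_result <- function(x, ...) {
  cat(sprintf("dF/F0 = %.4g%%  [95%% CI %.4g, %.4g]  (F0 = %.6g)\n",
              x$dFF0_percent, x$ci[1], x$ci[2], x$F0))
  invisible(x)
}

#' Integrate gating charge from a gating-current trace
#'
#' A linear baseline, fitted over user-defined windows where the gating
#' current has returned to zero, is subtracted, and the trace is integrated
#' by the trapezoidal rule over the integration window.
#'
#' @param gating numeric vector of gating-current samples (microamps).
#' @param sample_rate sampling rate (kHz).
#' @param baseline_windows list of `(start, end)` windows (ms) used for the
#'   linear baseline fit.
#' @param integration_window `(start, end)` window (ms) to integrate over.
#' @return charge in microamp-milliseconds (nanocoulombs).
#' @export
integrate_charge <- function(gating, sample_rate, baseline_windows,
                             integration_window) {
  gating <- as.numeric(gating)
  t <- seq(0, by = 1 / sample_rate, length.out = length(gating))
  bc <- .baseline_correct(t, gating, baseline_windows)
  if (integration_window[1] < t[1] - 1e-9 ||
      integration_window[2] > t[length(t)] + 1e-9)
    stop("integration window outside the trace")
  sel <- t >= integration_window[1] & t <= integration_window[2] + 1e-9
  tt <- t[sel]; yy <- bc$corrected[sel]
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}
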