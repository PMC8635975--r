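#' Cole-Moore prepulse analysis of fluorescence kinetics
#'
#' For recordings grouped by hyperpolarizing-prepulse condition, averages
#' each group, subtracts a linear baseline fitted over the pre-prepulse
#' holding period, fits a weighted double exponential to the fluorescence
#' during the test pulse, and reports the amplitude-weighted time constant
#' per condition. A deeper or longer-populated closed state slows the test
#' response, so the weighted tau grows with prepulse duration.
#'
#' Protocols must follow the shape holding baseline, prepulse, test pulse
#' (optional tail); all groups must share an identical test pulse.
#'
#' @param groups a `cole_moore_set` from [generate_cole_moore_set()], or a
#'   named list where each element is a list of [sweep_recording()]s sharing
#'   one prepulse condition.
#' @param fit_window optional `(start, end)` (ms) overriding the test-pulse
#'   fit window.
#' @return object of class `cole_moore_result`: data frame `entries` with
#'   `prepulse_voltage_mV`, `prepulse_duration_ms`, `weighted_tau_ms`, plus
#'   the per-condition fits.
#' @export
cole_moore_tau <- function(groups, fit_window = NULL) {
  if (inherits(groups, "cole_moore_set")) groups <- groups$groups
  if (length(groups) < 1L) stop("no prepulse groups given")
  info <- lapply(groups, function(g) {
    if (inherits(g, "sweep_recording")) g <- list(g)
    seg <- protocol_segments(g[[1]]$protocol)
    if (nrow(seg) < 3L)
      stop("each protocol needs baseline, prepulse and test segments")
    list(sweeps = g,
         baseline_end = seg$end_ms[1],
         prepulse_voltage = seg$voltage_mV[2],
         prepulse_duration = seg$end_ms[2] - seg$start_ms[2],
         test_start = seg$start_ms[3], test_end = seg$end_ms[3],
         test_voltage = seg$voltage_mV[3])
  })
  tv <- vapply(info, `[[`, numeric(1), "test_voltage")
  td <- vapply(info, function(x) x$test_end - x$test_start, numeric(1))
  if (length(unique(tv)) != 1L || max(td) - min(td) > 1e-9)
    stop("test pulses are inconsistent across prepulse groups")
  fits <- lapply(info, function(x) {
    avg <- average_sweeps(x$sweeps)
    t <- sweep_times(avg)
    bc <- .baseline_correct(t, avg$fluorescence, c(0, 0.8 * x$baseline_end))
    win <- if (is.null(fit_window)) c(x$test_start, x$test_end) else fit_window
    sel <- t >= win[1] & t < win[2]
    fit_exponential(bc$corrected[sel], t[sel], order = 2L)
  })
  entries <- data.frame(
    prepulse_voltage_mV = vapply(info, `[[`, numeric(1), "prepulse_voltage"),
    prepulse_duration_ms = vapply(info, `[[`, numeric(1), "prepulse_duration"),
    weighted_tau_ms = vapply(fits, weighted_tau, numeric(1)))
  if (!is.null(names(groups))) rownames(entries) <- names(groups)
  structure(list(entries = entries, fits = fits), class = "cole_moore_result")
}

#' @exportS3Method base::print
print.cole_moore_result <- function(x, ...) {
  cat("<cole_moore_result>\n")
  print(x$entries)
  invisible(x)
}
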