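#' Define a piecewise-constant voltage-clamp protocol
#'
#' A protocol is an ordered list of (duration, voltage) segments applied from
#' `t = 0`, preceded by an indefinite holding potential. The voltage is
#' piecewise constant on left-closed, right-open segments, i.e. the voltage of
#' segment k applies on `[t_k, t_k + duration_k)`; `v(t < 0)` equals the
#' holding potential.
#'
#' @param segments a data frame (or list coercible to one) with columns
#'   `duration_ms` (> 0) and `voltage_mV`.
#' @param holding_voltage holding potential (mV) applied before `t = 0`.
#' @param sample_interval output sampling interval in ms (> 0).
#' @return an object of class `voltage_protocol`.
#' @examples
#' p <- voltage_protocol(data.frame(duration_ms = c(10, 50, 20),
#'                                  voltage_mV  = c(-120, 80, -120)),
#'                       holding_voltage = -120, sample_interval = 0.1)
#' protocol_voltage(p, c(-1, 0, 15, 70))
#' @export
voltage_protocol <- function(segments, holding_voltage, sample_interval) {
  segments <- as.data.frame(segments)
  if (!all(c("duration_ms", "voltage_mV") %in% names(segments)))
    stop("`segments` needs columns `duration_ms` and `voltage_mV`")
  if (nrow(segments) < 1L) stop("protocol must contain at least one segment")
  if (!all(is.finite(segments$duration_ms)) || any(segments$duration_ms <= 0))
    stop("all segment durations must be finite and strictly positive")
  if (!all(is.finite(segments$voltage_mV)))
    stop("all segment voltages must be finite")
  if (!is.finite(holding_voltage)) stop("holding_voltage must be finite")
  if (!is.finite(sample_interval) || sample_interval <= 0)
    stop("sample_interval must be > 0")
  structure(
    list(segments = segments[, c("duration_ms", "voltage_mV")],
         holding_voltage = holding_voltage,
         sample_interval = sample_interval),
    class = "voltage_protocol")
}

#' @exportS3Method base::print
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %d segment(s), %.6g ms total, holding %g mV, dt %g ms\n",
              nrow(x$segments), protocol_duration(x), x$holding_voltage,
              x$sample_interval))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Total duration of a protocol in ms
#' @param protocol a [voltage_protocol()].
#' @return duration in ms.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  sum(protocol$segments$duration_ms)
}

#' Output time grid of a protocol
#'
#' Times run from 0 to the total duration in steps of `sample_interval`
#' (the end point is included only when it falls on the grid).
#' @param protocol a [voltage_protocol()].
#' @return numeric vector of times (ms).
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  total <- protocol_duration(protocol)
  n <- floor(total / protocol$sample_interval + 1e-9)
  seq(0, by = protocol$sample_interval, length.out = n + 1L)
}

#' Voltage at given times
#' @param protocol a [voltage_protocol()].
#' @param t numeric vector of times (ms); values before 0 return the holding
#'   potential, values at or beyond the end return the last segment's voltage.
#' @return numeric vector of voltages (mV).
#' @export
protocol_voltage <- function(protocol, t) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  edges <- cumsum(protocol$segments$duration_ms)
  starts <- c(0, edges[-length(edges)])
  idx <- findInterval(t, starts)       # 0 for t < 0
  v <- protocol$segments$voltage_mV[pmax(idx, 1L)]
  v[t < 0] <- protocol$holding_voltage
  v
}

#' Segment boundaries of a protocol
#' @param protocol a [voltage_protocol()].
#' @return data frame with `start_ms`, `end_ms`, `voltage_mV` per segment.
#' @export
protocol_segments <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  edges <- cumsum(protocol$segments$duration_ms)
  data.frame(start_ms = c(0, edges[-length(edges)]),
             end_ms = edges,
             voltage_mV = protocol$segments$voltage_mV)
}

#' Time of the first voltage change (pulse onset)
#'
#' The onset is the start of the first segment whose voltage differs from the
#' protocol's initial (first-segment) voltage; used as the default anchor for
#' baseline windows and fluorescence-change measurements.
#' @param protocol a [voltage_protocol()].
#' @return onset time (ms), or the total duration when the voltage never
#'   changes.
#' @export
pulse_onset <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  seg <- protocol_segments(protocol)
  chg <- which(seg$voltage_mV != seg$voltage_mV[1])
  if (length(chg) == 0) protocol_duration(protocol) else seg$start_ms[chg[1]]
}
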