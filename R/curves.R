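#' Build a normalized charge-voltage or fluorescence-voltage curve
#'
#' Normalization is performed per recording (as done per oocyte in
#' voltage-clamp fluorimetry): QV values are mapped to \[0, 1\] by their
#' minimum and maximum, FV values are divided by the maximum absolute
#' value. Curves pooling several recordings report the mean and standard
#' error of the mean per voltage after per-recording normalization.
#'
#' @param values data frame with columns `voltage_mV`, `value`, and
#'   optionally `recording_id` (a single recording is assumed when absent).
#' @param kind "QV" or "FV".
#' @param normalize normalize per recording (default `TRUE`).
#' @return object of class `voltage_curve`: `kind`, `normalized`, `points`
#'   (per-voltage `value`, `sem`, `n`), `per_recording` (normalized values
#'   per recording).
#' @export
build_voltage_curve <- function(values, kind = c("QV", "FV"), normalize = TRUE) {
  kind <- match.arg(kind)
  d <- as.data.frame(values)
  if (!all(c("voltage_mV", "value") %in% names(d)))
    stop("need columns voltage_mV and value")
  if (!"recording_id" %in% names(d)) d$recording_id <- "rec1"
  per <- do.call(rbind, lapply(split(d, d$recording_id), function(g) {
    if (length(unique(g$voltage_mV)) < 2L)
      stop("each recording needs at least 2 voltages")
    if (anyDuplicated(g$voltage_mV))
      stop("duplicate voltages within recording ", g$recording_id[1])
    v <- g$value
    if (normalize) {
      if (kind == "QV") {
        span <- max(v) - min(v)
        if (span <= 0) stop("zero span in recording ", g$recording_id[1])
        v <- (v - min(v)) / span
      } else {
        m <- max(abs(v))
        if (m <= 0) stop("zero span in recording ", g$recording_id[1])
        v <- v / m
      }
    }
    data.frame(recording_id = g$recording_id, voltage_mV = g$voltage_mV,
               value = v)
  }))
  rownames(per) <- NULL
  pts <- do.call(rbind, lapply(split(per, per$voltage_mV), function(g) {
    data.frame(voltage_mV = g$voltage_mV[1], value = mean(g$value),
               sem = if (nrow(g) > 1) stats::sd(g$value) / sqrt(nrow(g)) else 0,
               n = nrow(g))
  }))
  pts <- pts[order(pts$voltage_mV), ]
  rownames(pts) <- NULL
  structure(list(kind = kind, normalized = normalize, points = pts,
                 per_recording = per),
            class = "voltage_curve")
}

#' @exportS3Method base::print
print.voltage_curve <- function(x, ...) {
  cat(sprintf("<voltage_curve> %s%s, %d voltages, %d recording(s)\n",
              x$kind, if (x$normalized) " (normalized)" else "",
              nrow(x$points), length(unique(x$per_recording$recording_id))))
  print(x$points, row.names = FALSE)
  invisible(x)
}
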