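#' Construct a sweep recording
#'
#' A paired fluorescence / gating-current recording acquired under a voltage
#' protocol, with acquisition metadata. Sample vectors must match the
#' protocol's sampling grid (which includes `t = 0`).
#'
#' @param protocol a [voltage_protocol()].
#' @param fluorescence numeric vector of fluorescence samples (arbitrary
#'   units), one per protocol grid time.
#' @param gating_current optional numeric vector of gating-current samples
#'   (microamps), same length.
#' @param n_averaged number of consecutively acquired traces averaged into
#'   this recording (default 1).
#' @param construct_label free-text construct identifier.
#' @param meta optional named list of provenance (seeds, generator settings).
#' @return an object of class `sweep_recording`.
#' @export
sweep_recording <- function(protocol, fluorescence, gating_current = NULL,
                            n_averaged = 1L, construct_label = "",
                            meta = list()) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  nt <- length(protocol_times(protocol))
  fluorescence <- as.numeric(fluorescence)
  if (length(fluorescence) != nt)
    stop(sprintf("fluorescence has %d samples but the protocol grid has %d",
                 length(fluorescence), nt))
  if (!is.null(gating_current)) {
    gating_current <- as.numeric(gating_current)
    if (length(gating_current) != nt)
      stop("gating_current length must match the protocol grid")
  }
  sample_rate <- 1 / protocol$sample_interval
  if (sample_rate < 1) stop("sample rates below 1 kHz are not supported")
  structure(
    list(protocol = protocol, sample_rate = sample_rate,
         fluorescence = fluorescence, gating_current = gating_current,
         n_averaged = as.integer(n_averaged),
         construct_label = construct_label, meta = meta),
    class = "sweep_recording")
}

#' @exportS3Method base::print
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> '%s': %d samples at %g kHz, %d averaged%s\n",
              x$construct_label, length(x$fluorescence), x$sample_rate,
              x$n_averaged,
              if (is.null(x$gating_current)) "" else ", with gating current"))
  invisible(x)
}

#' Time grid of a sweep recording
#' @param sweep a [sweep_recording()].
#' @return numeric vector of sample times (ms).
#' @export
sweep_times <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_recording"))
  protocol_times(sweep$protocol)
}

#' Average consecutively acquired sweeps
#'
#' Pointwise mean of sweeps sharing an identical protocol and sample rate,
#' as done during acquisition (typically four consecutive traces per voltage
#' step). `n_averaged` of the result is the sum of the inputs'.
#'
#' @param sweeps list of [sweep_recording()] objects.
#' @return a single averaged [sweep_recording()].
#' @export
average_sweeps <- function(sweeps) {
  if (inherits(sweeps, "sweep_recording")) sweeps <- list(sweeps)
  if (length(sweeps) < 1L) stop("need at least one sweep")
  ref <- sweeps[[1L]]
  for (s in sweeps[-1L]) {
    if (!isTRUE(all.equal(s$protocol, ref$protocol)) ||
        s$sample_rate != ref$sample_rate)
      stop("all sweeps must share an identical protocol and sample rate")
  }
  fl <- rowMeans(vapply(sweeps, `[[`, numeric(length(ref$fluorescence)),
                        "fluorescence"))
  have_g <- vapply(sweeps, function(s) !is.null(s$gating_current), logical(1))
  g <- if (all(have_g)) {
    rowMeans(vapply(sweeps, `[[`, numeric(length(ref$fluorescence)),
                    "gating_current"))
  } else NULL
  sweep_recording(ref$protocol, fl, g,
                  n_averaged = sum(vapply(sweeps, `[[`, integer(1), "n_averaged")),
                  construct_label = ref$construct_label,
                  meta = ref$meta)
}
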