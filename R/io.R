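#' Write sweep recordings to the plain-text sweep format
#'
#' A CSV dialect with a commented header block (`# key: value`) followed by
#' the columns `sweep`, `time_ms`, `voltage_mV`, `fluorescence` and, when
#' present, `gating_current`. Values are written at full precision so that
#' `read_sweeps(write_sweeps(x))` reproduces `x` exactly. All I/O uses the
#' C locale conventions (decimal points, UTF-8).
#'
#' Header keys: `format_version`, `construct_label`, `sample_rate` (kHz),
#' `n_averaged`, `holding_mV`, `segments` (protocol segments encoded as
#' `duration:voltage` pairs separated by `|`), and optionally `seed` and
#' `noise_free`.
#'
#' @param recordings a [sweep_recording()] or list of them (all sharing one
#'   protocol and construct).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(recordings, path) {
  if (inherits(recordings, "sweep_recording")) recordings <- list(recordings)
  if (length(recordings) < 1L) stop("no recordings to write")
  ref <- recordings[[1L]]
  for (s in recordings)
    if (!isTRUE(all.equal(s$protocol, ref$protocol)))
      stop("all recordings in one file must share a protocol")
  num <- function(x) formatC(x, digits = 17, format = "g")
  seg <- ref$protocol$segments
  hdr <- c(
    "# vsdtrack sweep file; units: ms, mV, uA, arbitrary fluorescence",
    "# format_version: 1",
    paste0("# construct_label: ", ref$construct_label),
    paste0("# sample_rate: ", num(ref$sample_rate)),
    paste0("# n_averaged: ", ref$n_averaged),
    paste0("# holding_mV: ", num(ref$protocol$holding_voltage)),
    paste0("# segments: ",
           paste(paste0(num(seg$duration_ms), ":", num(seg$voltage_mV)),
                 collapse = "|")),
    paste0("# n_sweeps: ", length(recordings)))
  if (!is.null(ref$meta$seed)) hdr <- c(hdr, paste0("# seed: ", ref$meta$seed))
  if (isTRUE(ref$meta$noise_free)) hdr <- c(hdr, "# noise_free: true")
  has_g <- !is.null(ref$gating_current)
  cols <- c("sweep", "time_ms", "voltage_mV", "fluorescence",
            if (has_g) "gating_current")
  t <- protocol_times(ref$protocol)
  v <- protocol_voltage(ref$protocol, t)
  rows <- lapply(seq_along(recordings), function(i) {
    s <- recordings[[i]]
    line <- paste(i, num(t), num(v), num(s$fluorescence), sep = ",")
    if (has_g) {
      if (is.null(s$gating_current))
        stop("all recordings must consistently have or lack gating current")
      line <- paste(line, num(s$gating_current), sep = ",")
    }
    line
  })
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = ",")), con)
  writeLines(unlist(rows), con)
  invisible(path)
}

#' Read sweep recordings from the plain-text sweep format
#'
#' Parses the commented header block and the data columns written by
#' [write_sweeps()]. Missing mandatory header keys and ragged rows are
#' reported with the key name or line number. A file without a
#' `gating_current` column loads with the gating current absent (not
#' zero-filled).
#'
#' @param path file path.
#' @return list of [sweep_recording()]s.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  hdr_lines <- lines[is_hdr & grepl("^#\\s*[A-Za-z_]+\\s*:", lines)]
  kv <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    kv[[m[2]]] <- trimws(m[3])
  }
  for (key in c("format_version", "construct_label", "sample_rate",
                "n_averaged", "holding_mV", "segments"))
    if (is.null(kv[[key]])) stop("missing header key: ", key)
  if (kv$format_version != "1")
    stop("unrecognized format_version: ", kv$format_version)
  sample_rate <- as.numeric(kv$sample_rate)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("invalid sample_rate header")
  seg_parts <- strsplit(strsplit(kv$segments, "|", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
  segments <- data.frame(
    duration_ms = vapply(seg_parts, function(p) as.numeric(p[1]), numeric(1)),
    voltage_mV = vapply(seg_parts, function(p) as.numeric(p[2]), numeric(1)))
  protocol <- voltage_protocol(segments,
                               holding_voltage = as.numeric(kv$holding_mV),
                               sample_interval = 1 / sample_rate)

  body_idx <- which(!is_hdr)
  if (length(body_idx) < 2L) stop("file has no data rows")
  cols <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  need <- c("sweep", "time_ms", "voltage_mV", "fluorescence")
  if (!all(need %in% cols)) stop("missing data columns: ",
                                 paste(setdiff(need, cols), collapse = ", "))
  has_g <- "gating_current" %in% cols
  data_idx <- body_idx[-1]
  fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("ragged row at line ", data_idx[which(nf != length(cols))[1]],
         ": expected ", length(cols), " fields")
  m <- matrix(as.numeric(unlist(fields)), ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  meta <- list()
  if (!is.null(kv$seed)) meta$seed <- as.integer(kv$seed)
  if (!is.null(kv$noise_free)) meta$noise_free <- tolower(kv$noise_free) == "true"
  lapply(sort(unique(m[, "sweep"])), function(i) {
    rows <- m[m[, "sweep"] == i, , drop = FALSE]
    sweep_recording(protocol, rows[, "fluorescence"],
                    gating_current = if (has_g) rows[, "gating_current"],
                    n_averaged = as.integer(kv$n_averaged),
                    construct_label = kv$construct_label, meta = meta)
  })
}

# ---- configuration files ----------------------------------------------------

.check_keys <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing key(s) in ", where, ": ", paste(missing, collapse = ", "))
}

#' Read a model configuration file
#'
#' YAML configuration with sections `scheme` (positions, charges,
#' transitions, optional kT_mV), `geometry` (x_w, lambda_half, F0),
#' `protocol` (holding_mV, sample_interval_ms, segments) and optional
#' `noise` (gaussian_sd, drift_slope, bleach_rate, seed). All units are
#' ms, mV, Angstrom and elementary charges, as stated in the shipped file
#' headers. Unknown keys are rejected; invariant violations are reported
#' with field names.
#'
#' @param path YAML file path.
#' @return list with elements `scheme`, `geometry`, `protocol`, `noise`
#'   (a zero-noise model when the section is absent).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, c("scheme", "geometry", "protocol", "noise"),
              c("scheme", "geometry", "protocol"), "config")
  s <- cfg$scheme
  .check_keys(s, c("positions", "charges", "transitions", "kT_mV"),
              c("positions", "charges", "transitions"), "scheme")
  tr <- do.call(rbind, lapply(seq_along(s$transitions), function(i) {
    x <- s$transitions[[i]]
    .check_keys(x, c("from", "to", "rate0", "z"), c("from", "to", "rate0", "z"),
                sprintf("scheme$transitions[[%d]]", i))
    as.data.frame(x)
  }))
  scheme <- kinetic_scheme(positions = as.numeric(s$positions),
                           charges = as.numeric(s$charges),
                           transitions = tr,
                           kT_mV = if (is.null(s$kT_mV)) 25.4 else s$kT_mV)
  g <- cfg$geometry
  .check_keys(g, c("x_w", "lambda_half", "F0"), c("x_w", "lambda_half", "F0"),
              "geometry")
  if (!is.null(g$lambda_half) && (!is.numeric(g$lambda_half) || g$lambda_half <= 0))
    stop("invalid geometry field: lambda_half must be > 0")
  geometry <- quencher_geometry(g$x_w, g$lambda_half, g$F0)
  p <- cfg$protocol
  .check_keys(p, c("holding_mV", "sample_interval_ms", "segments"),
              c("holding_mV", "sample_interval_ms", "segments"), "protocol")
  seg <- do.call(rbind, lapply(seq_along(p$segments), function(i) {
    x <- p$segments[[i]]
    .check_keys(x, c("duration_ms", "voltage_mV"), c("duration_ms", "voltage_mV"),
                sprintf("protocol$segments[[%d]]", i))
    as.data.frame(x)
  }))
  protocol <- voltage_protocol(seg, holding_voltage = p$holding_mV,
                               sample_interval = p$sample_interval_ms)
  noise <- if (is.null(cfg$noise)) noise_model() else {
    n <- cfg$noise
    .check_keys(n, c("gaussian_sd", "drift_slope", "bleach_rate", "seed"),
                character(0), "noise")
    noise_model(gaussian_sd = if (is.null(n$gaussian_sd)) 0 else n$gaussian_sd,
                drift_slope = if (is.null(n$drift_slope)) 0 else n$drift_slope,
                bleach_rate = if (is.null(n$bleach_rate)) 0 else n$bleach_rate,
                seed = if (is.null(n$seed)) 1L else n$seed)
  }
  list(scheme = scheme, geometry = geometry, protocol = protocol, noise = noise)
}

#' Write a model configuration file
#'
#' Inverse of [read_config()]; `read_config(write_config(...))` round-trips
#' the objects unchanged.
#'
#' @param scheme a [kinetic_scheme()].
#' @param geometry a [quencher_geometry()].
#' @param protocol a [voltage_protocol()].
#' @param noise a [noise_model()] (optional).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(scheme, geometry, protocol, noise = NULL, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(geometry, "quencher_geometry"),
            inherits(protocol, "voltage_protocol"))
  cfg <- list(
    scheme = list(
      positions = scheme$positions, charges = scheme$charges,
      transitions = lapply(seq_len(nrow(scheme$transitions)), function(i)
        as.list(scheme$transitions[i, ])),
      kT_mV = scheme$kT_mV),
    geometry = list(x_w = geometry$x_w, lambda_half = geometry$lambda_half,
                    F0 = geometry$F0),
    protocol = list(
      holding_mV = protocol$holding_voltage,
      sample_interval_ms = protocol$sample_interval,
      segments = lapply(seq_len(nrow(protocol$segments)), function(i)
        as.list(protocol$segments[i, ]))))
  if (!is.null(noise))
    cfg$noise <- list(gaussian_sd = noise$gaussian_sd,
                      drift_slope = noise$drift_slope,
                      bleach_rate = noise$bleach_rate, seed = noise$seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
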