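# Published per-construct fractional fluorescence changes at +80 mV
# (percent, signed; negative = quench) with their SEMs and effect classes.
# Kinetic rates attached to these labels are artifact tuning choices for
# millisecond-scale gating, not published values.
.preset_table <- data.frame(
  label = c("R1C-qBBr",
            "R1C-qBBr:W454A",
            "R1C-qBBr:W454A;F244W",
            "R1C-qBBr:W454A;E247W",
            "R1C-qBBr:W454A;F290W",
            "R1C-qBBr:W454A;L294W",
            "R1C-qBBr:W454A;I320W",
            "R1C-qBBr:W454A;T326W",
            "R1C-qBBr:W454A;Y415W",
            "R2C-qBBr",
            "R2C-qBBr:I241W",
            "R2C-qBBr:F244W",
            "R2C-qBBr:I287W",
            "R2C-qBBr:L294W",
            "R2C-qBBr:T326W",
            "R2C-qBBr:Y415W",
            "R2C-qBBr:F416W"),
  target = c(-0.154, 0.206, 0.191, 0.930, 0.0946, 0.127, 0.247, 0.448,
             -0.147, 0.168, 0.261, 0.454, 0.493, 0.183, -0.094, -0.851,
             -0.0448),
  sem = c(0.0172, 0.037, 0.026, 0.205, 0.0323, 0.086, 0.095, 0.167,
          0.015, 0.0241, 0.132, 0.171, 0.156, 0.036, 0.017, 0.123, 0.098),
  effect = c("quench", "no effect", "unquench", "unquench", "no effect",
             "no effect", "unquench", "unquench", "quench", "no effect",
             "unquench", "unquench", "unquench", "unquench", "quench",
             "quench", "quench"),
  stringsAsFactors = FALSE)

#' Labels of the shipped construct presets
#' @return character vector of preset names accepted by [make_preset()].
#' @export
preset_labels <- function() c(.preset_table$label, "deep-closed")

# default 3-state scheme with a deep closed state reachable only at very
# negative potentials (entry time constant ~1 s at -160 mV, exit ~10 ms at
# +80 mV); used for Cole-Moore style simulations.
.deep_closed_scheme <- function() {
  kinetic_scheme(
    positions = c(-5, 0, 10),
    charges = c(-0.5, 0, 1),
    transitions = data.frame(
      from  = c(2, 3, 2, 1),
      to    = c(3, 2, 1, 2),
      rate0 = c(0.05, 0.00214, 9.2e-7, 0.02),
      z     = c(1, -1, -1, 0.5)))
}

#' Construct a ground-truth synthetic-recording preset
#'
#' Returns a named parameter bundle (kinetic scheme, fluorophore trajectory
#' positions, quencher geometry, background fraction, target fractional
#' fluorescence change) whose noiseless forward simulation reproduces the
#' construct's published fractional fluorescence change at +80 mV and its
#' effect class. The background fraction is solved analytically from the
#' steady-state occupancies at the holding and depolarized potentials, so
#' presets are self-consistent by construction. "No effect" constructs are
#' modelled as a small, fast, voltage-independent additive step (their
#' mechanism is not modelled). The extra label `"deep-closed"` is a
#' synthetic demonstration preset with a deep closed state populated by
#' strong hyperpolarization, for Cole-Moore style protocols.
#'
#' @param label one of [preset_labels()].
#' @param holding_mV reference holding potential used for calibration
#'   (default -120).
#' @param depol_mV reference depolarized potential (default +80, where the
#'   published values were measured).
#' @return object of class `construct_preset`.
#' @examples
#' p <- make_preset("R1C-qBBr")
#' preset_predicted_dFF0(p)   # -0.154
#' @export
make_preset <- function(label, holding_mV = -120, depol_mV = 80) {
  if (label == "deep-closed") {
    scheme <- .deep_closed_scheme()
    target <- -0.3; sem <- NA_real_; effect <- "quench"
  } else {
    row <- .preset_table[.preset_table$label == label, ]
    if (nrow(row) != 1L)
      stop("unknown preset '", label, "'; available: ",
           paste(preset_labels(), collapse = ", "))
    scheme <- two_state_scheme()
    target <- row$target; sem <- row$sem; effect <- row$effect
  }
  positions <- scheme$positions
  x_active <- positions[length(positions)]
  x_rest <- positions[which(scheme$charges == 0)[1]]
  x_w <- switch(effect,
                quench = x_active,      # quencher at the active-state position
                unquench = x_rest,      # quencher at the resting position
                `no effect` = x_active + 60)  # far from the whole trajectory
  geometry <- quencher_geometry(x_w = x_w, lambda_half = 6, F0 = 1000)
  g <- quench_factor(abs(positions - x_w), geometry$lambda_half)
  fh <- sum(steady_state(scheme, holding_mV) * g)
  fd <- sum(steady_state(scheme, depol_mV) * g)
  a <- fd - fh
  tfrac <- target / 100
  if (effect == "no effect") {
    background <- 1
    residual <- list(amplitude_percent = target, tau_ms = 0.5)
  } else {
    background <- (a - tfrac * fh) / (tfrac * (1 - fh) + a)
    if (background < 0 || background >= 1)
      stop("preset calibration failed: background fraction out of [0, 1)")
    residual <- NULL
  }
  structure(
    list(label = label, scheme = scheme, positions = positions,
         geometry = geometry, background_fraction = background,
         target_dFF0_at_80mV = target, sem_percent = sem,
         effect_class = effect, residual = residual,
         holding_mV = holding_mV, depol_mV = depol_mV),
    class = "construct_preset")
}

#' @exportS3Method base::print
print.construct_preset <- function(x, ...) {
  cat(sprintf("<construct_preset> '%s': %s, target dF/F0 = %g%% at +%g mV, background %.4f\n",
              x$label, x$effect_class, x$target_dFF0_at_80mV, x$depol_mV,
              x$background_fraction))
  invisible(x)
}

#' Predicted steady-state fractional fluorescence change of a preset
#'
#' Noiseless forward prediction from the dilution rule: the recorded
#' intensity is `F0 * (b + (1 - b) * sum_i P_i g_i)` (plus the residual step
#' for "no effect" presets), evaluated at the steady states of the holding
#' and test potentials.
#'
#' @param preset a [make_preset()] result.
#' @param voltage test potential (mV), default the preset's +80 reference.
#' @return predicted fractional fluorescence change in percent (signed).
#' @export
preset_predicted_dFF0 <- function(preset, voltage = preset$depol_mV) {
  stopifnot(inherits(preset, "construct_preset"))
  g <- quench_factor(abs(preset$positions - preset$geometry$x_w),
                     preset$geometry$lambda_half)
  b <- preset$background_fraction
  fh <- b + (1 - b) * sum(steady_state(preset$scheme, preset$holding_mV) * g)
  fv <- b + (1 - b) * sum(steady_state(preset$scheme, voltage) * g)
  res <- if (is.null(preset$residual)) 0 else preset$residual$amplitude_percent / 100 * fh
  100 * (fv + res - fh) / fh
}
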