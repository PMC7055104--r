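#' Single-channel, single-phase blood pressure series
#'
#' Container for one patient-phase pressure channel: ordered `(time, value)`
#' samples at a nominal 15-s cadence, gaps allowed. Systolic pressure cannot
#' carry a bypass-phase series (non-pulsatile flow).
#'
#' @param patient_id patient identifier (scalar, coerced to character).
#' @param channel `"SBP"` or `"MAP"`.
#' @param phase `"pre_bypass"`, `"bypass"` or `"post_bypass"`.
#' @param time_s sample times in seconds, strictly increasing.
#' @param value_mmhg pressures in mmHg, finite and positive.
#' @return An object of class `bp_series`.
#' @export
#' @examples
#' s <- bp_series("P1", "MAP", "pre_bypass", seq(0, 60, 15), c(78, 80, 77, 79, 81))
#' poincare_sd(s)
bp_series <- function(patient_id, channel, phase, time_s, value_mmhg) {
  channel <- match.arg(channel, bpv_channels)
  phase <- match.arg(phase, bpv_phases)
  if (channel == "SBP" && phase == "bypass") {
    stop("SBP is not recorded during bypass (non-pulsatile flow)")
  }
  time_s <- as.numeric(time_s)
  value_mmhg <- as.numeric(value_mmhg)
  if (length(time_s) != length(value_mmhg)) {
    stop("time_s and value_mmhg must have equal length")
  }
  if (length(time_s)) {
    if (any(!is.finite(time_s))) stop("sample times must be finite")
    if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
      stop("sample times must be strictly increasing")
    }
    if (any(!is.finite(value_mmhg) | value_mmhg <= 0)) {
      stop("pressure values must be finite and positive")
    }
  }
  structure(
    list(patient_id = as.character(patient_id)[1], channel = channel,
         phase = phase, time_s = time_s, value_mmhg = value_mmhg),
    class = "bp_series"
  )
}

# internal fast-path constructor for series already known to satisfy the
# invariants (generator output); skips argument matching and validation
new_bp_series <- function(patient_id, channel, phase, time_s, value_mmhg) {
  structure(
    list(patient_id = patient_id, channel = channel, phase = phase,
         time_s = time_s, value_mmhg = value_mmhg),
    class = "bp_series"
  )
}

#' @export
print.bp_series <- function(x, ...) {
  cat(sprintf("<bp_series> patient %s, %s, %s: %d samples",
              x$patient_id, x$channel, x$phase, length(x$time_s)))
  if (length(x$time_s)) {
    cat(sprintf(" over %.0f s, median %.1f mmHg",
                diff(range(x$time_s)), stats::median(x$value_mmhg)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.bp_series <- function(x) length(x$time_s)
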