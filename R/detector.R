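#' Fluorophore photophysics
#'
#' A point fluorophore characterized by its fluorescence lifetime, quantum
#' yield, initial photon budget and position. The pre-exponential factor
#' of the emission decay is `A = round(a * qy)`: the initial number of
#' photons times the probability that an excitation is re-emitted.
#'
#' @param tau fluorescence lifetime, ns (> 0).
#' @param qy quantum yield, fraction in (0, 1].
#' @param a initial number of photons (>= 0).
#' @param position a [source_position()].
#' @param label optional text label (e.g. the dye the parameters mimic).
#' @return An object of class `fluorophore`.
#' @examples
#' fluorophore(tau = 0.65, qy = 0.009, a = 5e6, label = "ICG-like")
#' @export
fluorophore <- function(tau, qy, a, position = source_position(),
                        label = "") {
  stopifnot(tau > 0, qy > 0, qy <= 1, a >= 0)
  structure(list(tau = tau, qy = qy, a = a, position = position,
                 label = label), class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf(
    "Fluorophore%s: tau = %g ns, QY = %g%%, a = %g, at (%g, %g) cm, z = %g cm\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$tau, 100 * x$qy, x$a, x$position$x, x$position$y, x$position$z))
  invisible(x)
}

#' Time-gating configuration
#'
#' Gate timing of the time-gated acquisition emulated by the simulator.
#' Gate `k` opens at `t_k = (k - 1) * gate_step`; the forward model uses a
#' zero gate width, i.e. gates are samples of the decay curve, and the
#' gates tile (approximately) one laser period.
#'
#' @param n_gates number of gates G (>= 2).
#' @param gate_step gate spacing `g_s`, ps.
#' @param gate_width gate width `g_w`, ps; the simulation path uses 0.
#' @param rep_rate_mhz laser repetition rate, MHz; the period is
#'   `T = 1000 / rep_rate_mhz` ns and the phasor harmonic equals the
#'   repetition rate.
#' @return An object of class `gate_config` with derived fields
#'   `period_ns` and `gate_times_ns`.
#' @examples
#' gate_config()   # 117 gates, 428 ps apart, 20 MHz
#' @export
gate_config <- function(n_gates = 117, gate_step = 428, gate_width = 0,
                        rep_rate_mhz = 20) {
  stopifnot(n_gates >= 2, gate_step > 0, gate_width >= 0, rep_rate_mhz > 0)
  period <- 1000 / rep_rate_mhz
  if (n_gates * gate_step / 1000 > period + gate_step / 1000)
    stop("gates overrun the laser period: need G * g_s <= T + g_s")
  structure(list(n_gates = as.integer(n_gates), gate_step = gate_step,
                 gate_width = gate_width, rep_rate_mhz = rep_rate_mhz,
                 period_ns = period,
                 gate_times_ns = (seq_len(n_gates) - 1) * gate_step / 1000),
            class = "gate_config")
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf(
    "Gating: G = %d gates, g_s = %g ps, g_w = %g ps, %g MHz (T = %g ns)\n",
    x$n_gates, x$gate_step, x$gate_width, x$rep_rate_mhz, x$period_ns))
  invisible(x)
}

#' Pixelated detector geometry
#'
#' The SPAD-array detector as seen by the forward model: a rectangle in
#' the tissue-surface plane, divided into pixels, detecting each arriving
#' photon independently with probability `pe` (photon efficiency). Contact
#' mapping is assumed: a photon's surface exit point is binned directly to
#' the enclosing pixel.
#'
#' @param width,height physical size, cm.
#' @param n_px_x,n_px_y pixel counts.
#' @param pe photon efficiency, fraction in (0, 1].
#' @param center lateral position `c(x, y)` of the detector center, cm.
#' @return An object of class `detector_config`; `pitch_x`/`pitch_y` give
#'   the pixel pitch in cm.
#' @examples
#' detector_config()   # 1 x 1 cm, 512 x 512, PE 13%
#' @export
detector_config <- function(width = 1, height = 1, n_px_x = 512,
                            n_px_y = 512, pe = 0.13, center = c(0, 0)) {
  stopifnot(width > 0, height > 0, n_px_x >= 1, n_px_y >= 1,
            pe > 0, pe <= 1, length(center) == 2)
  structure(list(width = width, height = height,
                 n_px_x = as.integer(n_px_x), n_px_y = as.integer(n_px_y),
                 pe = pe, center = as.numeric(center),
                 pitch_x = width / n_px_x, pitch_y = height / n_px_y),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "Detector: %g x %g cm, %d x %d px (pitch %.3g um), PE = %g%%, center (%g, %g)\n",
    x$width, x$height, x$n_px_x, x$n_px_y, 1e4 * x$pitch_x, 100 * x$pe,
    x$center[1], x$center[2]))
  invisible(x)
}

#' Photons emitted per gate from an exponential decay
#'
#' Samples the fluorophore's emission decay at the gate times:
#' `N(t_k) = round(A * exp(-t_k / tau))` with `A = round(a * qy)`.
#' Rounding is round-half-to-even, unbiased across gates.
#'
#' @param fluor a [fluorophore()].
#' @param gates a [gate_config()].
#' @param scale optional multiplier on the photon budget `a` (used to run
#'   scaled-down versions of a scene).
#' @return Integer vector of length `n_gates`, monotone non-increasing.
#' @examples
#' n <- emission_counts(fluorophore(0.65, 0.009, 5e6), gate_config())
#' n[1:4]   # 45000, 23297, ...
#' @export
emission_counts <- function(fluor, gates, scale = 1) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(gates, "gate_config"),
            scale >= 0)
  A <- round(fluor$a * scale * fluor$qy)
  as.integer(round(A * exp(-gates$gate_times_ns / fluor$tau)))
}
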