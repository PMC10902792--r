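#' Per-pixel phasor transform of a gate stack
#'
#' For every pixel the decay trace `F(t_k)` across gates is condensed to
#' the phasor pair
#' \deqn{g = \sum_k F(t_k)\cos(2\pi f t_k) / \sum_k F(t_k), \quad
#'       s = \sum_k F(t_k)\sin(2\pi f t_k) / \sum_k F(t_k),}
#' with the harmonic `f` equal to the laser repetition rate (the
#' fundamental of the gating period). Pixels with zero total counts are
#' flagged invalid (`NA`).
#'
#' @param stack a [gate_stack()].
#' @param roi optional pixel rectangle `c(x1, x2, y1, y2)` (inclusive
#'   bounds); default is the full frame.
#' @return An object of class `phasor_field`: matrices `g`, `s`, `total`,
#'   plus the harmonic frequency, gate metadata and calibration state.
#' @examples
#' st <- analytic_stack(tau = 1, total_counts = 1e4,
#'                      detector = detector_config(n_px_x = 8, n_px_y = 8))
#' ph <- compute_phasor(st)
#' mean(ph$g, na.rm = TRUE)
#' @export
compute_phasor <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "gate_stack"))
  nx <- stack$detector$n_px_x; ny <- stack$detector$n_px_y
  if (is.null(roi)) roi <- c(1L, nx, 1L, ny)
  stopifnot(length(roi) == 4, roi[1] >= 1, roi[2] <= nx, roi[3] >= 1,
            roi[4] <= ny, roi[1] <= roi[2], roi[3] <= roi[4])
  w <- omega_ns(stack$gates$rep_rate_mhz)
  tk <- stack$gates$gate_times_ns
  cs <- cos(w * tk); sn <- sin(w * tk)
  xs <- roi[1]:roi[2]; ys <- roi[3]:roi[4]
  gn <- sn_ <- tot <- matrix(0, length(xs), length(ys))
  for (k in seq_along(tk)) {
    Fk <- stack$counts[xs, ys, k, drop = TRUE]
    gn <- gn + Fk * cs[k]
    sn_ <- sn_ + Fk * sn[k]
    tot <- tot + Fk
  }
  bad <- tot <= 0
  g <- gn / tot; s <- sn_ / tot
  g[bad] <- NA_real_; s[bad] <- NA_real_
  if (all(bad)) warning("ROI contains no counts; all pixels invalid")
  structure(list(g = g, s = s, total = tot,
                 f_mhz = stack$gates$rep_rate_mhz, gates = stack$gates,
                 calibrated = FALSE, roi = as.integer(roi),
                 calibration = NULL),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  ok <- !is.na(x$g)
  cat(sprintf("Phasor field: %d x %d px (%d valid), f = %g MHz, %s\n",
              nrow(x$g), ncol(x$g), sum(ok), x$f_mhz,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  if (any(ok))
    cat(sprintf("  pooled phasor: g = %.4f, s = %.4f\n",
                Re(pooled_phasor(x)), Im(pooled_phasor(x))))
  invisible(x)
}

#' Aggregate (pooled) phasor of a field
#'
#' The count-weighted mean phasor, identical to the phasor of the summed
#' decay trace over all valid pixels. This is the aggregate used for
#' reference calibration: it is stable even when individual pixels hold
#' only a few photons.
#'
#' @param field a `phasor_field`.
#' @return A complex scalar `g + i s`.
#' @export
pooled_phasor <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  ok <- !is.na(field$g)
  if (!any(ok)) stop("no valid pixels to pool")
  wt <- field$total[ok]
  complex(real = sum(wt * field$g[ok]) / sum(wt),
          imaginary = sum(wt * field$s[ok]) / sum(wt))
}

#' Theoretical phasor coordinates of a mono-exponential decay
#'
#' The continuous-decay phasor at harmonic `f`:
#' `g = 1 / (1 + (2 pi f tau)^2)`, `s = 2 pi f tau / (1 + (2 pi f tau)^2)`,
#' i.e. `1 / (1 - i w tau)`. A zero lifetime (instrument-response
#' reference) maps to `(1, 0)`. These points lie on the universal
#' semicircle of radius 1/2 centered at (1/2, 0).
#'
#' @param tau lifetime, ns (vectorized; `0` allowed).
#' @param f_mhz harmonic frequency, MHz.
#' @return Complex vector `g + i s`.
#' @export
phasor_theoretical <- function(tau, f_mhz) {
  stopifnot(all(tau >= 0), f_mhz > 0)
  1 / (1 - 1i * omega_ns(f_mhz) * tau)
}

#' Phasor of an ideal discretely sampled exponential decay
#'
#' The exact phasor of a noiseless decay `exp(-t_k / tau)` sampled at the
#' gate times, i.e. the geometric-series closed form
#' `sum r^(k-1) / sum x^(k-1)` with `x = exp(-g_s/tau)` and
#' `r = x * exp(i w g_s)`. This differs from [phasor_theoretical()] by the
#' finite, discrete gating -- the bias that reference calibration removes.
#' Serves as the analytic stand-in for a measured reference stack.
#'
#' @param tau lifetime, ns (> 0).
#' @param gates a [gate_config()].
#' @return Complex scalar `g + i s`.
#' @export
phasor_discrete <- function(tau, gates) {
  stopifnot(tau > 0, inherits(gates, "gate_config"))
  w <- omega_ns(gates$rep_rate_mhz)
  tk <- gates$gate_times_ns
  wts <- exp(-tk / tau)
  sum(wts * exp(1i * w * tk)) / sum(wts)
}

#' Calibrate a phasor field against a reference of known lifetime
#'
#' Computes the single complex rotation-and-scale factor that maps the
#' measured aggregate phasor of a reference sample onto its theoretical
#' mono-exponential position `1 / (1 - i w tau_ref)` (or `(1, 0)` for a
#' zero-lifetime instrument-response reference), and applies it to every
#' pixel. This removes the bias of discrete, finite gating and any
#' instrumental phase/modulation offset, provided target and reference
#' share the same gate configuration.
#'
#' @param raw an uncalibrated `phasor_field`.
#' @param ref the measured reference: a `phasor_field` (its pooled phasor
#'   is used), a [gate_stack()] (phasor computed over its full frame), a
#'   complex scalar, or the string `"analytic"` for the exact discrete
#'   reference [phasor_discrete()] at `ref_tau`; `"self"` uses the pooled
#'   phasor of `raw` itself (self-calibration).
#' @param ref_tau known reference lifetime, ns (0 for an IRF reference).
#' @return A calibrated `phasor_field`; the applied factor is stored in
#'   `$calibration`.
#' @export
calibrate <- function(raw, ref, ref_tau) {
  stopifnot(inherits(raw, "phasor_field"), is.numeric(ref_tau),
            ref_tau >= 0)
  meas <-
    if (inherits(ref, "phasor_field")) pooled_phasor(ref)
    else if (inherits(ref, "gate_stack")) pooled_phasor(compute_phasor(ref))
    else if (is.character(ref) && ref == "self") pooled_phasor(raw)
    else if (is.character(ref) && ref == "analytic") {
      if (ref_tau == 0) complex(real = 1) else phasor_discrete(ref_tau, raw$gates)
    } else if (is.complex(ref) && length(ref) == 1) ref
    else stop("unsupported reference specification")
  if (Mod(meas) == 0 || is.na(meas))
    stop("reference phasor at the origin; cannot calibrate")
  fac <- phasor_theoretical(ref_tau, raw$f_mhz) / meas
  z <- complex(real = raw$g, imaginary = raw$s) * fac
  out <- raw
  out$g <- matrix(Re(z), nrow(raw$g)); out$s <- matrix(Im(z), nrow(raw$s))
  out$calibrated <- TRUE
  out$calibration <- list(factor = fac, ref_tau = ref_tau,
                          measured = meas)
  out
}

#' Phase and modulation of a phasor field
#'
#' `phi = atan2(s, g)` (two-argument arctangent, principal value) and
#' `m = sqrt(g^2 + s^2)`. Invalid pixels propagate as `NA`.
#'
#' @param field a `phasor_field`.
#' @return List of matrices `phi` (radians) and `m`.
#' @export
phase_and_modulation <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  phi <- atan2(field$s, field$g)
  phi[is.na(field$g)] <- NA_real_
  list(phi = phi, m = sqrt(field$g^2 + field$s^2))
}

#' Phase lifetime from the phasor angle
#'
#' `tau_phi = tan(phi) / (2 pi f)`, in ns for `f` in MHz. Only phases in
#' `[0, pi/2)` correspond to physical single-harmonic lifetimes; values
#' outside are returned as computed but flagged via the `"physical"`
#' attribute rather than silently wrapped, and `phi = pi/2` yields `Inf`.
#'
#' @param phi phase, radians (vector or matrix).
#' @param f_mhz harmonic frequency, MHz.
#' @return Numeric like `phi`, with logical attribute `"physical"`.
#' @examples
#' phase_lifetime(atan(2 * pi * 0.02 * 1), 20)   # exactly 1 ns
#' @export
phase_lifetime <- function(phi, f_mhz) {
  stopifnot(f_mhz > 0)
  w <- omega_ns(f_mhz)
  tau <- tan(phi) / w
  tau[!is.na(phi) & phi == pi / 2] <- Inf
  phys <- !is.na(phi) & phi >= 0 & phi < pi / 2
  dim(phys) <- dim(phi)
  attr(tau, "physical") <- phys
  tau
}

#' Aggregate (intensity-weighted) phase lifetime of a field
#'
#' The phase lifetime of the pooled phasor ([pooled_phasor()]), i.e. of
#' the summed decay over all valid pixels. Unlike the mean of per-pixel
#' phase lifetimes, this estimator is unbiased at arbitrarily low
#' per-pixel counts (the tangent is applied after averaging), which makes
#' it the stable choice for single-dye lifetime readout of sparse deep-
#' tissue images.
#'
#' @param field a calibrated `phasor_field`.
#' @return Phase lifetime, ns.
#' @export
aggregate_lifetime <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  p <- pooled_phasor(field)
  as.numeric(phase_lifetime(atan2(Im(p), Re(p)), field$f_mhz))
}
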