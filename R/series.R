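#' Single-dye lifetime recovery across tissue depths
#'
#' For each depth, simulates the dye and a reference dye under identical
#' optics/gating, calibrates the target phasors against the simulated
#' reference, and records the recovered phase lifetime. This is the
#' depth-invariance experiment: a well-calibrated phasor analysis should
#' return the same lifetime at every depth. Two estimates are reported
#' per depth: `pooled_tau`, the intensity-weighted aggregate phase
#' lifetime ([aggregate_lifetime()], unbiased at low per-pixel counts),
#' and `mean_tau`, the arithmetic mean of the per-pixel histogram
#' ([extract_single_lifetime()]).
#'
#' Simulations use the simplified surface rule of the forward model
#' (photons exit on reaching the surface; no Fresnel re-entry).
#'
#' @param depths source depths, cm.
#' @param dye,ref_dye names from [dye_presets()].
#' @param a initial photon budget (shared by target and reference).
#' @param scale photon-budget multiplier.
#' @param seed optional seed for the whole series.
#' @param cutoff,time_window,bin_width,min_count analysis settings, see
#'   [phasor_flim()].
#' @return Data frame: `depth`, `pooled_tau`, `mean_tau` (ns),
#'   `n_detected`, `n_pixels`.
#' @export
single_dye_depth_series <- function(depths = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    dye = "irdye800", ref_dye = "icg",
                                    a = 7.6e7, scale = 0.1, seed = NULL,
                                    cutoff = 0, time_window = NULL,
                                    bin_width = 0.01, min_count = 1) {
  if (!is.null(seed)) set.seed(seed)
  dy <- dye_presets()[[dye]]; rf <- dye_presets()[[ref_dye]]
  stopifnot(!is.null(dy), !is.null(rf))
  optics <- tissue_optics(fresnel = FALSE)
  det <- detector_config(); gates <- gate_config()
  rows <- lapply(depths, function(z) {
    st <- simulate_gate_stack(
      fluorophore(dy$tau, dy$qy, a, source_position(0, 0, z), dy$label),
      optics, det, gates, scale = scale)
    ref <- simulate_gate_stack(
      fluorophore(rf$tau, rf$qy, a, source_position(0, 0, z), rf$label),
      optics, det, gates, scale = scale)
    fit <- phasor_flim(st, ref_tau = rf$tau, ref = ref, cutoff = cutoff,
                       time_window = time_window, bin_width = bin_width,
                       min_count = min_count, components = "one")
    data.frame(depth = z,
               pooled_tau = aggregate_lifetime(fit$field),
               mean_tau = fit$mean_lifetime,
               n_detected = sum(st$n_detected), n_pixels = fit$n_retained)
  })
  do.call(rbind, rows)
}

two_dye_run <- function(z, dx, a, scale, cutoff, time_window, bin_width,
                        min_count, ref_dye = "icg") {
  spec <- paper_scene("two_dye_depth", z = z, dx = dx, a = a)
  st <- simulate_scene(spec, seed = NULL, scale = scale)
  rf <- dye_presets()[[ref_dye]]
  ref <- simulate_gate_stack(
    fluorophore(rf$tau, rf$qy, a %||% 7.6e7, source_position(0, 0, z),
                rf$label),
    spec$optics, spec$detector, spec$gates, scale = scale)
  mx <- multiplex_lifetimes(st, ref = ref, ref_tau = rf$tau,
                            cutoff = cutoff, time_window = time_window,
                            bin_width = bin_width, min_count = min_count)
  # label by dye identity (scene order: shorter-lifetime dye first)
  data.frame(depth = z, dx = dx,
             f1 = unname(mx$region_means[1]),
             f2 = unname(mx$region_means[2]),
             n1 = unname(mx$region_n[1]), n2 = unname(mx$region_n[2]),
             n_detected = sum(st$n_detected),
             n_retained = mx$histogram$n_pixels)
}

#' Two-dye multiplexing across tissue depths
#'
#' Simulates the two-dye scene (ICG-like and IRDye800-like dyes at a
#' fixed lateral separation) at each depth, applies the percentile
#' cutoff to the joint phase-lifetime histogram, and extracts the two
#' component lifetimes from the pixels of each dye's intensity spot
#' ([multiplex_lifetimes()]): `f1` shorter, `f2` longer.
#'
#' @param depths source depths, cm.
#' @param dx lateral separation, cm.
#' @inheritParams single_dye_depth_series
#' @return Data frame: `depth`, `dx`, `f1`, `f2`, `n1`, `n2`,
#'   `n_detected`, `n_retained`.
#' @export
two_dye_depth_series <- function(depths = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 dx = 2, a = NULL, scale = 0.1,
                                 seed = NULL, cutoff = 1,
                                 time_window = NULL, bin_width = 0.01,
                                 min_count = 1) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(depths, function(z)
    two_dye_run(z, dx, a, scale, cutoff, time_window, bin_width,
                min_count)))
}

#' Two-dye multiplexing across lateral separations
#'
#' As [two_dye_depth_series()], but varying the center-to-center
#' separation of the two dyes at a fixed depth.
#'
#' @param seps lateral separations, cm.
#' @param z fixed depth, cm.
#' @inheritParams single_dye_depth_series
#' @return Data frame as in [two_dye_depth_series()].
#' @export
two_dye_separation_series <- function(seps = c(1, 1.5, 2), z = 0.3,
                                      a = NULL, scale = 0.1, seed = NULL,
                                      cutoff = 1, time_window = NULL,
                                      bin_width = 0.01, min_count = 1) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seps, function(dx)
    two_dye_run(z, dx, a, scale, cutoff, time_window, bin_width,
                min_count)))
}

#' Intensity and spot-radius depth profile of a single dye
#'
#' Simulates a single-dye scene at each depth (keeping the continuous
#' exit records) and reports the full-frame mean intensity and the mean
#' photon radius about the source position. Mean intensity declines and
#' mean radius grows with depth as scattering and absorption accumulate.
#'
#' @inheritParams single_dye_depth_series
#' @return Data frame: `depth`, `mean_intensity`, `mean_radius`,
#'   `n_detected`.
#' @export
spot_depth_series <- function(depths = c(0.1, 0.2, 0.3),
                              dye = "irdye800", a = 7.6e7, scale = 0.1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dy <- dye_presets()[[dye]]
  optics <- tissue_optics(fresnel = FALSE)
  det <- detector_config(); gates <- gate_config()
  rows <- lapply(depths, function(z) {
    st <- simulate_gate_stack(
      fluorophore(dy$tau, dy$qy, a, source_position(0, 0, z), dy$label),
      optics, det, gates, scale = scale, keep_records = TRUE)
    ss <- spot_summary(st, center = c(0, 0))
    data.frame(depth = z, mean_intensity = ss$mean_intensity,
               mean_radius = ss$mean_radius,
               n_detected = sum(st$n_detected))
  })
  do.call(rbind, rows)
}
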