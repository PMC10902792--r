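#' Dye presets used throughout the simulations
#'
#' Photophysics of the four simulated dyes: an ICG-like dye (0.65 ns,
#' QY 0.9%), an IRDye800-like dye (1 ns, QY 1.3%), and two brighter
#' hypothetical dyes (0.8 ns / 18% and 1.1 ns / 28%).
#'
#' @return Named list of `tau` (ns) / `qy` pairs.
#' @export
dye_presets <- function() {
  list(
    icg          = list(tau = 0.65, qy = 0.009, label = "ICG-like"),
    irdye800     = list(tau = 1.0,  qy = 0.013, label = "IRDye800-like"),
    highqy_0.8ns = list(tau = 0.8,  qy = 0.18,  label = "high-QY 0.8 ns"),
    highqy_1.1ns = list(tau = 1.1,  qy = 0.28,  label = "high-QY 1.1 ns")
  )
}

#' Standard simulation scenes
#'
#' Builds the full configuration (fluorophores, optics, detector, gating)
#' of the standard study conditions: single NIR dyes at depth, and
#' two-dye multiplexing scenes at a lateral separation. Single-dye scenes
#' use the 512 x 512, 1 x 1 cm detector centered above the source.
#' Two-dye scenes place the sources at x = -dx/2 and +dx/2 and image the
#' whole two-spot field onto the 512 x 512 array (4 x 4 cm field of
#' view, 78 um effective pitch), so both intensity spots and the mixing
#' zone between them fall on the detector. Photon budgets default to
#' `a = 5e6` for the single-dye characterization scenes and `a = 7.6e7`
#' for the intensity/multiplexing scenes. Scene optics use the tissue
#' defaults but with the surface rule of the underlying simplified
#' forward model: photons exit on reaching the surface (`fresnel =
#' FALSE`), rather than undergoing Fresnel re-entry.
#'
#' @param name one of `"icg_single"`, `"irdye800_single"`,
#'   `"highqy_0.8ns"`, `"highqy_1.1ns"`, `"two_dye_depth"`,
#'   `"two_dye_sep"`.
#' @param z source depth, cm.
#' @param dx lateral center-to-center separation of the two dyes, cm
#'   (two-dye scenes).
#' @param a optional photon-budget override.
#' @param seed optional seed stored in the spec.
#' @return An object of class `scene_spec`: list with `name`,
#'   `fluorophores`, `optics`, `detector`, `gates`, `dx`, `seed`.
#' @examples
#' paper_scene("icg_single", z = 0.3)
#' paper_scene("two_dye_sep", dx = 1.5)
#' @export
paper_scene <- function(name, z = 0.3, dx = 2, a = NULL, seed = NULL) {
  dyes <- dye_presets()
  valid <- c("icg_single", "irdye800_single", "highqy_0.8ns",
             "highqy_1.1ns", "two_dye_depth", "two_dye_sep")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stop("unknown scene; valid names: ", paste(valid, collapse = ", "))
  stopifnot(z >= 0, dx >= 0)
  single <- function(key, a_def) {
    d <- dyes[[key]]
    list(fluorophore(d$tau, d$qy, a %||% a_def,
                     source_position(0, 0, z), d$label))
  }
  fl <- switch(name,
    icg_single      = single("icg", 5e6),
    irdye800_single = single("irdye800", 7.6e7),
    highqy_0.8ns    = single("highqy_0.8ns", 5e6),
    highqy_1.1ns    = single("highqy_1.1ns", 5e6),
    {
      a0 <- a %||% 7.6e7
      list(fluorophore(dyes$icg$tau, dyes$icg$qy, a0,
                       source_position(-dx / 2, 0, z), dyes$icg$label),
           fluorophore(dyes$irdye800$tau, dyes$irdye800$qy, a0,
                       source_position(dx / 2, 0, z), dyes$irdye800$label))
    })
  two <- grepl("^two_dye", name)
  structure(list(name = name, fluorophores = fl,
                 optics = tissue_optics(fresnel = FALSE),
                 detector = if (two)
                   detector_config(width = 4, height = 4)
                 else detector_config(),
                 gates = gate_config(),
                 dx = if (grepl("^two_dye", name)) dx else NA_real_,
                 seed = seed),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene '%s'%s\n", x$name,
              if (!is.na(x$dx)) sprintf(" (dx = %g cm)", x$dx) else ""))
  for (f in x$fluorophores) print(f)
  print(x$optics); print(x$detector); print(x$gates)
  invisible(x)
}

#' Simulate the gate stack of a scene specification
#'
#' @param spec a [paper_scene()] specification.
#' @param seed seed; defaults to the one stored in the spec.
#' @param scale photon-budget multiplier.
#' @param ... passed to [simulate_gate_stack()].
#' @return A [gate_stack()].
#' @export
simulate_scene <- function(spec, seed = spec$seed, scale = 1, ...) {
  stopifnot(inherits(spec, "scene_spec"))
  simulate_gate_stack(spec$fluorophores, spec$optics, spec$detector,
                      spec$gates, seed = seed, scale = scale, ...)
}

#' Analytic (transport-free) mono-exponential gate stack
#'
#' A gate stack whose per-gate totals follow the ideal sampled decay
#' `exp(-t_k / tau)` exactly, distributed over a Gaussian spatial spot.
#' In `"noiseless"` mode counts are real-valued expectations, the exact
#' oracle for phasor arithmetic; `"poisson"` mode draws independent
#' Poisson counts with those expectations.
#'
#' @param tau lifetime, ns.
#' @param total_counts expected total count of the stack.
#' @param gates a [gate_config()].
#' @param detector a [detector_config()].
#' @param spot_sigma Gaussian spot standard deviation, cm.
#' @param mode `"noiseless"` or `"poisson"`.
#' @param center spot center `c(x, y)`, cm.
#' @param seed optional seed (`"poisson"` mode).
#' @return A [gate_stack()] (marked `analytic = TRUE` in its metadata).
#' @export
analytic_stack <- function(tau, total_counts, gates = gate_config(),
                           detector = detector_config(n_px_x = 16,
                                                      n_px_y = 16),
                           spot_sigma = 0.1,
                           mode = c("noiseless", "poisson"),
                           center = c(0, 0), seed = NULL) {
  stopifnot(tau > 0, total_counts >= 0, spot_sigma > 0)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  wk <- exp(-gates$gate_times_ns / tau)
  wk <- wk / sum(wk)
  px <- detector$center[1] - detector$width / 2 +
    (seq_len(detector$n_px_x) - 0.5) * detector$pitch_x
  py <- detector$center[2] - detector$height / 2 +
    (seq_len(detector$n_px_y) - 0.5) * detector$pitch_y
  sp <- outer(exp(-(px - center[1])^2 / (2 * spot_sigma^2)),
              exp(-(py - center[2])^2 / (2 * spot_sigma^2)))
  sp <- sp / sum(sp)
  lam <- outer(c(sp), wk) * total_counts
  cnt <- if (mode == "noiseless") lam
         else array(rpois(length(lam), lam), dim = dim(lam))
  gate_stack(array(cnt, c(detector$n_px_x, detector$n_px_y,
                          gates$n_gates)),
             gates, detector, seed = seed,
             extra = list(analytic = TRUE, tau = tau, mode = mode))
}

#' Add uniform Poisson background to a gate stack
#'
#' Injects detector dark counts / background: independent Poisson counts
#' with mean `dark_rate` added to every pixel of every gate. Emulates the
#' dispersed phasor cloud that background produces in real regions of
#' interest, so the cutoff method can be exercised under realistic
#' conditions. The input stack is not modified.
#'
#' @param stack a [gate_stack()].
#' @param dark_rate mean background counts per pixel per gate (>= 0).
#' @param seed optional seed.
#' @return A new [gate_stack()] with the background added.
#' @export
inject_background <- function(stack, dark_rate, seed = NULL) {
  stopifnot(inherits(stack, "gate_stack"), dark_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- stack
  if (dark_rate > 0)
    out$counts <- stack$counts +
      array(rpois(length(stack$counts), dark_rate), dim(stack$counts))
  out$dark_rate <- dark_rate
  out
}
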