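#' Write a gate stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are written in gate order, one 2D image per gate, as 16-bit
#' unsigned integers by default. Counts exceeding 65535 require
#' `bits = 32` (32-bit float pages with a power-of-two scale recorded in
#' the sidecar; lossless for integer counts below 2^24). The sidecar
#' `<path>.json` carries the gate, detector, optics and scene metadata
#' plus the seed, so a written stack reloads into an identical object.
#'
#' @param stack a [gate_stack()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @param bits 16 or 32.
#' @return `path`, invisibly.
#' @export
write_gate_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "gate_stack"), bits %in% c(16, 32))
  mx <- max(stack$counts)
  if (bits == 16) {
    if (mx > 65535)
      stop("counts exceed the 16-bit range; write with bits = 32")
    if (any(stack$counts != round(stack$counts)))
      stop("non-integer counts; write with bits = 32")
    scale <- 65535
  } else {
    scale <- 2^24
    if (mx >= scale) stop("counts exceed the 32-bit float-exact range")
  }
  pages <- lapply(seq_len(stack$gates$n_gates),
                  function(k) t(stack$counts[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  integer_counts <- all(stack$counts == round(stack$counts))
  side <- list(
    format = "flimmc-gate-stack", version = 1L,
    bits = bits, count_scale = scale, integer_counts = integer_counts,
    gates = unclass(stack$gates)[c("n_gates", "gate_step", "gate_width",
                                   "rep_rate_mhz")],
    detector = unclass(stack$detector)[c("width", "height", "n_px_x",
                                         "n_px_y", "pe", "center")],
    optics = if (!is.null(stack$optics))
      unclass(stack$optics)[c("n", "mu_a", "mu_s", "g", "fresnel",
                              "max_events")],
    scene = if (!is.null(stack$scene)) lapply(stack$scene, function(f)
      list(tau = f$tau, qy = f$qy, a = f$a, label = f$label,
           x = f$position$x, y = f$position$y, z = f$position$z)),
    seed = stack$seed, scale_factor = stack$scale
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a gate stack written by [write_gate_stack()]
#'
#' @param path TIFF path with its `<path>.json` sidecar alongside.
#' @return A [gate_stack()].
#' @export
read_gate_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar ", sidecar,
         "; gate timing metadata is required to interpret the stack")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  gates <- gate_config(side$gates$n_gates, side$gates$gate_step,
                       side$gates$gate_width, side$gates$rep_rate_mhz)
  det <- detector_config(side$detector$width, side$detector$height,
                         side$detector$n_px_x, side$detector$n_px_y,
                         side$detector$pe, side$detector$center)
  pages <- tiff::readTIFF(path, all = TRUE,
                          as.is = identical(side$bits, 16L) ||
                            identical(side$bits, 16))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != gates$n_gates)
    stop(sprintf("TIFF has %d pages but sidecar declares %d gates",
                 length(pages), gates$n_gates))
  counts <- array(0, c(det$n_px_x, det$n_px_y, gates$n_gates))
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    if (side$bits == 32) {
      m <- m * side$count_scale
      if (isTRUE(side$integer_counts)) m <- round(m)
    }
    counts[, , k] <- t(m)
  }
  if (isTRUE(side$integer_counts)) storage.mode(counts) <- "integer"
  optics <- if (!is.null(side$optics))
    tissue_optics(side$optics$n, side$optics$mu_a, side$optics$mu_s,
                  side$optics$g, side$optics$fresnel,
                  side$optics$max_events)
  scene <- if (!is.null(side$scene) && length(side$scene))
    lapply(seq_len(nrow(side$scene)), function(i) {
      s <- side$scene[i, ]
      fluorophore(s$tau, s$qy, s$a, source_position(s$x, s$y, s$z),
                  s$label)
    })
  gate_stack(counts, gates, det, optics = optics, scene = scene,
             seed = side$seed, extra = list(scale = side$scale_factor))
}

#' Export per-pixel phasor coordinates and phase lifetimes as CSV
#'
#' One row per valid pixel with columns `pixel_i`, `pixel_j`, `g`, `s`,
#' `tau_phi_ns`, `total_counts`.
#'
#' @param field a `phasor_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phasor_csv <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  pm <- phase_and_modulation(field)
  tau <- phase_lifetime(pm$phi, field$f_mhz)
  ok <- which(!is.na(field$g), arr.ind = TRUE)
  df <- data.frame(pixel_i = ok[, 1] + field$roi[1] - 1L,
                   pixel_j = ok[, 2] + field$roi[3] - 1L,
                   g = field$g[ok], s = field$s[ok],
                   tau_phi_ns = tau[ok], total_counts = field$total[ok])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a lifetime histogram as CSV
#'
#' @param hist a [lifetime_histogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "lifetime_histogram"))
  df <- data.frame(bin_lo = hist$bin_edges[-length(hist$bin_edges)],
                   bin_hi = hist$bin_edges[-1],
                   count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
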