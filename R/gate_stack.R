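#' Construct a gate stack container
#'
#' A gate stack holds the per-gate detector images `F[i, j, k]` (pixel
#' `(i, j)`, gate `k`) together with the gating, detector, optics and
#' scene metadata needed to analyze them. Counts are integer photon counts
#' for simulated stacks; analytic (noiseless expectation) stacks may carry
#' real values.
#'
#' @param counts numeric array of dimension `c(n_px_x, n_px_y, n_gates)`.
#' @param gates a [gate_config()].
#' @param detector a [detector_config()].
#' @param optics a [tissue_optics()] or `NULL` for transport-free stacks.
#' @param scene list of [fluorophore()]s (may be `NULL`).
#' @param seed the seed the stack was generated under, or `NULL`.
#' @param records optional data frame of detected-photon exit records
#'   (columns `gate`, `x`, `y`).
#' @param extra named list merged into the metadata.
#' @return An object of class `gate_stack`.
#' @export
gate_stack <- function(counts, gates, detector, optics = NULL,
                       scene = NULL, seed = NULL, records = NULL,
                       extra = list()) {
  stopifnot(inherits(gates, "gate_config"),
            inherits(detector, "detector_config"))
  d <- dim(counts)
  if (length(d) != 3 || d[1] != detector$n_px_x || d[2] != detector$n_px_y ||
      d[3] != gates$n_gates)
    stop("counts must be an n_px_x x n_px_y x n_gates array")
  if (any(counts < 0)) stop("negative counts")
  structure(c(list(counts = counts, gates = gates, detector = detector,
                   optics = optics, scene = scene, seed = seed,
                   records = records), extra),
            class = "gate_stack")
}

#' Summed intensity image of a gate stack
#'
#' Pixelwise sum of all gate pages, the plain fluorescence-intensity
#' image used for display, region selection and spot statistics.
#'
#' @param stack a [gate_stack()].
#' @return A numeric `n_px_x x n_px_y` matrix.
#' @export
total_intensity_image <- function(stack) {
  stopifnot(inherits(stack, "gate_stack"))
  rowSums(stack$counts, dims = 2)
}

#' @export
print.gate_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Gate stack: %d x %d px, %d gates, %s counts total\n",
              d[1], d[2], d[3], format(sum(x$counts), big.mark = ",")))
  print(x$gates)
  print(x$detector)
  if (!is.null(x$scene))
    for (f in x$scene) print(f)
  invisible(x)
}

#' @export
plot.gate_stack <- function(x, log = TRUE, ...) {
  img <- total_intensity_image(x)
  if (log) img <- log1p(img)
  det <- x$detector
  xs <- det$center[1] + (seq_len(det$n_px_x) - 0.5) * det$pitch_x - det$width / 2
  ys <- det$center[2] + (seq_len(det$n_px_y) - 0.5) * det$pitch_y - det$height / 2
  image(xs, ys, img, useRaster = TRUE, xlab = "x (cm)", ylab = "y (cm)",
        col = gray.colors(256, start = 0, end = 1), asp = 1, ...)
  invisible(x)
}
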