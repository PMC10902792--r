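#' Propagate fluorescence photons through the tissue slab
#'
#' Runs the random walk for `n` photons emitted isotropically from a point
#' source at depth `z`. Each photon hops with exponential free paths, is
#' absorbed at an interaction with probability `mu_a / (mu_a + mu_s)` and
#' otherwise deflected by a Henyey-Greenstein angle. A hop crossing the
#' surface plane is advanced exactly to the intersection, where the
#' Fresnel/total-internal-reflection test (if enabled) decides between
#' escape into air and specular re-entry. The medium is semi-infinite:
#' there is no bottom or lateral boundary, so with `mu_a > 0` every photon
#' terminates with probability one. Whole photons are tracked; there is no
#' statistical weight decay, so detector counts remain integral.
#'
#' @param n number of photons.
#' @param source a [source_position()] (or anything with `x`, `y`, `z`).
#' @param optics a [tissue_optics()] object.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first. Otherwise draws continue from the current RNG state.
#' @return A data frame of class `photon_fates` with one row per photon:
#'   `outcome` (factor: `absorbed`, `escaped`, `truncated`), `exit_x`,
#'   `exit_y` (cm, `NA` unless escaped), `path_length` (cm), and
#'   `n_scatter` (scattering events). Truncation (event cap reached, only
#'   possible in practice when `mu_a = 0`) is also reported via
#'   `attr(, "n_truncated")`.
#' @examples
#' fates <- propagate_photons(500, source_position(z = 0.05),
#'                            tissue_optics(), seed = 1)
#' table(fates$outcome)
#' @export
propagate_photons <- function(n, source, optics, seed = NULL) {
  stopifnot(n >= 0, inherits(optics, "tissue_optics"))
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_propagate(as.integer(n), source$x, source$y, source$z,
                        optics$n, optics$mu_a, optics$mu_s, optics$g,
                        optics$fresnel, as.integer(optics$max_events))
  out <- data.frame(
    outcome = factor(c("absorbed", "escaped", "truncated")[res$outcome + 1L],
                     levels = c("absorbed", "escaped", "truncated")),
    exit_x = res$exit_x, exit_y = res$exit_y,
    path_length = res$path_length, n_scatter = res$n_scatter
  )
  n_trunc <- sum(res$outcome == 2L)
  if (n_trunc > 0)
    warning(sprintf("%d photon(s) hit the %g-event cap and were truncated",
                    n_trunc, optics$max_events))
  attr(out, "n_truncated") <- n_trunc
  class(out) <- c("photon_fates", class(out))
  out
}
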