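#' Optical properties of a homogeneous semi-infinite tissue slab
#'
#' Bundles the bulk optical parameters used by the photon random walk. The
#' medium occupies the half-space `z >= 0` (depth measured from the surface
#' into the tissue) and is unbounded laterally and below; air (`n = 1`)
#' lies above the surface. Defaults describe highly pigmented skin in the
#' near infrared around 800 nm, the conditions under which the simulator is
#' normally run.
#'
#' @param n refractive index of the tissue (>= 1).
#' @param mu_a absorption coefficient, 1/cm.
#' @param mu_s scattering coefficient, 1/cm.
#' @param g anisotropy factor (mean cosine of the Henyey-Greenstein
#'   single-scattering deflection), in `[-1, 1]`.
#' @param fresnel logical; apply the unpolarized Fresnel/total-internal-
#'   reflection boundary test at the tissue-air interface. When `FALSE`
#'   every photon reaching the surface escapes.
#' @param max_events hard cap on interactions per photon; a photon
#'   exceeding it is reported as truncated. Guarantees termination when
#'   `mu_a = 0`.
#'
#' @return An object of class `tissue_optics`.
#' @examples
#' tissue_optics()                  # NIR skin-like defaults
#' tissue_optics(mu_s = 503)        # stronger scattering variant
#' @export
tissue_optics <- function(n = 1.4, mu_a = 0.4, mu_s = 300, g = 0.96,
                          fresnel = TRUE, max_events = 1e6) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(mu_a), mu_a >= 0,
            is.numeric(mu_s), mu_s >= 0,
            abs(g) <= 1, max_events >= 1)
  if (mu_a + mu_s <= 0)
    stop("total attenuation mu_a + mu_s must be positive")
  structure(list(n = n, mu_a = mu_a, mu_s = mu_s, g = g,
                 fresnel = isTRUE(fresnel), max_events = max_events),
            class = "tissue_optics")
}

#' @export
print.tissue_optics <- function(x, ...) {
  cat("Semi-infinite tissue optics\n")
  cat(sprintf("  n = %.3g, mu_a = %.4g /cm, mu_s = %.4g /cm, g = %.3g\n",
              x$n, x$mu_a, x$mu_s, x$g))
  cat(sprintf("  Fresnel boundary: %s, event cap: %g\n",
              if (x$fresnel) "on" else "off", x$max_events))
  invisible(x)
}

#' Fluorophore position inside the tissue
#'
#' Lateral coordinates are measured in the detector plane with the origin
#' at the detector center; `z` is the depth below the tissue surface.
#'
#' @param x,y lateral position, cm.
#' @param z depth, cm (>= 0). A source at `z = 0` sits on the surface and
#'   its photons escape at the source position without scattering.
#' @return An object of class `source_position`.
#' @export
source_position <- function(x = 0, y = 0, z = 0.1) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z), z >= 0)
  structure(list(x = x, y = y, z = z), class = "source_position")
}
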