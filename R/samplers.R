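#' Elementary Monte Carlo samplers for photon transport
#'
#' The building blocks of the random walk, exposed individually so their
#' distributions can be validated: isotropic emission directions, free
#' path lengths, Henyey-Greenstein deflections, and the Fresnel boundary
#' test. All draw from R's global random number generator, so results are
#' reproducible under [set.seed()].
#'
#' @param n number of draws.
#' @return `sample_isotropic_direction`: an `n x 3` matrix of unit vectors
#'   uniform on the sphere.
#' @examples
#' set.seed(1)
#' v <- sample_isotropic_direction(1000)
#' colMeans(v)                    # each component near 0
#' @name samplers
NULL

#' @rdname samplers
#' @export
sample_isotropic_direction <- function(n) {
  uz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  sr <- sqrt(pmax(0, 1 - uz^2))
  cbind(ux = sr * cos(phi), uy = sr * sin(phi), uz = uz)
}

#' @rdname samplers
#' @param optics a [tissue_optics()] object; the mean free path is
#'   `1 / (mu_a + mu_s)`.
#' @return `sample_step_length`: `n` exponential hop lengths in cm,
#'   `-log(xi) / (mu_a + mu_s)` with `xi` uniform on (0, 1].
#' @export
sample_step_length <- function(n, optics) {
  stopifnot(inherits(optics, "tissue_optics"))
  mu_t <- optics$mu_a + optics$mu_s
  if (mu_t <= 0) stop("total attenuation must be positive")
  -log1p(-runif(n)) / mu_t
}

#' @rdname samplers
#' @param g anisotropy factor in `[-1, 1]`.
#' @return `sample_hg_deflection`: a list with `cos_theta` (Henyey-
#'   Greenstein distributed with mean cosine `g`) and `phi` (azimuth,
#'   uniform on `[0, 2*pi)`).
#' @export
sample_hg_deflection <- function(n, g) {
  stopifnot(abs(g) <= 1)
  u <- runif(n)
  if (g == 0) {
    ct <- 2 * u - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u)
    ct <- pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
  }
  list(cos_theta = ct, phi = runif(n, 0, 2 * pi))
}

#' Fresnel reflectance and stochastic boundary test
#'
#' Unpolarized Fresnel reflectance at a planar interface, and the
#' coin-flip transmission test used when a photon reaches the tissue
#' surface. Incidence beyond the critical angle gives total internal
#' reflection (reflectance 1).
#'
#' @param cos_incidence cosine of the incidence angle from the surface
#'   normal, in `[0, 1]`. Vectorized.
#' @param n_in,n_out refractive indices on the incidence and transmission
#'   sides (tissue and air, respectively, at the top surface).
#' @return `fresnel_reflectance`: the reflectance in `[0, 1]`.
#'   `fresnel_transmit`: logical, `TRUE` where the photon is transmitted.
#' @examples
#' fresnel_reflectance(1, 1.4, 1)   # ((1.4-1)/(1.4+1))^2
#' @export
fresnel_reflectance <- function(cos_incidence, n_in, n_out) {
  stopifnot(all(cos_incidence >= 0 & cos_incidence <= 1))
  if (n_in == n_out) return(rep(0, length(cos_incidence)))
  sin_i2 <- 1 - cos_incidence^2
  sin_t2 <- (n_in / n_out)^2 * sin_i2
  R <- rep(1, length(cos_incidence))      # total internal reflection
  ok <- sin_t2 < 1
  if (any(ok)) {
    ci <- cos_incidence[ok]
    ct <- sqrt(1 - sin_t2[ok])
    rs <- (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct)
    rp <- (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci)
    R[ok] <- 0.5 * (rs^2 + rp^2)
  }
  R
}

#' @rdname fresnel_reflectance
#' @export
fresnel_transmit <- function(cos_incidence, n_in, n_out) {
  R <- fresnel_reflectance(cos_incidence, n_in, n_out)
  runif(length(R)) >= R
}
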