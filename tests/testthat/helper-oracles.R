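# Independent reference implementations used as oracles.

# Vectorized pure-R random walker implementing the same hop / binary-fate /
# Henyey-Greenstein spin / surface rules as the compiled engine, written
# against the exported samplers only. Returns escape fraction and exit
# positions. Used to cross-check the C++ engine statistically.
r_reference_walker <- function(n, z0, optics, max_iter = 50000) {
  x <- y <- numeric(n); z <- rep(z0, n)
  dir <- sample_isotropic_direction(n)
  ux <- dir[, 1]; uy <- dir[, 2]; uz <- dir[, 3]
  alive <- rep(TRUE, n)
  ex <- ey <- rep(NA_real_, n)
  p_abs <- optics$mu_a / (optics$mu_a + optics$mu_s)
  it <- 0L
  while (any(alive) && it < max_iter) {
    it <- it + 1L
    idx <- which(alive)
    s <- sample_step_length(length(idx), optics)
    cross <- uz[idx] < 0 & z[idx] + s * uz[idx] < 0
    if (any(cross)) {
      ci <- idx[cross]
      d <- z[ci] / (-uz[ci])
      px <- x[ci] + ux[ci] * d
      py <- y[ci] + uy[ci] * d
      tr <- if (optics$fresnel)
        fresnel_transmit(-uz[ci], optics$n, 1) else rep(TRUE, length(ci))
      esc <- ci[tr]
      ex[esc] <- px[tr]; ey[esc] <- py[tr]; alive[esc] <- FALSE
      rf <- ci[!tr]
      if (length(rf)) {   # mirrored direction, remaining sub-step
        rem <- s[cross][!tr] - d[!tr]
        x[rf] <- px[!tr] + ux[rf] * rem
        y[rf] <- py[!tr] + uy[rf] * rem
        uz[rf] <- -uz[rf]
        z[rf] <- uz[rf] * rem
      }
    }
    go <- idx[!cross]
    if (length(go)) {
      x[go] <- x[go] + ux[go] * s[!cross]
      y[go] <- y[go] + uy[go] * s[!cross]
      z[go] <- z[go] + uz[go] * s[!cross]
    }
    act <- which(alive)
    if (!length(act)) break
    dead <- runif(length(act)) < p_abs
    alive[act[dead]] <- FALSE
    sc <- act[!dead]
    if (length(sc)) {
      hg <- sample_hg_deflection(length(sc), optics$g)
      ct <- hg$cos_theta; st_ <- sqrt(pmax(0, 1 - ct^2))
      cp <- cos(hg$phi); sp <- sin(hg$phi)
      nearz <- abs(uz[sc]) > 0.99999
      nux <- nuy <- nuz <- numeric(length(sc))
      if (any(nearz)) {
        nux[nearz] <- st_[nearz] * cp[nearz]
        nuy[nearz] <- st_[nearz] * sp[nearz]
        nuz[nearz] <- ct[nearz] * sign(uz[sc][nearz])
      }
      o <- !nearz
      if (any(o)) {
        den <- sqrt(1 - uz[sc][o]^2)
        nux[o] <- st_[o] * (ux[sc][o] * uz[sc][o] * cp[o] -
                              uy[sc][o] * sp[o]) / den + ux[sc][o] * ct[o]
        nuy[o] <- st_[o] * (uy[sc][o] * uz[sc][o] * cp[o] +
                              ux[sc][o] * sp[o]) / den + uy[sc][o] * ct[o]
        nuz[o] <- -st_[o] * cp[o] * den + uz[sc][o] * ct[o]
      }
      nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
      ux[sc] <- nux / nrm; uy[sc] <- nuy / nrm; uz[sc] <- nuz / nrm
    }
  }
  esc <- !is.na(ex)
  list(escape_fraction = mean(esc),
       exit_r = sqrt(ex[esc]^2 + ey[esc]^2))
}

# closed-form escape probability for a purely absorbing medium (mu_s = 0,
# boundary test disabled): an isotropic point source at depth z escapes
# upward with probability (1/2) * integral_0^1 exp(-mu_a z / u) du
escape_prob_absorbing <- function(mu_a, z) {
  0.5 * stats::integrate(function(u) exp(-mu_a * z / u), 0, 1,
                         rel.tol = 1e-10)$value
}

# small gate configuration for fast tests
tiny_gates <- function(n_gates = 30) gate_config(n_gates = n_gates)

tiny_detector <- function(n = 32, width = 2)
  detector_config(width = width, height = width, n_px_x = n, n_px_y = n,
                  pe = 1)
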