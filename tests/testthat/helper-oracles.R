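# Independent oracles used by the test suite. These deliberately avoid the
# package's own rendering/blur/profile code paths.

# Analytic sum-projection of a uniform ball of radius R (nm): column depth
# 2*sqrt(R^2 - rho^2), sampled on a grid `fine_factor` times finer than
# `pixel_size`, blurred laterally with EBImage's FFT convolution (an
# independent convolution implementation), central row returned as a
# profile.
oracle_ball_profile <- function(R, sigma_xy, pixel_size = 65,
                                fine_factor = 10) {
  h <- pixel_size / fine_factor
  half <- ceiling((2.2 * R + 6 * max(sigma_xy, h)) / h)
  xs <- (-half:half) * h
  img <- outer(xs, xs, function(y, x) {
    d2 <- x^2 + y^2
    2 * sqrt(pmax(R^2 - d2, 0))
  })
  if (sigma_xy > 0) {
    s <- sigma_xy / h
    r <- ceiling(4 * s)
    k1 <- exp(-((-r:r)^2) / (2 * s^2))
    k2 <- outer(k1, k1)
    k2 <- k2 / sum(k2)
    img <- as.matrix(EBImage::filter2(EBImage::Image(img), k2))
  }
  list(position_nm = xs, intensity = img[half + 1, ])
}

# Minimal independent FWHM: level = half the maximum above the minimum,
# first/last linear-interpolated crossings. Written separately from
# diameter_at_half_max on purpose.
oracle_fwhm <- function(pos, y) {
  lev <- min(y) + 0.5 * (max(y) - min(y))
  ab <- y >= lev
  i1 <- which(!ab[-length(ab)] & ab[-1])[1]
  dn <- which(ab[-length(ab)] & !ab[-1])
  i2 <- dn[length(dn)]
  x1 <- pos[i1] + (lev - y[i1]) / (y[i1 + 1] - y[i1]) * (pos[i1 + 1] - pos[i1])
  x2 <- pos[i2] + (lev - y[i2]) / (y[i2 + 1] - y[i2]) * (pos[i2 + 1] - pos[i2])
  x2 - x1
}

# Closed-form two-sided Student t p-value from the t CDF via the
# regularized incomplete beta function (pbeta), independent of t.test.
oracle_t_p <- function(t, df) {
  x <- df / (df + t^2)
  stats::pbeta(x, df / 2, 0.5)
}

# Small scene helpers shared across tests --------------------------------

centered_scene <- function(shape = c(32, 96, 96), granules, channels,
                           optics = optics_spec(psf_sigma_xy = 0,
                                                psf_sigma_z = 0),
                           seed = 1L) {
  scene_spec(shape = shape, channels = channels, granules = granules,
             optics = optics, seed = seed)
}

scene_center <- function(shape = c(32, 96, 96),
                         optics = optics_spec()) {
  c(shape[1] * optics$z_step, shape[2] * optics$pixel_size_xy,
    shape[3] * optics$pixel_size_xy) / 2
}

# Upsample a coarse example profile to 0.5-step linear interpolation; keeps
# every level crossing of the piecewise-linear profile exactly in place
# while satisfying the >= 8 sample contract.
dense_profile <- function(intensity, positions = seq_along(intensity) - 1) {
  f <- stats::approxfun(positions, intensity)
  pos <- seq(min(positions), max(positions), by = 0.5)
  list(position_nm = pos, intensity = f(pos))
}
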