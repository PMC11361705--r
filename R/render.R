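#' Render a synthetic two-channel stack from a scene
#'
#' Rasterizes each granule as a per-voxel label density (uniform inside the
#' radius for volume mode; uniform within the peripheral shell
#' `[radius * (1 - shell_fraction), radius]` for shell mode), with 3x
#' sub-voxel supersampling to limit partial-volume aliasing. Pore punctae are
#' deposited as point emitters by trilinear interpolation. Each channel is
#' then convolved with the separable anisotropic Gaussian PSF, the uniform
#' background is added, and (unless `noise = FALSE`) Poisson shot noise plus
#' Gaussian read noise are applied. All randomness derives from the scene
#' seed, so rendering the same scene twice is bit-identical.
#'
#' @param scene A [scene_spec()].
#' @param noise Apply Poisson + read noise? Default `TRUE`. With `FALSE` the
#'   returned stack is the noise-free expectation, useful for oracle checks.
#' @param supersample Sub-voxel sampling factor per axis for granule
#'   interiors (default 3).
#' @return An object of class `image_stack`: a list with `channels` (named
#'   list of 3D arrays, dim = (z, y, x)), `calibration`
#'   (`z_step`, `pixel_size_xy`, nm), and `ground_truth` (per-emitter true
#'   parameters; one record per emitter in the scene).
#' @examples
#' sc <- scene_spec(shape = c(16, 48, 48),
#'                  granules = list(granule_spec(c(1120, 1560, 1560), 300,
#'                                               channel = "strep")),
#'                  optics = optics_spec(psf_sigma_xy = 0, psf_sigma_z = 0))
#' stk <- render_scene(sc, noise = FALSE)
#' range(stk$channels$strep)
#' @export
render_scene <- function(scene, noise = TRUE, supersample = 3L) {
  stopifnot(inherits(scene, "scene_spec"))
  op <- scene$optics
  shape <- scene$shape
  chans <- lapply(scene$channels, function(ch) array(0, shape))
  names(chans) <- scene$channels

  for (g in scene$granules)
    chans[[g$channel]] <- chans[[g$channel]] +
      rasterize_granule(g, shape, op, supersample)

  gt_pores <- list()
  for (i in seq_along(scene$pore_rings)) {
    p <- scene$pore_rings[[i]]
    pos <- pore_positions(p)
    gt_pores[[i]] <- pos
    for (ch in names(p$channel_scaling)) {
      if (!ch %in% scene$channels) next
      amp <- p$pore_amplitude * p$channel_scaling[[ch]]
      for (k in seq_len(nrow(pos)))
        chans[[ch]] <- deposit_point(chans[[ch]], pos[k, ], amp, op)
    }
  }

  sz <- op$psf_sigma_z / op$z_step
  sxy <- op$psf_sigma_xy / op$pixel_size_xy
  for (ci in seq_along(scene$channels)) {
    ch <- scene$channels[ci]
    a <- blur_3d(chans[[ch]], sz, sxy) + op$background
    if (noise) {
      # noise stream keyed by channel position, so renaming channel labels
      # permutes stack channels and nothing else
      a <- with_seed(scene$seed + 7919L * ci, {
        n <- rpois(length(a), lambda = pmax(a, 0))
        if (op$read_noise_sd > 0)
          n <- n + rnorm(length(a), 0, op$read_noise_sd)
        array(pmax(n, 0), dim(a))
      })
    }
    chans[[ch]] <- a
  }

  gt <- list(
    granules = if (length(scene$granules))
      data.frame(
        center_z = vapply(scene$granules, function(g) g$center[1], 0),
        center_y = vapply(scene$granules, function(g) g$center[2], 0),
        center_x = vapply(scene$granules, function(g) g$center[3], 0),
        radius = vapply(scene$granules, function(g) g$radius, 0),
        labelling_mode = vapply(scene$granules, function(g) g$labelling_mode, ""),
        shell_fraction = vapply(scene$granules, function(g) g$shell_fraction, 0),
        channel = vapply(scene$granules, function(g) g$channel, "")
      ) else NULL,
    pores = if (length(gt_pores)) do.call(rbind, gt_pores) else NULL
  )

  structure(list(channels = chans,
                 calibration = list(z_step = op$z_step,
                                    pixel_size_xy = op$pixel_size_xy),
                 ground_truth = gt,
                 seed = scene$seed),
            class = "image_stack")
}

# Per-voxel mean label density of a sphere/shell over supersample^3 points
# per voxel, restricted to the granule's bounding box. Amplitude is photons
# per voxel at full occupancy.
rasterize_granule <- function(g, shape, op, supersample) {
  vox <- c(op$z_step, op$pixel_size_xy, op$pixel_size_xy)
  r_in <- if (g$labelling_mode == "shell") g$radius * (1 - g$shell_fraction) else 0
  a <- array(0, shape)
  lo <- pmax(1L, floor((g$center - g$radius) / vox - 1) + 1L)
  hi <- pmin(shape, ceiling((g$center + g$radius) / vox + 1))
  if (any(lo > hi)) return(a)
  s <- as.integer(supersample)
  off <- (seq_len(s) - 0.5) / s  # sub-voxel fractions in (0,1)
  idx <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
  sub <- expand.grid(dz = off, dy = off, dx = off)
  frac <- numeric(nrow(idx))
  for (k in seq_len(nrow(sub))) {
    pz <- (idx$z - 1 + sub$dz[k]) * vox[1] - g$center[1]
    py <- (idx$y - 1 + sub$dy[k]) * vox[2] - g$center[2]
    px <- (idx$x - 1 + sub$dx[k]) * vox[3] - g$center[3]
    d2 <- pz^2 + py^2 + px^2
    frac <- frac + (d2 <= g$radius^2 & d2 >= r_in^2)
  }
  frac <- frac / nrow(sub)
  a[cbind(idx$z, idx$y, idx$x)] <- frac * g$amplitude
  a
}

# Evenly spaced punctae on the nucleus mid-plane rim circle (constant z).
pore_positions <- function(p) {
  if (p$n_pores == 0L)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("z", "y", "x"))))
  th <- 2 * pi * (seq_len(p$n_pores) - 1) / p$n_pores
  cbind(z = rep(p$nucleus_center[1], p$n_pores),
        y = p$nucleus_center[2] + p$nucleus_radius * sin(th),
        x = p$nucleus_center[3] + p$nucleus_radius * cos(th))
}

# Trilinear deposition of a point emitter of total brightness `amp` into the
# 8 voxels around its physical position (voxel centers at (i - 0.5) * size).
deposit_point <- function(a, pos_nm, amp, op) {
  vox <- c(op$z_step, op$pixel_size_xy, op$pixel_size_xy)
  f <- pos_nm / vox + 0.5  # fractional voxel index (1-based centers)
  i0 <- floor(f)
  w1 <- f - i0
  d <- dim(a)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- i0[1] + bz; iy <- i0[2] + by; ix <- i0[3] + bx
    if (iz < 1 || iy < 1 || ix < 1 || iz > d[1] || iy > d[2] || ix > d[3]) next
    w <- (if (bz) w1[1] else 1 - w1[1]) *
         (if (by) w1[2] else 1 - w1[2]) *
         (if (bx) w1[3] else 1 - w1[3])
    a[iz, iy, ix] <- a[iz, iy, ix] + amp * w
  }
  a
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Image stack: %d channel(s) [%s], %d z-slices of %d x %d px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  cat(sprintf("  calibration: %g nm/px lateral, %g nm z-step\n",
              x$calibration$pixel_size_xy, x$calibration$z_step))
  if (!is.null(x$ground_truth$granules))
    cat(sprintf("  ground truth: %d granule(s)\n",
                nrow(x$ground_truth$granules)))
  invisible(x)
}
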