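#' Optical acquisition parameters
#'
#' Describes the microscope geometry and camera noise used when rendering a
#' synthetic stack: lateral pixel size (a 6.5 micron camera pixel behind a
#' 100x objective gives 65 nm/pixel), axial step between z-slices, the
#' anisotropic Gaussian point-spread-function widths, a uniform background
#' level and the Gaussian read-noise SD of the detector.
#'
#' @param pixel_size_xy Lateral pixel size, nm/pixel.
#' @param z_step Axial slice spacing, nm.
#' @param psf_sigma_xy Lateral PSF Gaussian sigma, nm. Zero disables lateral
#'   blur.
#' @param psf_sigma_z Axial PSF Gaussian sigma, nm. Zero disables axial blur.
#' @param background Uniform background, photons/voxel.
#' @param read_noise_sd Gaussian read-noise SD, detector units.
#' @return An object of class `optics_spec`.
#' @examples
#' optics_spec(psf_sigma_xy = 90, psf_sigma_z = 300)
#' @export
optics_spec <- function(pixel_size_xy = 65, z_step = 140,
                        psf_sigma_xy = 90, psf_sigma_z = 300,
                        background = 0, read_noise_sd = 0) {
  if (!is_pos_scalar(pixel_size_xy)) stopf("pixel_size_xy must be > 0")
  if (!is_pos_scalar(z_step)) stopf("z_step must be > 0")
  stopifnot(psf_sigma_xy >= 0, psf_sigma_z >= 0,
            background >= 0, read_noise_sd >= 0)
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 background = background, read_noise_sd = read_noise_sd),
            class = "optics_spec")
}

#' Spherical granule emitter
#'
#' A cytoplasmic granule rendered either with uniform label density through
#' its volume (`"volume"`, the streptavidin-like stain that penetrates the
#' granule) or with label restricted to a peripheral shell (`"shell"`, the
#' antibody-like stain excluded from the dense interior). Shell thickness is
#' `shell_fraction * radius`; `shell_fraction = 1` reduces to volume mode.
#'
#' @param center Numeric length-3 position (z, y, x), nm.
#' @param radius Granule radius, nm.
#' @param labelling_mode `"volume"` or `"shell"`.
#' @param shell_fraction Shell thickness as a fraction of radius, in (0, 1].
#' @param amplitude Photons per unit label volume (nm^3 scale absorbed into
#'   this constant).
#' @param channel Semantic channel label, e.g. `"HA"` or `"strep"`.
#' @return An object of class `granule_spec`.
#' @export
granule_spec <- function(center, radius, labelling_mode = c("volume", "shell"),
                         shell_fraction = 1, amplitude = 1, channel = "strep") {
  labelling_mode <- match.arg(labelling_mode)
  if (!is_pos_scalar(radius)) stopf("granule radius must be > 0")
  stopifnot(length(center) == 3L, is.numeric(center))
  if (labelling_mode == "shell" &&
      (shell_fraction <= 0 || shell_fraction > 1))
    stopf("shell mode requires 0 < shell_fraction <= 1")
  structure(list(center = as.numeric(center), radius = radius,
                 labelling_mode = labelling_mode,
                 shell_fraction = shell_fraction,
                 amplitude = amplitude, channel = channel),
            class = "granule_spec")
}

#' Nuclear-pore ring of point emitters
#'
#' Punctate nuclear-rim signal: `n_pores` point emitters placed evenly on the
#' mid-plane rim circle of a spherical nucleus, emulating nuclear pores seen
#' in a single plane. Per-channel amplitude scaling lets the same pore
#' geometry carry different brightness in each stain channel (e.g. an
#' antibody-inaccessible pore protein has low anti-HA scaling).
#'
#' @param nucleus_center Numeric length-3 (z, y, x), nm.
#' @param nucleus_radius Nucleus radius, nm.
#' @param n_pores Number of pore punctae (>= 0).
#' @param pore_amplitude Photons per puncta before channel scaling.
#' @param channel_scaling Named numeric vector, channel label -> scale factor.
#' @return An object of class `pore_ring_spec`.
#' @export
pore_ring_spec <- function(nucleus_center, nucleus_radius, n_pores = 16,
                           pore_amplitude = 500,
                           channel_scaling = c(strep = 1, HA = 1)) {
  stopifnot(length(nucleus_center) == 3L, is.numeric(nucleus_center))
  if (!is_pos_scalar(nucleus_radius)) stopf("nucleus_radius must be > 0")
  if (!is_count(n_pores)) stopf("n_pores must be a count >= 0")
  stopifnot(!is.null(names(channel_scaling)), all(channel_scaling >= 0))
  structure(list(nucleus_center = as.numeric(nucleus_center),
                 nucleus_radius = nucleus_radius,
                 n_pores = as.integer(n_pores),
                 pore_amplitude = pore_amplitude,
                 channel_scaling = channel_scaling),
            class = "pore_ring_spec")
}

#' Full synthetic scene description
#'
#' Collects emitters, optics, channel labels, volume shape and a seed into a
#' generative scene. Every emitter must lie within the physical volume
#' (`shape * calibration`); channel labels must be unique.
#'
#' @param shape Integer length-3 voxel counts (z, y, x). Default `c(48, 256,
#'   256)`, i.e. 48 z-slices of 256 x 256 pixels.
#' @param channels Character vector of unique channel labels.
#' @param granules List of [granule_spec()] objects.
#' @param pore_rings List of [pore_ring_spec()] objects.
#' @param optics An [optics_spec()].
#' @param seed Integer seed driving all stochastic rendering.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(48, 256, 256), channels = c("HA", "strep"),
                       granules = list(), pore_rings = list(),
                       optics = optics_spec(), seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (anyDuplicated(channels)) stopf("channel labels must be unique")
  stopifnot(inherits(optics, "optics_spec"))
  extent <- physical_extent(shape, optics)  # (z, y, x) nm
  for (i in seq_along(granules)) {
    g <- granules[[i]]
    stopifnot(inherits(g, "granule_spec"))
    if (!g$channel %in% channels)
      stopf("granule %d uses unknown channel '%s'", i, g$channel)
    if (any(g$center < 0) || any(g$center > extent))
      stopf("granule %d at (%s) nm lies outside the %s nm volume",
            i, paste(round(g$center), collapse = ", "),
            paste(round(extent), collapse = " x "))
  }
  for (i in seq_along(pore_rings)) {
    p <- pore_rings[[i]]
    stopifnot(inherits(p, "pore_ring_spec"))
    if (any(p$nucleus_center < 0) || any(p$nucleus_center > extent))
      stopf("pore ring %d center lies outside the volume", i)
  }
  structure(list(shape = as.integer(shape), channels = channels,
                 granules = granules, pore_rings = pore_rings,
                 optics = optics, seed = as.integer(seed)),
            class = "scene_spec")
}

physical_extent <- function(shape, optics) {
  c(shape[1] * optics$z_step,
    shape[2] * optics$pixel_size_xy,
    shape[3] * optics$pixel_size_xy)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d x %d voxels (z,y,x), channels: %s\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  %d granule(s), %d pore ring(s); pixel %g nm, z-step %g nm; seed %d\n",
              length(x$granules), length(x$pore_rings),
              x$optics$pixel_size_xy, x$optics$z_step, x$seed))
  invisible(x)
}
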