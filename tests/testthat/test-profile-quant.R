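make_proj <- function(img, px = 65) {
  structure(list(channels = list(strep = img), method = "sum",
                 calibration = list(z_step = 140, pixel_size_xy = px),
                 source_seed = 1L),
            class = "projection")
}

test_that("projections reduce over z correctly and conserve intensity", {
  a <- array(1, c(72, 5, 5))
  stk <- structure(list(channels = list(strep = a),
                        calibration = list(z_step = 140, pixel_size_xy = 65),
                        ground_truth = NULL, seed = 1L),
                   class = "image_stack")
  ps <- project(stk, "sum")
  expect_true(all(ps$channels$strep == 72))
  b <- array(stats::rnorm(16 * 6 * 7), c(16, 6, 7))
  stk2 <- structure(list(channels = list(strep = b),
                         calibration = list(z_step = 140, pixel_size_xy = 65),
                         ground_truth = NULL, seed = 1L),
                    class = "image_stack")
  expect_equal(sum(project(stk2, "sum")$channels$strep), sum(b))
  pm <- project(stk2, "max")
  expect_equal(pm$channels$strep[3, 4], max(b[, 3, 4]))
  expect_error(project(stk2, "median"))
})

test_that("profile extraction interpolates, averages and respects geometry", {
  img <- matrix(3.5, 41, 41)
  p <- extract_profile(make_proj(img), c(21, 21), 0, 30, 3, "strep")
  expect_true(all(abs(p$intensity - 3.5) < 1e-12))
  expect_gte(length(p$intensity), 8)
  expect_true(all(diff(p$position_nm) > 0))

  # isotropic disk: profiles at 0 and 90 degrees agree
  xs <- 1:41
  disk <- outer(xs, xs, function(y, x) pmax(15^2 - (y - 21)^2 - (x - 21)^2, 0))
  p0 <- extract_profile(make_proj(disk), c(21, 21), 0, 36, 3, "strep")
  p90 <- extract_profile(make_proj(disk), c(21, 21), 90, 36, 3, "strep")
  rms <- sqrt(mean((p0$intensity - p90$intensity)^2)) / max(p0$intensity)
  expect_lt(rms, 0.01)

  expect_error(extract_profile(make_proj(disk), c(21, 21), 45, 200, 3,
                               "strep"), "exits")
  expect_error(extract_profile(make_proj(disk), c(21, 21), 0, 36, 3, "blue"),
               "unknown channel")
})

test_that("diameter at 50% fluorescence follows the crossing conventions", {
  # triangle: level 50 crossed at 1 and 3 -> diameter 2
  tri <- dense_profile(c(0, 50, 100, 50, 0))
  d <- diameter_at_half_max(tri)
  expect_equal(d$diameter_nm, 2)
  expect_identical(d$flag, "ok")

  # double peak: outermost crossings at 0.5 and 3.5 -> outer width 3
  dbl <- dense_profile(c(0, 100, 40, 100, 0))
  expect_equal(diameter_at_half_max(dbl)$diameter_nm, 3)

  # level not crossed on both sides: flagged, no diameter
  mono <- dense_profile(c(0, 10, 30, 60, 100))
  dm <- diameter_at_half_max(mono)
  expect_identical(dm$flag, "unbounded")
  expect_true(is.na(dm$diameter_nm))

  expect_error(diameter_at_half_max(list(position_nm = 0:4,
                                         intensity = c(0, 50, 100, 50, 0))),
               "fewer than 8")
})

test_that("projected-sphere diameter approaches the half-maximum chord sqrt(3)*r", {
  # closed form: sum projection of a uniform ball is prop. to
  # sqrt(r^2 - x^2); its half-maximum width is sqrt(3)*r
  r <- 10
  pos <- seq(-20, 20, by = 0.05)
  prof <- list(position_nm = pos,
               intensity = sqrt(pmax(r^2 - pos^2, 0)))
  d <- diameter_at_half_max(prof, baseline = "zero")
  expect_equal(d$diameter_nm, sqrt(3) * r, tolerance = 1e-4)
})

test_that("peak counting uses prominence relative to the profile range", {
  expect_equal(count_peaks(list(position_nm = 0:4,
                                intensity = c(0, 50, 100, 50, 0))), 1L)
  expect_equal(count_peaks(list(position_nm = 0:4,
                                intensity = c(0, 100, 40, 100, 0)),
                           min_prominence_fraction = 0.3), 2L)
  # a shallow dip is not two peaks at the same threshold
  expect_equal(count_peaks(list(position_nm = 0:4,
                                intensity = c(0, 100, 90, 100, 0)),
                           min_prominence_fraction = 0.3), 1L)
  expect_error(count_peaks(list(position_nm = 0:4,
                                intensity = c(0, 1, 0, 1, 0)),
                           min_prominence_fraction = 2), "prominence")
})

test_that("rendered shell granules show two peaks where volume granules show one", {
  op <- optics_spec(psf_sigma_xy = 60, psf_sigma_z = 200)
  shp <- c(32, 96, 96)
  ctr <- scene_center(shp, op)
  r <- 600
  mk <- function(mode, sf) {
    sc <- scene_spec(shp, "strep",
                     list(granule_spec(ctr, r, mode, sf, amplitude = 100,
                                       channel = "strep")),
                     optics = op, seed = 2)
    pr <- project(render_scene(sc, noise = FALSE), "sum")
    extract_profile(pr, c(48.5, 48.5), 0, 60, 3, "strep")
  }
  expect_equal(count_peaks(mk("shell", 0.2)), 2L)
  expect_equal(count_peaks(mk("volume", 1)), 1L)
})

test_that("granule detection finds centers and orders by integrated intensity", {
  op <- optics_spec(psf_sigma_xy = 90, psf_sigma_z = 300,
                    background = 1, read_noise_sd = 0.5)
  shp <- c(24, 96, 96)
  g1 <- granule_spec(c(1680, 2000, 2000), 500, "volume", amplitude = 80,
                     channel = "strep")
  g2 <- granule_spec(c(1680, 4300, 4300), 330, "volume", amplitude = 80,
                     channel = "strep")
  sc <- scene_spec(shp, "strep", list(g1, g2), optics = op, seed = 6)
  det <- detect_granules(project(render_scene(sc), "sum"), "strep")
  expect_equal(nrow(det), 2)
  # larger granule first, centroid within 1 px of truth
  expect_equal(det$y[1], 2000 / 65 + 0.5, tolerance = 1 / det$y[1])
  expect_equal(det$x[1], 2000 / 65 + 0.5, tolerance = 1 / det$x[1])
  expect_gt(det$integrated[1], det$integrated[2])

  blank <- make_proj(matrix(0, 50, 50))
  d0 <- detect_granules(blank, "strep")
  expect_equal(nrow(d0), 0)
  expect_identical(attr(d0, "flag"), "none-detected")
})

test_that("granule measurements form quotients and propagate QC flags", {
  # synthetic projection with known half-max widths in the two channels
  xs <- 1:81
  mkimg <- function(w) outer(xs, xs, function(y, x)
    100 * exp(-((y - 41)^2 + (x - 41)^2) / (2 * (w / 2.3548)^2)))
  proj <- structure(list(channels = list(HA = mkimg(28), strep = mkimg(20)),
                         method = "sum",
                         calibration = list(z_step = 140, pixel_size_xy = 1),
                         source_seed = 1L),
                    class = "projection")
  m <- measure_granule(proj, c(41, 41), length_px = 78, baseline = "zero")
  expect_equal(m$quotient, 28 / 20, tolerance = 0.01)
  expect_identical(m$flag, "ok")

  # identical channels: quotient exactly 1
  proj2 <- proj; proj2$channels$HA <- proj2$channels$strep
  m2 <- measure_granule(proj2, c(41, 41), length_px = 78)
  expect_equal(m2$quotient, 1)

  # strep channel never dropping below half: flagged, quotient undefined
  proj3 <- proj; proj3$channels$strep <- mkimg(20) + 150
  m3 <- measure_granule(proj3, c(41, 41), length_px = 78, baseline = "zero")
  expect_true(is.na(m3$quotient))
  expect_match(m3$flag, "unbounded")
})

test_that("replicate summaries compute mean, sample SD and peak fractions", {
  meas <- data.frame(replicate = c(1, 1, 1, 2, 3),
                     quotient = c(1.2, 1.4, 1.6, 1.1, NA),
                     peaks_ha = c(2, 2, 1, 2, 1),
                     peaks_strep = c(1, 1, 1, 1, 1))
  expect_warning(s <- summarise_replicates(meas), "excluded")
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_quotient[1], 1.4)
  expect_equal(s$sd_quotient[1], 0.2)
  expect_equal(s$frac_double_ha[1], 2 / 3)
  expect_true(is.na(s$sd_quotient[2]))  # single quotient: SD undefined
})

test_that("the estimated mean quotient is stable under reseeding", {
  means <- vapply(1:5, function(s) {
    sim <- simulate_granule_experiment(n_replicates = 3,
                                       cells_per_replicate = 6,
                                       seed = 500 + s)
    fit <- granule_quant(sim$stacks, sim$replicate)
    mean(fit$measurements$quotient, na.rm = TRUE)
  }, 0)
  expect_lt(stats::sd(means), 0.05)
})

test_that("shell staining widens the measured diameter (quotient > 1)", {
  sim <- simulate_granule_experiment(n_replicates = 2, cells_per_replicate = 4,
                                     seed = 14)
  fit <- granule_quant(sim$stacks, sim$replicate)
  expect_true(all(fit$replicates$mean_quotient > 1))
  # swapping the channel roles inverts each quotient exactly
  fit_sw <- granule_quant(sim$stacks, sim$replicate,
                          ha_channel = "strep", strep_channel = "HA",
                          detect_channel = "strep")
  ok <- !is.na(fit$measurements$quotient)
  expect_equal(fit_sw$measurements$quotient[ok],
               1 / fit$measurements$quotient[ok])
})
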