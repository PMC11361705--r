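#' Simulate a granule co-staining experiment
#'
#' Generates the stack ensemble the diameter-quotient analysis consumes:
#' `n_replicates` biological replicates of `cells_per_replicate` cells, each
#' cell a two-channel crop containing one cytoplasmic granule labelled in
#' shell mode in the antibody channel and in volume mode in the streptavidin
#' channel, on identical geometry. Granule radius is jittered per cell from
#' a seeded log-normal; replicate-level amplitude jitter emulates
#' staining-batch variation.
#'
#' @param n_replicates Number of biological replicates (>= 1).
#' @param cells_per_replicate Stacks per replicate (>= 1).
#' @param radius_mean,radius_cv Mean granule radius (nm) and coefficient of
#'   variation of the per-cell log-normal jitter. `radius_cv = 0` (with
#'   `jitter = FALSE`) fixes the geometry.
#' @param shell_fraction Shell thickness fraction for the antibody channel.
#' @param amplitude Photons per unit label density, streptavidin channel.
#' @param ha_amplitude Same for the antibody channel (defaults to
#'   `amplitude`).
#' @param channels Length-2 channel labels: `c(antibody, streptavidin)`.
#'   The first is rendered in shell mode, the second in volume mode.
#' @param optics An [optics_spec()].
#' @param shape Per-cell crop shape (z, y, x) in voxels.
#' @param noise Apply Poisson/read noise (default `TRUE`).
#' @param jitter Apply per-cell radius and per-replicate amplitude jitter
#'   (default `TRUE`). With `FALSE` every cell shares identical ground truth.
#' @param seed Integer master seed.
#' @return A list of class `granule_sim`: `stacks` (list of [render_scene()]
#'   outputs), `replicate` (integer vector, parallel to `stacks`), and
#'   `ground_truth` (data.frame of true per-cell parameters).
#' @export
simulate_granule_experiment <- function(n_replicates = 3,
                                        cells_per_replicate = 25,
                                        radius_mean = 600, radius_cv = 0.15,
                                        shell_fraction = 0.25,
                                        amplitude = 150,
                                        ha_amplitude = amplitude,
                                        channels = c("HA", "strep"),
                                        optics = optics_spec(background = 2,
                                                             read_noise_sd = 1),
                                        shape = c(32, 96, 96),
                                        noise = TRUE, jitter = TRUE,
                                        seed = 1L) {
  if (!is_count(n_replicates) || n_replicates < 1)
    stopf("n_replicates must be >= 1")
  if (!is_count(cells_per_replicate) || cells_per_replicate < 1)
    stopf("cells_per_replicate must be >= 1")
  stopifnot(length(channels) == 2L)
  extent <- physical_extent(shape, optics)
  center <- extent / 2

  params <- with_seed(seed, {
    rep_amp <- if (jitter) exp(rnorm(n_replicates, 0, 0.1)) else rep(1, n_replicates)
    df <- expand.grid(cell = seq_len(cells_per_replicate),
                      replicate = seq_len(n_replicates))
    n <- nrow(df)
    sdlog <- if (jitter) sqrt(log(1 + radius_cv^2)) else 0
    df$radius <- radius_mean * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    df$amp_scale <- rep_amp[df$replicate]
    df$cell_seed <- sample.int(2^30, n)
    df
  })

  stacks <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    r <- min(params$radius[i], 0.4 * min(extent))  # keep granule well inside
    sc <- scene_spec(
      shape = shape, channels = channels,
      granules = list(
        granule_spec(center, r, "shell", shell_fraction,
                     amplitude = ha_amplitude * params$amp_scale[i],
                     channel = channels[1]),
        granule_spec(center, r, "volume",
                     amplitude = amplitude * params$amp_scale[i],
                     channel = channels[2])),
      optics = optics, seed = params$cell_seed[i])
    stacks[[i]] <- render_scene(sc, noise = noise)
  }

  structure(list(stacks = stacks, replicate = params$replicate,
                 ground_truth = params, channels = channels),
            class = "granule_sim")
}

#' @export
print.granule_sim <- function(x, ...) {
  cat(sprintf("Simulated granule experiment: %d stacks in %d replicate(s)\n",
              length(x$stacks), max(x$replicate)))
  cat(sprintf("  channels: %s (shell-labelled), %s (volume-labelled)\n",
              x$channels[1], x$channels[2]))
  invisible(x)
}

#' Simulate nuclear-pore-ring cells for accessibility scoring
#'
#' Renders `n_cells` two-channel stacks, each carrying one ring of nuclear
#' pore punctae with full streptavidin amplitude and antibody amplitude
#' scaled by `ha_scaling` — the ground-truth accessibility of the tagged
#' protein. Both channels share the same uniform background.
#'
#' @param n_cells Number of cells (>= 1).
#' @param ha_scaling True antibody/streptavidin amplitude ratio (>= 0).
#' @param n_pores Punctae per ring.
#' @param pore_amplitude Photons per puncta in the streptavidin channel.
#' @param nucleus_radius Nucleus radius, nm.
#' @param channels Length-2 labels `c(antibody, streptavidin)`.
#' @param optics An [optics_spec()]; give it a nonzero `background` so the
#'   background region is informative.
#' @param shape Per-cell crop shape (z, y, x) voxels.
#' @param noise Apply Poisson/read noise (default `TRUE`).
#' @param seed Integer master seed.
#' @return List of class `pore_sim`: `stacks` (list of `image_stack`),
#'   `ha_scaling`.
#' @export
simulate_pore_cells <- function(n_cells = 12, ha_scaling = 0.5,
                                n_pores = 16, pore_amplitude = 4000,
                                nucleus_radius = 1200,
                                channels = c("HA", "strep"),
                                optics = optics_spec(background = 5,
                                                     read_noise_sd = 1),
                                shape = c(24, 96, 96),
                                noise = TRUE, seed = 1L) {
  if (!is_count(n_cells) || n_cells < 1) stopf("n_cells must be >= 1")
  stopifnot(ha_scaling >= 0, length(channels) == 2L)
  extent <- physical_extent(shape, optics)
  seeds <- with_seed(seed, sample.int(2^30, n_cells))
  scaling <- stats::setNames(c(ha_scaling, 1), channels)
  stacks <- lapply(seq_len(n_cells), function(i) {
    sc <- scene_spec(shape = shape, channels = channels,
                     pore_rings = list(pore_ring_spec(
                       extent / 2, nucleus_radius, n_pores, pore_amplitude,
                       channel_scaling = scaling)),
                     optics = optics, seed = seeds[i])
    render_scene(sc, noise = noise)
  })
  structure(list(stacks = stacks, ha_scaling = ha_scaling,
                 channels = channels),
            class = "pore_sim")
}

#' Simulation design for a synthetic LFQ table
#'
#' Describes a label-free quantification experiment: per-protein base log2
#' abundances, a true log2 enrichment effect added to the bait group, and a
#' missing-not-at-random dropout model in which the probability that a
#' measurement is missing decreases logistically with its log2 intensity
#' (emulating the detection limit of the mass spectrometer).
#'
#' @param n_proteins Number of protein groups.
#' @param group_sizes Named integer vector of replicate counts; must contain
#'   a `control` entry. Any group entering a t-test needs >= 2 replicates.
#' @param true_effect Per-protein true log2 effect (bait - control); recycled
#'   to `n_proteins`.
#' @param base_mean,base_sd Mean and SD of the between-protein base log2
#'   intensity distribution.
#' @param rep_sd Within-group replicate SD on the log2 scale.
#' @param dropout_midpoint Log2 intensity at which dropout probability is
#'   0.5. `-Inf` disables dropout.
#' @param dropout_slope Logistic steepness (per log2 unit); 0 with a finite
#'   midpoint gives constant probability 0.5, so disable via midpoint.
#' @param seed Integer seed.
#' @return An object of class `lfq_sim_spec`.
#' @export
lfq_sim_spec <- function(n_proteins = 300,
                         group_sizes = c(bait = 3, control = 3),
                         true_effect = 0,
                         base_mean = 25, base_sd = 2, rep_sd = 0.4,
                         dropout_midpoint = 22, dropout_slope = 1,
                         seed = 1L) {
  if (!is_count(n_proteins) || n_proteins < 1) stopf("n_proteins must be >= 1")
  if (is.null(names(group_sizes)) || !"control" %in% names(group_sizes))
    stopf("group_sizes must be named and include 'control'")
  if (any(group_sizes < 1)) stopf("every group needs >= 1 replicate")
  stopifnot(base_sd > 0, rep_sd >= 0, dropout_slope >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 group_sizes = group_sizes,
                 true_effect = rep_len(true_effect, n_proteins),
                 base_mean = base_mean, base_sd = base_sd, rep_sd = rep_sd,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope, seed = as.integer(seed)),
            class = "lfq_sim_spec")
}

#' Simulate a raw-scale LFQ intensity table with dropout
#'
#' Draws per-protein base log2 intensities, adds the true effect to the bait
#' columns and replicate noise to every cell, applies the logistic
#' intensity-dependent dropout, and returns the table on the raw intensity
#' scale (`2^log2`), with dropped cells as `NA`. The true effects are
#' returned for recovery tests.
#'
#' @param spec An [lfq_sim_spec()].
#' @return A list of class `lfq_sim`: `table` (an [lfq_table()]),
#'   `true_effect` (numeric per protein), and `log2_complete` (the noise-free
#'   complete log2 matrix, before dropout).
#' @export
simulate_lfq_table <- function(spec) {
  stopifnot(inherits(spec, "lfq_sim_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  samples <- paste0(groups, "_", unlist(lapply(spec$group_sizes, seq_len)))
  n <- spec$n_proteins
  m <- length(samples)
  out <- with_seed(spec$seed, {
    base <- rnorm(n, spec$base_mean, spec$base_sd)
    mu <- outer(base, rep(1, m))
    bait_cols <- groups != "control"
    mu[, bait_cols] <- mu[, bait_cols] + spec$true_effect
    x <- mu + matrix(rnorm(n * m, 0, spec$rep_sd), n, m)
    p_miss <- if (is.infinite(spec$dropout_midpoint) && spec$dropout_midpoint < 0)
      matrix(0, n, m)
    else
      stats::plogis(-(x - spec$dropout_midpoint) * spec$dropout_slope)
    miss <- matrix(stats::runif(n * m), n, m) < p_miss
    list(x = x, miss = miss, mu = mu)
  })
  raw <- 2^out$x
  raw[out$miss] <- NA_real_
  colnames(raw) <- samples
  rownames(raw) <- sprintf("P%04d", seq_len(n))
  tab <- lfq_table(raw, stats::setNames(groups, samples))
  structure(list(table = tab, true_effect = spec$true_effect,
                 log2_complete = out$x),
            class = "lfq_sim")
}
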