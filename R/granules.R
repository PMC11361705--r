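#' Detect candidate granules in a projection
#'
#' Thresholds the detection channel (by default Otsu's method via EBImage),
#' labels connected components, discards those below `min_area_px`, and
#' returns intensity-weighted centroids sorted by integrated intensity,
#' largest first — so taking the first detection emulates measuring "one of
#' the larger granules" of a cell. Detection is normally run on the
#' streptavidin channel, the stain that fills granule interiors.
#'
#' @param proj A [project()] output.
#' @param channel Channel to detect on (default `"strep"` if present, else
#'   the first channel).
#' @param min_area_px Minimum component area in pixels (default 5).
#' @param threshold `"otsu"` (default) or a numeric absolute threshold.
#' @return data.frame with columns `y`, `x` (pixel centroids), `area_px`,
#'   `integrated` — sorted by `integrated` descending; zero rows (with
#'   attribute `flag = "none-detected"`) when nothing exceeds the threshold.
#' @export
detect_granules <- function(proj, channel = NULL, min_area_px = 5,
                            threshold = "otsu") {
  stopifnot(inherits(proj, "projection"))
  if (is.null(channel))
    channel <- if ("strep" %in% names(proj$channels)) "strep"
               else names(proj$channels)[1]
  img <- proj$channels[[channel]]
  if (is.null(img)) stopf("unknown channel '%s'", channel)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) Inf  # flat image: nothing detectable
    else {
      sc <- (img - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
    }
  } else if (is.numeric(threshold)) threshold
  else stopf("threshold must be \"otsu\" or a number")
  mask <- img > thr
  empty <- data.frame(y = numeric(0), x = numeric(0),
                      area_px = integer(0), integrated = numeric(0))
  if (!any(mask)) {
    attr(empty, "flag") <- "none-detected"
    return(empty)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(lab)
  dim(lab) <- dim(img)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_area_px) return(NULL)
    w <- img[px]
    data.frame(y = sum(px[, 1] * w) / sum(w),
               x = sum(px[, 2] * w) / sum(w),
               area_px = nrow(px), integrated = sum(w))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    attr(empty, "flag") <- "none-detected"
    return(empty)
  }
  rows[order(-rows$integrated), , drop = FALSE]
}

#' Measure one granule across both stain channels
#'
#' Extracts the same line segment in the antibody and streptavidin channels
#' of a projection, computes the diameter at 50% fluorescence and the peak
#' count per channel, and forms the diameter quotient
#' (antibody diameter / streptavidin diameter). The quotient is undefined
#' (and the measurement flagged) whenever either diameter is flagged.
#'
#' @param proj A two-channel [project()] output.
#' @param center Segment midpoint, (y, x) pixels (e.g. from
#'   [detect_granules()]).
#' @param ha_channel,strep_channel Channel labels for the antibody and
#'   streptavidin stains.
#' @param angle,length_px,width_px Segment geometry, see
#'   [extract_profile()].
#' @param min_prominence_fraction Peak-count threshold, see [count_peaks()].
#' @param baseline Baseline convention, see [diameter_at_half_max()].
#' @return One-row data.frame: `diameter_ha_nm`, `diameter_strep_nm`,
#'   `quotient`, `peaks_ha`, `peaks_strep`, `flag` (`"ok"` or the offending
#'   channel's QC flag).
#' @export
measure_granule <- function(proj, center, ha_channel = "HA",
                            strep_channel = "strep", angle = 0,
                            length_px = 40, width_px = 3,
                            min_prominence_fraction = 0.3,
                            baseline = "decile") {
  prof <- lapply(c(ha_channel, strep_channel), function(ch)
    extract_profile(proj, center, angle, length_px, width_px, ch))
  dia <- lapply(prof, diameter_at_half_max, baseline = baseline)
  pk <- vapply(prof, count_peaks, 0L,
               min_prominence_fraction = min_prominence_fraction)
  flag <- if (dia[[1]]$flag != "ok") paste0(ha_channel, ":", dia[[1]]$flag)
          else if (dia[[2]]$flag != "ok") paste0(strep_channel, ":", dia[[2]]$flag)
          else "ok"
  data.frame(diameter_ha_nm = dia[[1]]$diameter_nm,
             diameter_strep_nm = dia[[2]]$diameter_nm,
             quotient = if (flag == "ok")
               dia[[1]]$diameter_nm / dia[[2]]$diameter_nm else NA_real_,
             peaks_ha = pk[1], peaks_strep = pk[2],
             flag = flag, stringsAsFactors = FALSE)
}

#' Quantify granule diameters across an experiment
#'
#' The end-to-end diameter-quotient analysis: for each stack, sum-project,
#' detect granules on the streptavidin channel, take the largest, draw one
#' line through its centroid, and measure both channels on that identical
#' segment. Returns per-granule measurements plus per-replicate summaries.
#'
#' @param stacks List of `image_stack` objects (e.g.
#'   `simulate_granule_experiment()$stacks`).
#' @param replicate Integer vector assigning each stack to a replicate.
#' @param ha_channel,strep_channel Stain channel labels.
#' @param detect_channel Channel granule detection runs on (default
#'   `strep_channel`). Keeping this fixed while exchanging the stain roles
#'   reuses the identical segment, so the swapped quotients are the exact
#'   reciprocals of the originals (the fluorophore-swap control).
#' @param angle,length_px,width_px,min_prominence_fraction,baseline Passed
#'   to [measure_granule()].
#' @param length_factor When `length_px` is `NULL`, the segment length is
#'   `length_factor * sqrt(area)` of the detected component (default 6),
#'   clamped inside the image.
#' @return An object of class `granule_experiment`: list with
#'   `measurements` (one row per stack) and `replicates`
#'   ([summarise_replicates()] output).
#' @examples
#' \donttest{
#' sim <- simulate_granule_experiment(n_replicates = 2,
#'                                    cells_per_replicate = 3, seed = 3)
#' fit <- granule_quant(sim$stacks, sim$replicate)
#' summary(fit)
#' }
#' @export
granule_quant <- function(stacks, replicate = rep(1L, length(stacks)),
                          ha_channel = "HA", strep_channel = "strep",
                          detect_channel = strep_channel,
                          angle = 0, length_px = NULL, width_px = 3,
                          min_prominence_fraction = 0.3,
                          baseline = "decile", length_factor = 6) {
  stopifnot(length(stacks) == length(replicate), length(stacks) >= 1)
  rows <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    proj <- project(stacks[[i]], "sum")
    det <- detect_granules(proj, detect_channel)
    if (!nrow(det)) {
      rows[[i]] <- data.frame(stack = i, replicate = replicate[i],
                              diameter_ha_nm = NA_real_,
                              diameter_strep_nm = NA_real_,
                              quotient = NA_real_, peaks_ha = NA_integer_,
                              peaks_strep = NA_integer_,
                              flag = "none-detected")
      next
    }
    ctr <- c(det$y[1], det$x[1])
    len <- if (is.null(length_px)) {
      d <- dim(proj$channels[[detect_channel]])
      # longest segment through ctr staying >= 1 px inside the image
      max_len <- 2 * min(ctr[1] - 1, d[1] - ctr[1], ctr[2] - 1, d[2] - ctr[2])
      min(length_factor * sqrt(det$area_px[1]), max_len)
    } else length_px
    m <- measure_granule(proj, ctr, ha_channel, strep_channel, angle,
                         len, width_px, min_prominence_fraction, baseline)
    rows[[i]] <- cbind(data.frame(stack = i, replicate = replicate[i]), m)
  }
  meas <- do.call(rbind, rows)
  structure(list(measurements = meas,
                 replicates = summarise_replicates(meas),
                 channels = c(ha = ha_channel, strep = strep_channel)),
            class = "granule_experiment")
}

#' Summarise granule measurements per replicate
#'
#' Per replicate: number of granules with a defined quotient, mean and
#' sample SD (n - 1 denominator; `NA` for a single granule) of the
#' quotients, and the fraction of profiles with >= 2 peaks per channel.
#' Replicates without any defined quotient are excluded with a warning.
#'
#' @param measurements data.frame with columns `replicate`, `quotient`,
#'   `peaks_ha`, `peaks_strep` (as produced by [granule_quant()]).
#' @return data.frame with one row per retained replicate: `replicate`, `n`,
#'   `mean_quotient`, `sd_quotient`, `frac_double_ha`, `frac_double_strep`.
#' @export
summarise_replicates <- function(measurements) {
  stopifnot(all(c("replicate", "quotient") %in% names(measurements)))
  out <- lapply(split(measurements, measurements$replicate), function(d) {
    q <- d$quotient[!is.na(d$quotient)]
    if (!length(q)) return(NULL)
    data.frame(replicate = d$replicate[1], n = length(q),
               mean_quotient = mean(q),
               sd_quotient = if (length(q) > 1) stats::sd(q) else NA_real_,
               frac_double_ha = mean(d$peaks_ha >= 2, na.rm = TRUE),
               frac_double_strep = mean(d$peaks_strep >= 2, na.rm = TRUE))
  })
  dropped <- names(out)[vapply(out, is.null, TRUE)]
  if (length(dropped))
    warnf("replicate(s) %s excluded: no defined quotient",
          paste(dropped, collapse = ", "))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.granule_experiment <- function(x, ...) {
  m <- x$measurements
  ok <- !is.na(m$quotient)
  cat(sprintf("Granule experiment: %d stacks, %d measured quotients\n",
              nrow(m), sum(ok)))
  if (any(ok))
    cat(sprintf("  pooled quotient (%s/%s): %.2f +/- %.2f (mean +/- SD)\n",
                x$channels["ha"], x$channels["strep"],
                mean(m$quotient[ok]), stats::sd(m$quotient[ok])))
  invisible(x)
}

#' @export
summary.granule_experiment <- function(object, ...) {
  m <- object$measurements
  q <- m$quotient[!is.na(m$quotient)]
  out <- list(replicates = object$replicates,
              pooled_mean = mean(q), pooled_sd = stats::sd(q),
              across_replicate_mean = mean(object$replicates$mean_quotient),
              across_replicate_sd = stats::sd(object$replicates$mean_quotient),
              n = length(q), n_flagged = sum(is.na(m$quotient)))
  class(out) <- "summary.granule_experiment"
  out
}

#' @export
print.summary.granule_experiment <- function(x, ...) {
  cat("Per-replicate summaries:\n")
  print(x$replicates, row.names = FALSE)
  cat(sprintf("Pooled over %d granules: quotient %.2f +/- %.2f (mean +/- SD)\n",
              x$n, x$pooled_mean, x$pooled_sd))
  cat(sprintf("Across replicate means:  %.2f +/- %.2f\n",
              x$across_replicate_mean, x$across_replicate_sd))
  if (x$n_flagged)
    cat(sprintf("%d stack(s) flagged/undetected\n", x$n_flagged))
  invisible(x)
}

#' @export
plot.granule_experiment <- function(x, ...) {
  m <- x$measurements
  graphics::boxplot(quotient ~ replicate, data = m[!is.na(m$quotient), ],
                    xlab = "replicate", ylab = "diameter quotient (HA/strep)",
                    ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
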