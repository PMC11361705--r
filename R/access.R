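#' Reference mask from the streptavidin channel
#'
#' The streptavidin channel defines where the tagged protein actually is
#' (it localizes faithfully even in dense, phase-separated regions), so the
#' reference mask is the set of pixels above an automatic threshold (Otsu by
#' default) in that channel, optionally intersected with a user annulus
#' (e.g. a nuclear-rim ring). The background region is the complement,
#' eroded by 2 px so threshold-edge pixels contaminate neither region.
#'
#' @param proj A [project()] output.
#' @param reference_channel Channel defining the mask (default `"strep"`).
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param annulus Optional logical matrix intersected with the mask.
#' @return List of class `reference_mask`: `mask`, `background` (logical
#'   matrices), `threshold`.
#' @export
reference_mask <- function(proj, reference_channel = "strep",
                           threshold = "otsu", annulus = NULL) {
  stopifnot(inherits(proj, "projection"))
  img <- proj$channels[[reference_channel]]
  if (is.null(img)) stopf("unknown channel '%s'", reference_channel)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0)
      stopf("reference channel is flat; no mask can be formed")
    sc <- (img - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
  } else if (is.numeric(threshold)) threshold
  else stopf("threshold must be \"otsu\" or a number")
  mask <- img > thr
  if (!is.null(annulus)) {
    stopifnot(is.logical(annulus), all(dim(annulus) == dim(img)))
    mask <- mask & annulus
  }
  if (!any(mask)) stopf("reference mask is empty for this cell")
  bg <- !mask
  kern <- EBImage::makeBrush(5, "disc")  # radius-2 erosion
  bg <- as.logical(EBImage::erode(EBImage::Image(bg * 1), kern) > 0.5)
  dim(bg) <- dim(img)
  if (!any(bg)) stopf("background region is empty for this cell")
  structure(list(mask = mask, background = bg, threshold = thr),
            class = "reference_mask")
}

#' Antibody-accessibility score of one cell
#'
#' Quantifies how accessible a tagged protein is to the antibody where the
#' streptavidin reference says the protein resides:
#' `score = max(0, median(HA in mask) - median(HA in background)) /
#'          max(eps, median(strep in mask) - median(strep in background))`.
#' Medians make the score robust to hot pixels and puncta-to-puncta
#' variability; the background subtraction removes diffuse stain; the
#' streptavidin denominator normalizes for labelling density, so the score
#' is invariant under global rescaling of the image. A score near 0 means
#' the protein is antibody-inaccessible (the phase-separated case); a score
#' near 1 means antibody and streptavidin report equally.
#'
#' @param proj A two-channel [project()] output.
#' @param ref A [reference_mask()] (computed from `proj` if `NULL`).
#' @param ha_channel,strep_channel Channel labels.
#' @param eps Denominator guard in detector units (default 1e-6).
#' @return List of class `accessibility_cell`: `score` (NA when flagged),
#'   `ha_signal`, `strep_signal` (background-subtracted medians), `flag`
#'   (`"ok"` or `"no reference signal"`).
#' @export
accessibility_score <- function(proj, ref = NULL, ha_channel = "HA",
                                strep_channel = "strep", eps = 1e-6) {
  stopifnot(inherits(proj, "projection"))
  if (is.null(ref)) ref <- reference_mask(proj, strep_channel)
  ha <- proj$channels[[ha_channel]]
  st <- proj$channels[[strep_channel]]
  if (is.null(ha) || is.null(st)) stopf("missing channel in projection")
  ha_sig <- stats::median(ha[ref$mask]) - stats::median(ha[ref$background])
  st_sig <- stats::median(st[ref$mask]) - stats::median(st[ref$background])
  if (st_sig < eps)
    return(structure(list(score = NA_real_, ha_signal = ha_sig,
                          strep_signal = st_sig,
                          flag = "no reference signal"),
                     class = "accessibility_cell"))
  structure(list(score = max(0, ha_sig) / st_sig, ha_signal = ha_sig,
                 strep_signal = st_sig, flag = "ok"),
            class = "accessibility_cell")
}

#' Aggregate accessibility over cells for one tagged terminus
#'
#' Scores each cell with [accessibility_score()] and aggregates by the
#' median across cells. Fewer than `n_min` unflagged cells flags the
#' aggregate rather than reporting an unstable score.
#'
#' @param projections List of per-cell [project()] outputs.
#' @param protein Protein name.
#' @param terminus `"N"` or `"C"` (which terminus carries the tag).
#' @param n_min Minimum unflagged cells required (default 10).
#' @param ... Passed to [accessibility_score()].
#' @return One-row data.frame: `protein`, `terminus`, `score` (median across
#'   cells), `n_cells`, `flag`.
#' @export
accessibility_aggregate <- function(projections, protein,
                                    terminus = c("N", "C"), n_min = 10, ...) {
  terminus <- match.arg(terminus)
  cells <- lapply(projections, function(p) accessibility_score(p, ...))
  sc <- vapply(cells, function(c) c$score, 0)
  ok <- !is.na(sc)
  flag <- if (sum(ok) < n_min)
    sprintf("only %d scored cell(s), need %d", sum(ok), n_min) else "ok"
  data.frame(protein = protein, terminus = terminus,
             score = if (any(ok)) stats::median(sc[ok]) else NA_real_,
             n_cells = sum(ok), flag = flag, stringsAsFactors = FALSE)
}

#' Bin accessibility scores into increment classes
#'
#' Assembles the accessibility map table: one row per (protein, terminus),
#' the score binned into half-open intervals `[edge_i, edge_{i+1})` —
#' class 0 is the least accessible bin. Scores exactly on an edge go to the
#' upper interval; flagged rows get class `NA` (`"undetermined"`).
#'
#' @param scores data.frame as produced by rbind-ing
#'   [accessibility_aggregate()] rows.
#' @param class_edges Strictly increasing numeric edges, starting at 0.
#' @return An object of class `access_map`: the input with added
#'   `increment` (integer, 0-based) and `increment_label` columns.
#' @export
bin_accessibility <- function(scores, class_edges = c(0, 0.1, 0.5, 1.0)) {
  stopifnot(is.data.frame(scores),
            all(c("protein", "terminus", "score") %in% names(scores)))
  if (any(diff(class_edges) <= 0)) stopf("class_edges must be strictly increasing")
  if (class_edges[1] != 0) stopf("lowest edge must be 0")
  if (anyDuplicated(scores[c("protein", "terminus")]))
    stopf("at most one row per (protein, terminus)")
  cls <- findInterval(scores$score, class_edges) - 1L  # 0-based
  labs <- c(paste0("[", class_edges[-length(class_edges)], ",",
                   class_edges[-1], ")"),
            paste0(">=", class_edges[length(class_edges)]))
  scores$increment <- cls
  scores$increment_label <- ifelse(is.na(cls), "undetermined", labs[cls + 1L])
  attr(scores, "class_edges") <- class_edges
  class(scores) <- c("access_map", "data.frame")
  scores
}

#' @export
print.access_map <- function(x, ...) {
  cat(sprintf("Accessibility map: %d (protein, terminus) entries, edges %s\n",
              nrow(x), paste(attr(x, "class_edges"), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
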