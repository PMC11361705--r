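#' Z-projection of an image stack
#'
#' Reduces each channel over z, either by summing slices (the projection the
#' diameter analysis uses; preserves total intensity per channel) or by the
#' per-pixel maximum.
#'
#' @param stack An `image_stack` from [render_scene()] or [read_stack()].
#' @param method `"sum"` or `"max"`.
#' @return An object of class `projection`: list with `channels` (named list
#'   of 2D matrices, dim = (y, x)), `method`, `calibration` and the source
#'   stack's seed as provenance.
#' @export
project <- function(stack, method = c("sum", "max")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  red <- function(a) {
    if (method == "sum") colSums(a)  # over z (first margin) -> (y, x)
    else apply(a, c(2, 3), max)
  }
  structure(list(channels = lapply(stack$channels, red),
                 method = method,
                 calibration = stack$calibration,
                 source_seed = stack$seed),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("%s projection: %d channel(s) [%s], %d x %d px (%g nm/px)\n",
              x$method, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$calibration$pixel_size_xy))
  invisible(x)
}
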