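#' Maximum-signal fold change between two staining conditions
#'
#' For each cell, takes the maximum intensity of its (sum-)projection within
#' the cell mask; then compares the two groups of per-cell maxima: fold
#' change as the ratio of group means (A / B) and an unpaired two-tailed
#' t-test (Student's equal-variance by default, Welch via
#' `var_equal = FALSE`). This is the statistic used to compare streptavidin
#' versus antibody detection brightness.
#'
#' @param projections_a,projections_b Lists of [project()] outputs (or bare
#'   numeric matrices), one per cell, for conditions A and B.
#' @param masks_a,masks_b Optional lists of logical matrices (same sizes);
#'   `NULL` uses the whole image as the mask. Cells with an empty mask are
#'   excluded with a warning.
#' @param channel Channel to read from `projection` inputs.
#' @param var_equal Equal-variance Student's t-test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @return An object of class `signal_stats`: list with `max_a`, `max_b`
#'   (per-cell maxima), `n`, `fold_change`, `t`, `df`, `p_value`,
#'   `var_equal`.
#' @export
max_signal_stats <- function(projections_a, projections_b,
                             masks_a = NULL, masks_b = NULL,
                             channel = NULL, var_equal = TRUE) {
  get_max <- function(projs, masks, side) {
    vals <- numeric(0)
    for (i in seq_along(projs)) {
      img <- projs[[i]]
      if (inherits(img, "projection")) {
        ch <- if (is.null(channel)) names(img$channels)[1] else channel
        img <- img$channels[[ch]]
        if (is.null(img)) stopf("unknown channel '%s'", channel)
      }
      msk <- if (is.null(masks)) TRUE else masks[[i]]
      v <- img[msk]
      if (!length(v)) {
        warnf("cell %d of group %s has an empty mask; excluded", i, side)
        next
      }
      vals <- c(vals, max(v))
    }
    vals
  }
  ma <- get_max(projections_a, masks_a, "A")
  mb <- get_max(projections_b, masks_b, "B")
  if (length(ma) < 2 || length(mb) < 2)
    stopf("need >= 2 cells per group (got %d vs %d)", length(ma), length(mb))
  tt <- stats::t.test(ma, mb, var.equal = var_equal)
  structure(list(max_a = ma, max_b = mb, n = c(A = length(ma), B = length(mb)),
                 fold_change = mean(ma) / mean(mb),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, var_equal = var_equal),
            class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("Maximum-signal comparison (n = %d vs %d cells)\n",
              x$n["A"], x$n["B"]))
  cat(sprintf("  fold change (A/B): %.2f\n", x$fold_change))
  cat(sprintf("  %s t-test: t = %.2f, df = %.1f, two-tailed p = %.3g\n",
              if (x$var_equal) "Student's" else "Welch", x$t, x$df,
              x$p_value))
  invisible(x)
}
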