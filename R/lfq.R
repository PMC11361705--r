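#' LFQ intensity table with a sample-to-group map
#'
#' Container for a protein-groups x samples label-free quantification
#' matrix. Intensities are raw-scale (arbitrary units, >= 0) or `NA` for
#' missing; each sample belongs to a group (bait groups of 2-3 replicates
#' and one `control` group in the designs this package targets).
#'
#' @param intensities Numeric matrix, rows = protein groups (rownames = IDs),
#'   columns = samples (colnames = sample names).
#' @param groups Named character vector mapping sample name -> group label.
#' @return An object of class `lfq_table`.
#' @export
lfq_table <- function(intensities, groups) {
  stopifnot(is.matrix(intensities), !is.null(colnames(intensities)))
  if (nrow(intensities) > 0 && is.null(rownames(intensities)))
    stopf("intensities must have protein-group IDs as rownames")
  if (anyDuplicated(colnames(intensities))) stopf("sample names must be unique")
  if (is.null(names(groups))) stopf("groups must be named by sample")
  missing_map <- setdiff(colnames(intensities), names(groups))
  if (length(missing_map))
    stopf("no group assigned for sample(s): %s",
          paste(missing_map, collapse = ", "))
  if (any(intensities < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  structure(list(intensities = intensities,
                 groups = groups[colnames(intensities)]),
            class = "lfq_table")
}

#' @export
print.lfq_table <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("LFQ table: %d protein groups x %d samples (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  missing cells: %.1f%%\n",
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

group_cols <- function(tab, group) {
  cols <- which(tab$groups == group)
  if (!length(cols)) stopf("group '%s' not present in table", group)
  cols
}

#' Filter for valid values in the bait group
#'
#' Keeps protein groups with at least `min_valid` non-missing intensities in
#' the bait sample group, mirroring the standard pre-filter of
#' proximity-labelling LFQ workflows. Removed IDs are reported via a
#' `removed` attribute and a message.
#'
#' @param tab An [lfq_table()].
#' @param bait_group Group label of the bait samples.
#' @param min_valid Minimum valid values required (default 1).
#' @return The filtered `lfq_table`, with attribute `removed` (character IDs).
#' @export
filter_valid <- function(tab, bait_group, min_valid = 1) {
  stopifnot(inherits(tab, "lfq_table"))
  cols <- group_cols(tab, bait_group)
  if (min_valid > length(cols))
    warnf("min_valid (%d) exceeds bait group size (%d); all rows removed",
          min_valid, length(cols))
  nv <- rowSums(!is.na(tab$intensities[, cols, drop = FALSE]))
  keep <- nv >= min_valid
  removed <- rownames(tab$intensities)[!keep]
  if (length(removed))
    message(sprintf("filter_valid: removed %d/%d protein groups (< %d valid value(s) in '%s')",
                    length(removed), length(keep), min_valid, bait_group))
  out <- lfq_table(tab$intensities[keep, , drop = FALSE], tab$groups)
  attr(out, "removed") <- removed
  out
}

#' Log2-transform an LFQ table
#'
#' Elementwise log2 of the raw intensities; missing cells stay missing.
#' Zero or negative intensities are rejected with the offending row and
#' sample named.
#'
#' @param tab An [lfq_table()].
#' @return The transformed `lfq_table` (attribute `log2 = TRUE`).
#' @export
log2_transform <- function(tab) {
  stopifnot(inherits(tab, "lfq_table"))
  bad <- which(tab$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-positive intensity at protein '%s', sample '%s'",
          rownames(tab$intensities)[bad[1, 1]],
          colnames(tab$intensities)[bad[1, 2]])
  out <- tab
  out$intensities <- log2(tab$intensities)
  attr(out, "log2") <- TRUE
  out
}

#' Imputation parameters for missing LFQ values
#'
#' Missing values are drawn from a normal distribution centred below each
#' sample's observed intensities — emulating values around the detection
#' limit of the mass spectrometer. Per sample column with observed mean
#' `mu` and SD `sigma`, missing cells are drawn from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)`.
#'
#' @param width Imputation SD as a fraction of the per-sample SD
#'   (default 0.3).
#' @param downshift Downshift in multiples of the per-sample SD
#'   (default 1.8).
#' @param seed Integer seed.
#' @return An object of class `impute_params`.
#' @export
impute_params <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  if (!is_pos_scalar(width)) stopf("width must be > 0")
  stopifnot(downshift >= 0)
  structure(list(width = width, downshift = downshift,
                 seed = as.integer(seed)),
            class = "impute_params")
}

#' Impute missing values from a downshifted normal distribution
#'
#' Column-wise imputation on the log2 scale: each sample's missing cells are
#' drawn from `Normal(mu - downshift * sigma, (width * sigma)^2)` where `mu`
#' and `sigma` are that column's observed mean and SD. Each column's draw
#' stream is seeded from the master seed and the sample name, so the result
#' does not depend on column order. A table without missing cells is
#' returned unchanged.
#'
#' @param tab A log2-transformed [lfq_table()].
#' @param params An [impute_params()].
#' @return The imputed `lfq_table` (no `NA` cells remain).
#' @export
impute <- function(tab, params = impute_params()) {
  stopifnot(inherits(tab, "lfq_table"), inherits(params, "impute_params"))
  x <- tab$intensities
  if (!anyNA(x)) return(tab)
  for (j in seq_len(ncol(x))) {
    obs <- x[!is.na(x[, j]), j]
    miss <- which(is.na(x[, j]))
    if (!length(miss)) next
    if (length(obs) < 3)
      stopf("sample '%s' has %d observed value(s); need >= 3 to estimate its distribution",
            colnames(x)[j], length(obs))
    mu <- mean(obs); sigma <- stats::sd(obs)
    col_seed <- (params$seed + string_seed(colnames(x)[j])) %% 2147483647L
    x[miss, j] <- with_seed(col_seed,
      stats::rnorm(length(miss), mu - params$downshift * sigma,
                   params$width * sigma))
  }
  out <- tab
  out$intensities <- x
  out
}

# Vectorized equal-variance two-sample t-test over rows of two matrices.
# Returns difference of means (a - b), t, df, and two-tailed p. Rows with
# zero pooled variance: p = 1 when the difference is also 0, else NA with a
# degenerate flag.
row_ttest <- function(a, b) {
  na_ <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  df <- na_ + nb - 2
  sp2 <- ((na_ - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na_ + 1 / nb))
  diff <- ma - mb
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- NA_real_
  data.frame(difference = diff, t = t, df = df, p_value = p,
             degenerate = degen)
}

#' Student's t-test of a bait group against the untagged control
#'
#' Per protein group, an equal-variance two-sample t-test of the bait
#' columns against the control columns on the (imputed) log2 scale. The
#' t-test difference — the difference between the means of the logarithmic
#' abundances, bait minus control — is the enrichment effect size that is
#' later binned into increments. A Benjamini-Hochberg adjusted p-value
#' column is included for convenience; the increments themselves are binned
#' on the raw differences.
#'
#' @param tab A complete (imputed) log2 [lfq_table()].
#' @param bait_group Bait group label.
#' @param control_group Control group label (default `"control"`).
#' @return A data.frame of class `enrichment_results` with columns `id`,
#'   `t_test_difference`, `t`, `p_value`, `p_adjust`, `degenerate`.
#' @export
ttest_vs_control <- function(tab, bait_group, control_group = "control") {
  stopifnot(inherits(tab, "lfq_table"))
  if (anyNA(tab$intensities))
    stopf("table still contains missing values; impute first")
  ca <- group_cols(tab, bait_group)
  cb <- group_cols(tab, control_group)
  if (length(ca) < 2 || length(cb) < 2)
    stopf("both groups need >= 2 samples for a t-test (got %d vs %d)",
          length(ca), length(cb))
  tt <- row_ttest(tab$intensities[, ca, drop = FALSE],
                  tab$intensities[, cb, drop = FALSE])
  if (any(tt$degenerate & is.na(tt$p_value)))
    warnf("%d protein group(s) with zero pooled variance and nonzero difference flagged degenerate",
          sum(tt$degenerate & is.na(tt$p_value)))
  res <- data.frame(id = rownames(tab$intensities),
                    t_test_difference = tt$difference,
                    t = tt$t, p_value = tt$p_value,
                    p_adjust = stats::p.adjust(tt$p_value, "BH"),
                    degenerate = tt$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("enrichment_results", "data.frame")
  attr(res, "bait_group") <- bait_group
  attr(res, "control_group") <- control_group
  res
}

#' Bin t-test differences into enrichment increments
#'
#' Maps each t-test difference onto half-open increment intervals
#' `[edge_i, edge_{i+1})`, the computable version of the shades-of-green
#' scheme used to colour nuclear-pore maps. Differences below the lowest
#' edge get class 0, labelled `"not enriched"`; a difference exactly on an
#' edge falls in the upper interval.
#'
#' @param results An `enrichment_results` data.frame.
#' @param edges Strictly increasing numeric vector of increment edges.
#' @return `results` with added integer `increment` and factor
#'   `increment_label` columns.
#' @export
bin_increments <- function(results, edges = c(1, 2, 4, 6)) {
  stopifnot(inherits(results, "data.frame"))
  if (any(diff(edges) <= 0)) stopf("edges must be strictly increasing")
  cls <- findInterval(results$t_test_difference, edges)  # 0 below lowest edge
  labs <- c("not enriched",
            paste0("[", edges[-length(edges)], ",", edges[-1], ")"),
            paste0(">=", edges[length(edges)]))
  results$increment <- cls
  results$increment_label <- factor(labs[cls + 1L], levels = labs)
  attr(results, "edges") <- edges
  results
}

#' Map enrichment results onto a named component list
#'
#' Joins results to a parts list (e.g. the nuclear pore complex components
#' and transport factors) by protein-group ID or synonym. Components absent
#' from the results are reported `"undetected"` (grey in the usual colour
#' scheme); result rows matching no component are `"unassigned"`.
#'
#' @param results An `enrichment_results` data.frame (binned or not).
#' @param components data.frame with columns `id`, `name`, `substructure`,
#'   and optional `synonyms` (`;`-separated). Default: the bundled synthetic
#'   trypanosome NPC parts list (see
#'   `system.file("extdata", "npc_components_synthetic.tsv",
#'   package = "proxiquant")`).
#' @return A data.frame keyed by component: `name`, `substructure`, `id`,
#'   `t_test_difference`, `p_value`, `increment` (if present), `status`
#'   (`"quantified"`/`"undetected"`); unmatched results appended with
#'   `status = "unassigned"`.
#' @export
map_components <- function(results, components = npc_components()) {
  stopifnot(inherits(results, "data.frame"),
            all(c("id", "name") %in% names(components)))
  syn <- strsplit(ifelse(is.na(components$synonyms), "",
                         components$synonyms), ";", fixed = TRUE)
  keys <- mapply(function(id, s) unique(c(id, trimws(s))),
                 components$id, syn, SIMPLIFY = FALSE)
  match_row <- vapply(keys, function(k) {
    hit <- match(k[nzchar(k)], results$id)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }, 0L)
  inc <- "increment" %in% names(results)
  comp <- data.frame(
    name = components$name,
    substructure = if ("substructure" %in% names(components))
      components$substructure else NA_character_,
    id = components$id,
    t_test_difference = results$t_test_difference[match_row],
    p_value = results$p_value[match_row],
    status = ifelse(is.na(match_row), "undetected", "quantified"),
    stringsAsFactors = FALSE)
  if (inc) comp$increment <- results$increment[match_row]
  extra <- setdiff(seq_len(nrow(results)),
                   match_row[!is.na(match_row)])
  if (length(extra)) {
    un <- data.frame(name = results$id[extra], substructure = NA_character_,
                     id = results$id[extra],
                     t_test_difference = results$t_test_difference[extra],
                     p_value = results$p_value[extra],
                     status = "unassigned", stringsAsFactors = FALSE)
    if (inc) un$increment <- results$increment[extra]
    comp <- rbind(comp, un)
  }
  comp
}

#' Bundled synthetic NPC parts list
#'
#' Loads the package's parts list of trypanosome nuclear pore components and
#' transport factors. Gene IDs are included where published; components
#' known only by protein name are keyed by that name (the list is a
#' synthetic stand-in for a full annotated parts table, hence its filename).
#'
#' @return data.frame with columns `id`, `name`, `substructure`, `synonyms`.
#' @export
npc_components <- function() {
  path <- system.file("extdata", "npc_components_synthetic.tsv",
                      package = "proxiquant")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Run the full LFQ enrichment pipeline
#'
#' Convenience wrapper chaining [filter_valid()], [log2_transform()],
#' [impute()], [ttest_vs_control()], [bin_increments()] and
#' [map_components()] with the workflow's standard defaults.
#'
#' @param tab A raw-scale [lfq_table()].
#' @param bait_group Bait group label.
#' @param control_group Control group label.
#' @param min_valid Valid-value filter threshold (default 1).
#' @param impute_width,impute_downshift Imputation parameters.
#' @param edges Increment edges for [bin_increments()].
#' @param components Parts list for [map_components()], or `NULL` to skip.
#' @param seed Seed for the imputation draws.
#' @return An object of class `lfq_enrichment`: list with `results`
#'   (binned `enrichment_results`), `component_map` (or `NULL`), and the
#'   parameters used.
#' @examples
#' sim <- simulate_lfq_table(lfq_sim_spec(n_proteins = 50, seed = 7))
#' fit <- lfq_enrich(sim$table, "bait", components = NULL, seed = 7)
#' head(fit$results)
#' @export
lfq_enrich <- function(tab, bait_group, control_group = "control",
                       min_valid = 1, impute_width = 0.3,
                       impute_downshift = 1.8, edges = c(1, 2, 4, 6),
                       components = npc_components(), seed = 1L) {
  tab <- filter_valid(tab, bait_group, min_valid)
  tab <- log2_transform(tab)
  tab <- impute(tab, impute_params(impute_width, impute_downshift, seed))
  res <- ttest_vs_control(tab, bait_group, control_group)
  res <- bin_increments(res, edges)
  cmap <- if (!is.null(components)) map_components(res, components) else NULL
  structure(list(results = res, component_map = cmap,
                 bait_group = bait_group, control_group = control_group,
                 edges = edges,
                 impute = impute_params(impute_width, impute_downshift, seed)),
            class = "lfq_enrichment")
}

#' @export
print.lfq_enrichment <- function(x, ...) {
  r <- x$results
  cat(sprintf("LFQ enrichment: %s vs %s, %d protein groups\n",
              x$bait_group, x$control_group, nrow(r)))
  cat(sprintf("  enriched (difference >= %g): %d; increment edges: %s\n",
              x$edges[1], sum(r$increment > 0),
              paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' @export
summary.lfq_enrichment <- function(object, ...) {
  r <- object$results
  out <- list(n = nrow(r),
              increments = table(r$increment_label),
              top = utils::head(r[order(-r$t_test_difference),
                                  c("id", "t_test_difference", "p_value",
                                    "increment")], 10))
  class(out) <- "summary.lfq_enrichment"
  out
}

#' @export
print.summary.lfq_enrichment <- function(x, ...) {
  cat(sprintf("%d protein groups\nIncrement counts:\n", x$n))
  print(x$increments)
  cat("Top enrichments:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Volcano plot of an LFQ enrichment
#'
#' @param x An `lfq_enrichment` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lfq_enrichment <- function(x, ...) {
  r <- x$results
  graphics::plot(r$t_test_difference, -log10(r$p_value),
                 xlab = "t-test difference (log2)",
                 ylab = expression(-log[10] ~ p),
                 pch = 16, cex = 0.6,
                 col = ifelse(r$increment > 0, "darkgreen", "grey60"), ...)
  graphics::abline(v = x$edges, lty = 3, col = "grey40")
  invisible(x)
}
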