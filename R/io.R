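#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' One TIFF per channel (pages = z-slices) named `<prefix>_<channel>.tif`,
#' plus `<prefix>.json` carrying the calibration, channel labels, seed,
#' per-channel intensity scale and the ground truth. TIFF storage is 32-bit
#' in [0, 1]; intensities are divided by a per-channel max recorded in the
#' sidecar and restored exactly on read (to 32-bit quantization).
#'
#' @param stack An `image_stack`.
#' @param prefix Output path prefix (directory must exist).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  scales <- lapply(stack$channels, function(a) max(a, 1e-12))
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]] / scales[[ch]]
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 32L)
  }
  side <- list(channels = names(stack$channels),
               calibration = stack$calibration,
               seed = stack$seed,
               scale = scales,
               ground_truth = stack$ground_truth)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `image_stack`.
#' @export
read_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  chans <- list()
  for (ch in side$channels) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    a <- array(0, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    chans[[ch]] <- a * side$scale[[ch]]
  }
  gt <- side$ground_truth
  if (!is.null(gt$granules)) gt$granules <- as.data.frame(gt$granules)
  if (!is.null(gt$pores)) gt$pores <- as.matrix(as.data.frame(gt$pores))
  structure(list(channels = chans,
                 calibration = as.list(side$calibration),
                 ground_truth = gt,
                 seed = side$seed),
            class = "image_stack")
}

#' Read an LFQ intensity TSV with a sample-to-group map
#'
#' The TSV's first column holds protein-group IDs; remaining columns are
#' sample intensities, empty cells meaning missing. MaxQuant-style
#' `LFQ intensity <sample>` headers are accepted and normalized to the bare
#' sample name. The group map is a YAML file (or named list) of
#' `sample: group` pairs.
#'
#' @param path TSV file path.
#' @param group_map YAML path or named list/vector mapping sample -> group.
#' @return An [lfq_table()].
#' @export
read_lfq_tsv <- function(path, group_map) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  colnames(mat) <- sub("^LFQ intensity ", "", colnames(mat))
  rownames(mat) <- ids
  if (is.character(group_map) && length(group_map) == 1 &&
      file.exists(group_map))
    group_map <- yaml::read_yaml(group_map)
  groups <- unlist(group_map)
  lfq_table(mat, groups)
}

#' Write an LFQ table to TSV
#'
#' Inverse of [read_lfq_tsv()]: first column `protein_group`, one column per
#' sample, missing cells empty.
#'
#' @param tab An [lfq_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lfq_tsv <- function(tab, path) {
  stopifnot(inherits(tab, "lfq_table"))
  df <- data.frame(protein_group = rownames(tab$intensities),
                   tab$intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write enrichment results to TSV
#'
#' @param results An `enrichment_results` data.frame (binned or not) or the
#'   `results` element of an `lfq_enrichment`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(results, path) {
  if (inherits(results, "lfq_enrichment")) results <- results$results
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
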