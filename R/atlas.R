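#' Region atlas table
#'
#' A `region_atlas` is a data frame with one row per parcellated brain
#' region and columns `id` (contiguous integer index starting at 1),
#' `label` (unique region name), `hemisphere` (`"left"` or `"right"`),
#' `x`, `y`, `z` (centroid coordinates in mm, arbitrary frame) and
#' `volume` (positive integer voxel count). The voxel count is the `n`
#' used by [volume_normalize()]; typical use is a 90-region whole-brain
#' parcellation with alternating left/right homologues.
#'
#' @param df data frame with columns `id`, `label`, `hemisphere`,
#'   `x`, `y`, `z`, `volume`. Ids may start at 0 or 1; they are shifted
#'   to start at 1 and must be contiguous.
#' @return A validated `region_atlas` data frame.
#' @export
region_atlas <- function(df) {
  req <- c("id", "label", "hemisphere", "x", "y", "z", "volume")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stopf("atlas is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$id <- as.integer(df$id)
  if (min(df$id) == 0L) df$id <- df$id + 1L  # 0-based files are shifted
  df <- df[order(df$id), , drop = FALSE]
  if (!identical(df$id, seq_len(nrow(df))))
    stopf("atlas ids must be contiguous from 0 or 1")
  if (anyDuplicated(df$label))
    stopf("atlas labels must be unique")
  if (!all(df$hemisphere %in% c("left", "right")))
    stopf("hemisphere must be 'left' or 'right'")
  df$volume <- as.integer(df$volume)
  if (any(is.na(df$volume)) || any(df$volume < 1L))
    stopf("atlas volumes must be positive integers")
  rownames(df) <- NULL
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' Read a region atlas from a TSV file
#'
#' Expects a header line with columns `id`, `label`, `hemisphere`,
#' `x`, `y`, `z`, `volume`.
#'
#' @param path path to the atlas TSV.
#' @return A [region_atlas()].
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  region_atlas(df)
}

#' Write a region atlas to TSV
#'
#' @param atlas a [region_atlas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Synthetic region atlas
#'
#' Builds a plausible atlas for simulation studies: `n` regions named
#' `R001`..`Rnnn`, alternating right/left hemisphere assignment (as in
#' interleaved whole-brain parcellations), centroids on a jittered grid
#' and voxel volumes drawn uniformly between `vol_range[1]` and
#' `vol_range[2]`.
#'
#' @param n_regions number of regions (default 90).
#' @param vol_range integer range of region volumes in voxels.
#' @param seed optional seed for reproducible centroids/volumes.
#' @return A [region_atlas()].
#' @export
synthetic_atlas <- function(n_regions = 90, vol_range = c(500L, 5000L),
                            seed = NULL) {
  if (n_regions < 1) stopf("n_regions must be >= 1")
  with_seed(seed, {
    region_atlas(data.frame(
      id = seq_len(n_regions),
      label = sprintf("R%03d", seq_len(n_regions)),
      hemisphere = rep_len(c("right", "left"), n_regions),
      x = stats::runif(n_regions, -70, 70),
      y = stats::runif(n_regions, -100, 70),
      z = stats::runif(n_regions, -45, 75),
      volume = sample(vol_range[1]:vol_range[2], n_regions, replace = TRUE),
      stringsAsFactors = FALSE
    ))
  })
}
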