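#' Connectome matrix object
#'
#' A `connectome` couples one subject's symmetric nonnegative weighted
#' adjacency matrix with the region atlas it is defined over. The
#' diagonal is always zero and the matrix dimension equals the number of
#' atlas regions.
#'
#' @param weights N x N numeric matrix, symmetric, nonnegative, zero
#'   diagonal.
#' @param atlas a [region_atlas()] with N regions.
#' @param subject_id subject identifier string.
#' @return A `connectome` object (list with `subject_id`, `weights`,
#'   `atlas`).
#' @export
connectome <- function(weights, atlas, subject_id = "subject") {
  check_square_numeric(weights, "connectome weights")
  n <- nrow(weights)
  if (n != nrow(atlas))
    stopf("matrix dimension (%d) does not match atlas size (%d)",
          n, nrow(atlas))
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    stopf("weights are asymmetric beyond tolerance (max |w_ij - w_ji| = %g)",
          asym)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(atlas$label, atlas$label)
  structure(list(subject_id = subject_id, weights = weights, atlas = atlas),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  n <- nrow(x$weights)
  cat(sprintf("<connectome> subject '%s': %d regions, %d edges (density %.3f)\n",
              x$subject_id, n, e, e / (n * (n - 1) / 2)))
  invisible(x)
}

#' Read a subject connectome from a delimited adjacency file
#'
#' Reads a headerless square numeric matrix. Tab- and comma-separated
#' files are both accepted; the delimiter is sniffed from the first
#' line. Asymmetries within `1e-9` are symmetrised by averaging; larger
#' asymmetry is treated as a corrupt file and raises an error.
#'
#' @param path adjacency file path (TSV or CSV).
#' @param atlas a [region_atlas()]; the matrix must match its size.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return A [connectome()].
#' @export
read_connectome <- function(path, atlas,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "numeric")
  W <- as.matrix(df)
  dimnames(W) <- NULL
  if (nrow(W) != ncol(W))
    stopf("adjacency file '%s' is not square (%d x %d)", path,
          nrow(W), ncol(W))
  check_square_numeric(W, sprintf("adjacency file '%s'", path))
  asym <- max(abs(W - t(W)))
  if (asym > 1e-9)
    stopf("adjacency file '%s' is asymmetric beyond tolerance (max %g)",
          path, asym)
  connectome(W, atlas, subject_id)
}

#' Write a connectome's adjacency matrix to a headerless TSV
#'
#' @param C a [connectome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(C, path) {
  utils::write.table(C$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Symmetrise a directed connectivity-probability matrix
#'
#' Tractography seeded from region i gives a probability to region j
#' that generally differs from the j-to-i probability; the undirected
#' connectivity is taken as their average. The diagonal is zeroed.
#'
#' @param P square nonnegative numeric matrix of directed connection
#'   probabilities.
#' @return Symmetric matrix `(P + t(P)) / 2` with zero diagonal.
#' @export
symmetrize_directed <- function(P) {
  check_square_numeric(P, "probability matrix")
  out <- (P + t(P)) / 2
  diag(out) <- 0
  out
}

#' Normalise directed connectivity by seed-region volume
#'
#' Row i of the matrix (connections seeded in region i) is divided by
#' region i's voxel count, removing the dependence of streamline counts
#' on parcel size. Applied to the directed matrix before
#' [symmetrize_directed()] in the standard pipeline, though the two
#' steps are exposed separately.
#'
#' @param P square nonnegative numeric matrix (directed).
#' @param atlas a [region_atlas()] supplying per-region volumes.
#' @return Matrix with row i divided by `atlas$volume[i]`.
#' @export
volume_normalize <- function(P, atlas) {
  check_square_numeric(P, "probability matrix")
  if (nrow(P) != nrow(atlas))
    stopf("matrix dimension does not match atlas size")
  vol <- as.numeric(atlas$volume)
  if (any(vol <= 0)) stopf("atlas volumes must be positive")
  P / vol  # recycles down columns = divides row i by vol[i]
}

#' Remove the weakest fraction of links
#'
#' Controls for spurious connections from probabilistic tractography by
#' removing the bottom-ranked links by connection strength: among the E
#' nonzero undirected edges, the `floor(fraction * E)` weakest are set
#' to zero. Ties at the removal boundary are broken by lexicographic
#' (i, j) order so the operation is deterministic.
#'
#' @param C a [connectome()].
#' @param fraction fraction of existing links to remove, in [0, 1);
#'   default 0.01 (the bottom 1 percent).
#' @return A thresholded [connectome()].
#' @export
threshold_bottom_rank <- function(C, fraction = 0.01) {
  if (fraction < 0 || fraction >= 1)
    stopf("fraction must be in [0, 1)")
  W <- C$weights
  ed <- upper_edges(W)
  n_remove <- floor(fraction * nrow(ed))
  if (n_remove > 0) {
    ord <- order(ed$w, ed$i, ed$j)
    drop <- ed[ord[seq_len(n_remove)], , drop = FALSE]
    W[cbind(drop$i, drop$j)] <- 0
    W[cbind(drop$j, drop$i)] <- 0
  }
  connectome(W, C$atlas, C$subject_id)
}

#' Rescale a connectome by its maximum connectivity value
#'
#' Divides every weight by the matrix maximum so that the strongest
#' connection has weight 1, putting subjects on a common scale before
#' graph analysis.
#'
#' @param C a [connectome()].
#' @return A rescaled [connectome()] whose maximum weight is 1.
#' @export
rescale_by_max <- function(C) {
  mx <- max(C$weights)
  if (mx <= 0) stopf("cannot rescale an all-zero connectome")
  connectome(C$weights / mx, C$atlas, C$subject_id)
}

#' Cohort of connectomes with covariates
#'
#' A `cohort` is a labelled group of subjects: a list of [connectome()]
#' objects sharing one atlas plus a covariates data frame keyed by
#' `subject_id` with at least `age` (years) and `gender` (`"M"`/`"F"`),
#' and any number of numeric score columns.
#'
#' @param group_label group name (e.g. `"HC"`, `"patient"`).
#' @param subjects list of [connectome()] objects.
#' @param covariates data frame with a `subject_id` column covering
#'   every subject.
#' @return A `cohort` object.
#' @export
cohort <- function(group_label, subjects, covariates) {
  if (length(subjects) < 1) stopf("cohort '%s' has no subjects", group_label)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject ids in cohort")
  if (!"subject_id" %in% names(covariates))
    stopf("covariates need a subject_id column")
  miss <- setdiff(ids, covariates$subject_id)
  if (length(miss) > 0)
    stopf("covariates missing for subject(s): %s", paste(miss, collapse = ", "))
  covariates <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  rownames(covariates) <- NULL
  structure(list(group_label = group_label, subjects = subjects,
                 covariates = covariates),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> '%s': %d subjects, %d regions\n", x$group_label,
              length(x$subjects), nrow(x$subjects[[1]]$weights)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a [cohort()].
#' @param ... unused.
#' @export
length.cohort <- function(x) length(x$subjects)

#' Group-average connectome
#'
#' Element-wise mean of the member matrices, used e.g. as the substrate
#' for group-level community detection.
#'
#' @param ch a [cohort()].
#' @return A [connectome()] with subject id `"<group_label>-mean"`.
#' @export
group_average <- function(ch) {
  if (length(ch$subjects) < 1) stopf("empty cohort")
  W <- Reduce(`+`, lapply(ch$subjects, `[[`, "weights")) / length(ch$subjects)
  connectome(W, ch$subjects[[1]]$atlas,
             paste0(ch$group_label, "-mean"))
}

#' Apply the standard preprocessing chain to every subject in a cohort
#'
#' Bottom-rank thresholding followed (optionally) by max-rescaling,
#' subject by subject.
#'
#' @param ch a [cohort()].
#' @param fraction link fraction for [threshold_bottom_rank()].
#' @param rescale logical; apply [rescale_by_max()] after thresholding.
#' @return The preprocessed [cohort()].
#' @export
preprocess_cohort <- function(ch, fraction = 0.01, rescale = TRUE) {
  subs <- lapply(ch$subjects, function(s) {
    s <- threshold_bottom_rank(s, fraction)
    if (rescale) s <- rescale_by_max(s)
    s
  })
  cohort(ch$group_label, subs, ch$covariates)
}

#' Read a covariates table
#'
#' TSV with header `subject_id, group, age, gender, <scores...>`.
#'
#' @param path covariates TSV path.
#' @return A data frame.
#' @export
read_covariates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
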