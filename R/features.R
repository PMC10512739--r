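#' Per-subject trial features with binary labels
#'
#' @param X Numeric matrix, trials x voxels.
#' @param y Trial labels; coerced to +1/-1 (must already be in
#'   `c(1, -1)` or a two-level factor/character with `positive` naming
#'   the +1 level).
#' @param subject_id Identifier for the subject.
#' @param positive Optional label value mapped to +1.
#' @return A `subject_features` object with fields `X`, `y`, `subject_id`.
#' @export
subject_features <- function(X, y, subject_id = "s1", positive = NULL) {
  stopifnot(is.matrix(X))
  if (!all(is.finite(X))) stop("`X` contains non-finite entries")
  if (nrow(X) != length(y)) stop("rows of `X` must match length of `y`")
  if (!is.null(positive)) {
    y <- ifelse(y == positive, 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1 (or use `positive`)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  structure(list(X = X, y = y, subject_id = subject_id),
            class = "subject_features")
}

#' @export
print.subject_features <- function(x, ...) {
  cat(sprintf("<subject_features> '%s': %d trials (%d/%d) x %d voxels\n",
              x$subject_id, nrow(x$X), sum(x$y > 0), sum(x$y < 0),
              ncol(x$X)))
  invisible(x)
}

#' Average sampled voxels within each cluster
#'
#' Reduces a trials-by-voxels matrix to a trials-by-clusters matrix:
#' column \eqn{j} is the row-wise mean of the sampled voxels falling in
#' cluster \eqn{j}. Clusters with no sampled voxel are omitted (their
#' weight is undefined for that randomization and is treated as zero in
#' downstream scores).
#'
#' @param subject A `subject_features` or a trials x voxels matrix.
#' @param parcellation A [parcellation()].
#' @param sampled_voxels Integer vector of in-mask voxel indices to use;
#'   defaults to all voxels.
#' @return A `cluster_features`: list with `D` (trials x active
#'   clusters), `cluster_ids` (the active clusters, increasing) and
#'   `trial_ids`.
#' @export
average_features <- function(subject, parcellation,
                             sampled_voxels = seq_along(parcellation$labels)) {
  X <- if (inherits(subject, "subject_features")) subject$X else subject
  stopifnot(is.matrix(X))
  if (length(sampled_voxels) == 0L) stop("`sampled_voxels` is empty")
  if (any(sampled_voxels < 1L) || any(sampled_voxels > length(parcellation$labels)))
    stop("`sampled_voxels` out of range")
  lab <- parcellation$labels[sampled_voxels]
  ids <- sort(unique(lab))
  D <- vapply(ids, function(j) {
    cols <- sampled_voxels[lab == j]
    if (length(cols) == 1L) X[, cols] else rowMeans(X[, cols, drop = FALSE])
  }, numeric(nrow(X)))
  if (!is.matrix(D)) D <- matrix(D, nrow = nrow(X))
  structure(list(D = D, cluster_ids = ids, trial_ids = seq_len(nrow(X))),
            class = "cluster_features")
}

#' @export
print.cluster_features <- function(x, ...) {
  cat(sprintf("<cluster_features> %d trials x %d clusters\n",
              nrow(x$D), ncol(x$D)))
  invisible(x)
}
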