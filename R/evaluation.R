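#' Set of voxels selected for one subject
#'
#' @param voxels Integer vector of selected voxel indices (typically
#'   `which(evr != 0)`).
#' @param n_total Total number of in-mask voxels.
#' @return A `selection_set`.
#' @export
selection_set <- function(voxels, n_total) {
  voxels <- sort(unique(as.integer(voxels)))
  if (length(voxels) > 0 && (min(voxels) < 1L || max(voxels) > n_total))
    stop("voxel indices must lie in 1..n_total")
  structure(list(voxels = voxels, n_total = as.integer(n_total)),
            class = "selection_set")
}

#' Selected-voxel sets of every subject in a voting result
#'
#' @param result An `shv_result`.
#' @return List of [selection_set()]s, one per subject (voxels with
#'   nonzero EVR).
#' @export
selected_voxels <- function(result) {
  lapply(seq_len(result$n_subjects), function(i)
    selection_set(which(result$evr[, i] != 0), nrow(result$evr)))
}

#' Chance-corrected pairwise overlap of two selections
#'
#' The stability index between two selected-voxel sets:
#' \deqn{O(S_1, S_2) = \frac{\big| |S_1 \cap S_2| - |S_1||S_2|/N_V \big|}
#'       {\max(|S_1|, |S_2|)}}
#' where \eqn{|S_1||S_2|/N_V} is the overlap expected from two random
#' sets of the same sizes. Identical sets score \eqn{1 - |S|/N_V}.
#'
#' @param s1,s2 [selection_set()]s over the same voxel universe.
#' @return A value in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_overlap <- function(s1, s2) {
  stopifnot(inherits(s1, "selection_set"), inherits(s2, "selection_set"))
  if (s1$n_total != s2$n_total)
    stop("selections cover different voxel universes")
  n1 <- length(s1$voxels); n2 <- length(s2$voxels)
  if (n1 == 0L || n2 == 0L)
    stop("overlap is undefined for an empty selection")
  inter <- length(intersect(s1$voxels, s2$voxels))
  abs(inter - n1 * n2 / s1$n_total) / max(n1, n2)
}

#' Mean pairwise overlap across subjects
#'
#' Averages [pairwise_overlap()] over all unordered subject pairs: the
#' across-subject stability of the selection.
#'
#' @param selections List of at least two [selection_set()]s.
#' @return A scalar in `[0, 1]`.
#' @export
mean_overlap <- function(selections) {
  n <- length(selections)
  if (n < 2L) stop("need at least two selections")
  pairs <- utils::combn(n, 2L)
  mean(apply(pairs, 2L, function(p)
    pairwise_overlap(selections[[p[1]]], selections[[p[2]]])))
}

#' Overlap of every subject pair as a tibble
#'
#' @inheritParams mean_overlap
#' @return Tibble with columns `subject_i`, `subject_j`, `overlap`.
#' @export
overlap_table <- function(selections) {
  n <- length(selections)
  if (n < 2L) stop("need at least two selections")
  pairs <- utils::combn(n, 2L)
  tibble(subject_i = pairs[1, ], subject_j = pairs[2, ],
         overlap = apply(pairs, 2L, function(p)
           pairwise_overlap(selections[[p[1]]], selections[[p[2]]])))
}

#' Precision and recall of selected clusters against planted truth
#'
#' Precision is the fraction of retrieved clusters that are truly
#' discriminative; recall is the fraction of truly discriminative
#' clusters retrieved.
#'
#' @param selected Integer vector of selected cluster ids.
#' @param truth Non-empty integer vector of discriminative cluster ids.
#' @return Tibble with `precision`, `recall`, `n_selected`, `n_truth`,
#'   and `empty_selection` (precision is reported as 0 when nothing was
#'   selected).
#' @export
precision_recall <- function(selected, truth) {
  if (length(truth) == 0L) stop("`truth` must be non-empty")
  selected <- unique(selected); truth <- unique(truth)
  hits <- length(intersect(selected, truth))
  empty <- length(selected) == 0L
  tibble(precision = if (empty) 0 else hits / length(selected),
         recall = hits / length(truth),
         n_selected = length(selected), n_truth = length(truth),
         empty_selection = empty)
}

#' Decoding accuracy as a function of the number of selected voxels
#'
#' Ranks voxels by EVR (ties toward the lower index), and for each
#' requested count trains an l2-regularized linear support-vector
#' classifier (fixed cost 1) on the top-ranked voxels under stratified
#' k-fold cross-validation, z-scoring each fold's features by its
#' training moments. Counts exceeding the number of nonzero-EVR voxels
#' are padded with the next-ranked (zero-EVR) voxels and flagged.
#'
#' @param evr_map Numeric EVR vector over voxels.
#' @param subject A [subject_features()] on the same voxel space.
#' @param voxel_counts Increasing integer vector of voxel counts.
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return An `shv_accuracy_curve` tibble with columns `n_voxels`,
#'   `train_accuracy`, `test_accuracy`, `padded`.
#' @export
accuracy_vs_voxels <- function(evr_map, subject, voxel_counts,
                               k_folds = 4L, seed = 1L) {
  stopifnot(k_folds >= 2L, !is.unsorted(voxel_counts),
            all(voxel_counts >= 1L))
  X <- subject$X; y <- subject$y
  if (length(evr_map) != ncol(X))
    stop("`evr_map` must have one entry per voxel")
  rank_order <- order(-evr_map, seq_along(evr_map))
  n_nonzero <- sum(evr_map > 0)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }

  rows <- lapply(voxel_counts, function(cnt) {
    cnt <- min(cnt, length(evr_map))
    vox <- rank_order[seq_len(cnt)]
    tr_acc <- te_acc <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      Z <- scale_by_train(X[, vox, drop = FALSE], tr)
      mdl <- e1071::svm(Z[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "linear", cost = 1, scale = FALSE)
      pr_tr <- stats::predict(mdl, Z[tr, , drop = FALSE])
      pr_te <- stats::predict(mdl, Z[te, , drop = FALSE])
      tr_acc[f] <- mean(as.character(pr_tr) == as.character(y[tr]))
      te_acc[f] <- mean(as.character(pr_te) == as.character(y[te]))
    }
    tibble(n_voxels = cnt, train_accuracy = mean(tr_acc),
           test_accuracy = mean(te_acc), padded = cnt > n_nonzero)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shv_accuracy_curve", class(out))
  out
}
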