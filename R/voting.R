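#' Per-cluster score vector from cross-verification fits
#'
#' For one subject, the score of cluster \eqn{j} is the mean absolute
#' fitted weight across the inner cross-verification fits,
#' \eqn{s(j) = (1/N_L)\sum_l |W_l(j, i)|}. Clusters absent from a fit
#' (not sampled in that spatial randomization) contribute 0.
#'
#' @param fits List of `shv_group_fit` objects from the same spatial
#'   randomization.
#' @param subject_index Which subject's weight column to score.
#' @param n_clusters Total number of clusters in the parcellation.
#' @return Non-negative numeric vector of length `n_clusters`.
#' @export
score_vector <- function(fits, subject_index, n_clusters) {
  if (length(fits) == 0L) stop("need at least one fit")
  s <- numeric(n_clusters)
  for (f in fits) {
    si <- numeric(n_clusters)
    si[f$cluster_ids] <- abs(f$W[, subject_index])
    s <- s + si
  }
  s / length(fits)
}

#' Top-N selector over strictly positive entries
#'
#' Marks the `n_sel` largest strictly positive entries of a score vector
#' with 1 (ties broken toward the lower index) and everything else with
#' 0. If fewer than `n_sel` entries are positive, only those are marked;
#' a zero entry is never selected.
#'
#' @param scores Non-negative numeric vector.
#' @param n_sel Number of entries to select (>= 1).
#' @return 0/1 integer vector of the same length.
#' @export
top_n_selector <- function(scores, n_sel) {
  stopifnot(n_sel >= 1)
  ord <- order(-scores, seq_along(scores))
  ord <- ord[scores[ord] > 0]
  sel <- integer(length(scores))
  sel[head(ord, n_sel)] <- 1L
  sel
}

#' Quality-controlled selection of well-sampled loops
#'
#' Uniform spatial sampling often draws mostly uninformative voxels, so
#' only the top `floor(alpha_k * n_loops)` spatial randomizations (at
#' least one) by verification accuracy cast votes; ties are broken by
#' loop order. An optional minimum acceptable accuracy further filters
#' the retained loops (if it would discard everything, the single best
#' loop is kept with a warning).
#'
#' @param test_acc Numeric vector of per-loop mean verification
#'   accuracies.
#' @param alpha_k Quality-control ratio in `(0, 1]`.
#' @param min_precision Optional minimum accuracy.
#' @return Increasing integer vector of retained loop indices.
#' @export
select_qualified_loops <- function(test_acc, alpha_k, min_precision = NULL) {
  stopifnot(alpha_k > 0, alpha_k <= 1)
  n <- length(test_acc)
  n_keep <- max(1L, floor(alpha_k * n))
  ord <- order(-test_acc, seq_len(n))
  keep <- head(ord, n_keep)
  if (!is.null(min_precision)) {
    ok <- keep[test_acc[keep] >= min_precision]
    if (length(ok) == 0L) {
      warning("no loop reaches `min_precision`; keeping the single best")
      ok <- ord[1]
    }
    keep <- ok
  }
  sort(keep)
}

#' Groupwise cluster vote rate
#'
#' The hierarchical vote of the method's group level: per subject, each
#' qualified loop's score vector is reduced to a top-`n_sel` selector;
#' the selectors are averaged over loops into per-cluster frequencies;
#' the subject's top-`n_sel` frequencies are kept (outer selector); and
#' the binary outer selectors are averaged across subjects. Entries are
#' therefore exact multiples of `1/n_subjects`, and at most
#' `n_sel * n_subjects` clusters can be positive.
#'
#' @param selected_scores List (one element per subject) of matrices
#'   `n_clusters x n_qualified_loops` holding the score vectors of that
#'   subject's qualified loops.
#' @param n_sel Number of clusters each selector marks.
#' @return Numeric vector of length `n_clusters` with values in `[0, 1]`.
#' @export
cluster_vote_rate <- function(selected_scores, n_sel) {
  stopifnot(length(selected_scores) >= 1L)
  outer <- vapply(selected_scores, function(S) {
    if (is.vector(S)) S <- matrix(S, ncol = 1L)
    stopifnot(ncol(S) >= 1L)
    freq <- rowMeans(apply(S, 2L, top_n_selector, n_sel = n_sel))
    as.numeric(top_n_selector(freq, n_sel))
  }, numeric(nrow_or_len(selected_scores[[1]])))
  rowMeans(outer)
}

nrow_or_len <- function(x) if (is.matrix(x)) nrow(x) else length(x)

#' Per-voxel sampling-conditional vote rate
#'
#' For one subject, a voxel's vote rate is the number of qualified loops
#' in which it was sampled *and* its cluster was selected, divided by
#' the number of qualified loops in which it was sampled at all. Voxels
#' never sampled in a qualified loop have no evidence and get 0.
#'
#' @param sampled_sets List (per qualified loop) of sampled voxel index
#'   vectors.
#' @param selectors List (per qualified loop) of 0/1 cluster selectors.
#' @param parcellation A [parcellation()].
#' @return Numeric vector over voxels with values in `[0, 1]`.
#' @export
voxel_vote_rate <- function(sampled_sets, selectors, parcellation) {
  stopifnot(length(sampled_sets) == length(selectors),
            length(sampled_sets) >= 1L)
  nv <- length(parcellation$labels)
  num <- den <- numeric(nv)
  for (k in seq_along(sampled_sets)) {
    I <- sampled_sets[[k]]
    den[I] <- den[I] + 1
    sel_voxel <- selectors[[k]][parcellation$labels[I]] == 1
    num[I[sel_voxel]] <- num[I[sel_voxel]] + 1
  }
  ifelse(den > 0, num / den, 0)
}

#' Effective vote ratio (EVR)
#'
#' The method's per-voxel output map: the product of a voxel's
#' sampling-conditional vote rate and its cluster's groupwise vote rate,
#' \eqn{\phi^V(m) = \tilde\phi^V(m) \cdot \phi^C(j)} for \eqn{m \in g_j}.
#' Multiplying by the group-level rate suppresses voxels whose cluster
#' is not consistently selected across subjects.
#'
#' @param voxel_votes Per-voxel vote rates from [voxel_vote_rate()].
#' @param cluster_votes Per-cluster vote rates from
#'   [cluster_vote_rate()].
#' @param parcellation A [parcellation()].
#' @return Numeric vector over voxels with values in `[0, 1]`.
#' @export
effective_vote_ratio <- function(voxel_votes, cluster_votes, parcellation) {
  stopifnot(length(voxel_votes) == length(parcellation$labels),
            length(cluster_votes) == parcellation$n_clusters)
  voxel_votes * cluster_votes[parcellation$labels]
}
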