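#' Constrained block subsampling of voxels
#'
#' The outer stability loop does not sample voxels independently:
#' neighbouring voxels are strongly correlated, so whole axis-aligned
#' blocks (default 3 x 3 x 3, anchored at the grid origin) are drawn
#' uniformly without replacement until the in-mask voxels covered first
#' reach `alpha_col * n_voxels`. Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param mask A [voxel_mask()].
#' @param alpha_col Target fraction of in-mask voxels in `(0, 1)`.
#' @param block_size Integer vector of 3 block edge lengths.
#' @return Sorted integer vector of sampled in-mask voxel indices.
#' @export
block_subsample_voxels <- function(mask, alpha_col, block_size = c(3L, 3L, 3L)) {
  stopifnot(alpha_col > 0, alpha_col < 1, length(block_size) == 3L,
            all(block_size >= 1L))
  block_of <- (mask$coords[, 1] - 1L) %/% block_size[1] +
    1000L * ((mask$coords[, 2] - 1L) %/% block_size[2]) +
    1000000L * ((mask$coords[, 3] - 1L) %/% block_size[3])
  blocks <- split(seq_len(mask$n_voxels), block_of)
  target <- alpha_col * mask$n_voxels
  ord <- sample(length(blocks))
  covered <- cumsum(lengths(blocks)[ord])
  k <- which(covered >= target)[1]
  if (is.na(k)) k <- length(blocks)
  if (k == 1L && target < lengths(blocks)[ord][1] / 2)
    warning("`alpha_col` targets fewer voxels than a single block; ",
            "returning one whole block")
  sort(unlist(blocks[ord[seq_len(k)]], use.names = FALSE))
}

#' Stratified subsampling of trials into train and verification sets
#'
#' Draws `round(alpha_row * n_c)` trials from each class (clamped so
#' both classes keep at least one trial on each side); the verification
#' set is the complement. Stratification keeps tiny verification sets
#' (e.g. 4 of 40 trials) from being single-class, which would make the
#' test accuracy degenerate.
#'
#' @param labels +1/-1 trial labels (each class needs >= 2 trials).
#' @param alpha_row Training fraction in `(0, 1)`.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
subsample_trials <- function(labels, alpha_row) {
  stopifnot(alpha_row > 0, alpha_row < 1)
  classes <- unique(labels)
  if (any(vapply(classes, function(cl) sum(labels == cl), 1L) < 2L))
    stop("each class needs at least 2 trials")
  train <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    k <- min(max(1L, round(alpha_row * length(idx))), length(idx) - 1L)
    sample(idx, k)
  }), use.names = FALSE)
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}
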