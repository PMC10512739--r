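#' Voxel affinity graph from signal correlation and spatial distance
#'
#' Builds the sparse symmetric affinity matrix used by normalized-cut
#' parcellation. For voxels \eqn{v_1, v_2} within `support_radius` of each
#' other the affinity is
#' \deqn{A(v_1, v_2) = |corr(X_{:,v_1}, X_{:,v_2})| \cdot
#'       \exp(-dist(v_1, v_2)^2 / \sigma_d^2)}
#' where the correlation is Pearson's over the rows of `data` and the
#' distance is Euclidean in voxel units. Entries beyond `support_radius`
#' are zero, as is the diagonal.
#'
#' `data` may be raw BOLD time series (rows = scans), per-trial features
#' (rows = trials), or their row-wise concatenation across cues and
#' subjects as produced by [combined_group_data()].
#'
#' @param data Numeric matrix, rows = scans/trials, columns = in-mask
#'   voxels in `mask` linear order.
#' @param mask A [voxel_mask()].
#' @param sigma_d Connection radius (voxels) of the distance kernel.
#' @param support_radius Maximum voxel distance with a nonzero entry.
#'   Defaults to `3 * sigma_d`, beyond which the kernel is below
#'   \eqn{e^{-9}}.
#' @return An `affinity_graph`: a list with `weights` (sparse symmetric
#'   `Matrix`), `sigma_d`, `support_radius` and `diagonal = "zero"`.
#' @export
compute_affinity <- function(data, mask, sigma_d,
                             support_radius = 3 * sigma_d) {
  stopifnot(is.matrix(data))
  if (!inherits(mask, "voxel_mask")) stop("`mask` must be a voxel_mask")
  if (mask$n_voxels == 0L) stop("empty mask")
  if (ncol(data) != mask$n_voxels)
    stop("`data` must have one column per in-mask voxel")
  if (!is.numeric(sigma_d) || sigma_d <= 0) stop("`sigma_d` must be > 0")
  if (support_radius <= 0) stop("`support_radius` must be > 0")

  nv <- mask$n_voxels
  n <- nrow(data)
  if (n < 2L) stop("need at least two rows to compute correlations")

  mu <- colMeans(data)
  z <- sweep(data, 2L, mu, "-")
  ss <- sqrt(colSums(z^2))
  const <- ss == 0
  if (any(const)) {
    warning(sum(const), " constant column(s); their correlations are 0")
    ss[const] <- Inf  # zeroes the standardized column
  }
  z <- sweep(z, 2L, ss, "/")

  # enumerate half-space neighbour offsets within the support radius
  # (offsets cannot exceed the grid extent on any axis)
  r <- pmin(floor(support_radius), mask$shape - 1L)
  off <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2],
                               dz = -r[3]:r[3]))
  d2 <- rowSums(off^2)
  keep <- d2 > 0 & d2 <= support_radius^2
  lex <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off <- off[keep & lex, , drop = FALSE]
  d2 <- d2[keep & lex]

  ii <- jj <- integer(0)
  ww <- numeric(0)
  for (o in seq_len(nrow(off))) {
    nb <- sweep(mask$coords, 2L, as.integer(off[o, ]), "+")
    v2 <- mask_lookup(mask, nb)
    sel <- v2 > 0L
    if (!any(sel)) next
    v1 <- which(sel)
    v2 <- v2[sel]
    rho <- abs(colSums(z[, v1, drop = FALSE] * z[, v2, drop = FALSE]))
    rho <- pmin(rho, 1)
    w <- rho * exp(-d2[o] / sigma_d^2)
    nz <- w > 0
    ii <- c(ii, v1[nz]); jj <- c(jj, v2[nz]); ww <- c(ww, w[nz])
  }

  weights <- Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                                  dims = c(nv, nv), symmetric = TRUE)
  structure(
    list(weights = weights, sigma_d = sigma_d,
         support_radius = support_radius, diagonal = "zero"),
    class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf(
    "<affinity_graph> %d voxels, %d edges, sigma_d = %g, support = %g\n",
    nrow(x$weights), Matrix::nnzero(x$weights) / 2, x$sigma_d,
    x$support_radius))
  invisible(x)
}

#' Pool subjects into one matrix for group-level parcellation
#'
#' A single parcellation must serve all subjects, so the affinity is
#' computed on pooled data: each subject's matrix is column-standardized
#' (mean 0, sd 1; constant columns become 0) and the rows are
#' concatenated.
#'
#' @param datasets List of matrices sharing the same columns (voxels).
#' @return A single matrix with `sum(nrow)` rows.
#' @export
combined_group_data <- function(datasets) {
  if (!is.list(datasets) || length(datasets) == 0L)
    stop("`datasets` must be a non-empty list of matrices")
  nv <- ncol(datasets[[1]])
  if (!all(vapply(datasets, ncol, 1L) == nv))
    stop("all matrices must share the same number of columns")
  do.call(rbind, lapply(datasets, function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
    s[s == 0 | !is.finite(s)] <- Inf
    sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
  }))
}
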