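#' Parcellation of in-mask voxels into clusters
#'
#' @param labels Integer vector, one entry per in-mask voxel, with values
#'   in `1:n_clusters`.
#' @param n_clusters Number of clusters; defaults to `max(labels)`.
#' @return A `parcellation` with fields `labels`, `n_clusters` and
#'   `cluster_members` (list mapping cluster id to voxel indices).
#' @export
parcellation <- function(labels, n_clusters = max(labels)) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L) || any(labels > n_clusters))
    stop("labels must lie in 1:n_clusters with no missing values")
  members <- split(seq_along(labels), factor(labels, levels = seq_len(n_clusters)))
  if (any(lengths(members) == 0L)) stop("every cluster must be non-empty")
  structure(
    list(labels = labels, n_clusters = as.integer(n_clusters),
         cluster_members = members),
    class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  sz <- lengths(x$cluster_members)
  cat(sprintf("<parcellation> %d voxels in %d clusters (size %d-%d)\n",
              length(x$labels), x$n_clusters, min(sz), max(sz)))
  invisible(x)
}

#' @export
tidy.parcellation <- function(x, ...) {
  tibble(voxel = seq_along(x$labels), cluster = x$labels)
}

#' @export
glance.parcellation <- function(x, ...) {
  sz <- lengths(x$cluster_members)
  tibble(n_voxels = length(x$labels), n_clusters = x$n_clusters,
         min_size = min(sz), median_size = median(sz), max_size = max(sz))
}

#' Normalized-cut spectral parcellation
#'
#' Partitions the affinity graph into `n_clusters` clusters by the
#' classical spectral relaxation of the normalized cut: the top
#' eigenvectors of the symmetrically normalized affinity
#' \eqn{D^{-1/2} A D^{-1/2}} are row-normalized and clustered with
#' k-means. Results are bit-reproducible for a fixed `seed`.
#'
#' @param affinity An `affinity_graph` from [compute_affinity()].
#' @param n_clusters Number of clusters (at most the number of voxels).
#' @param seed Integer seed controlling k-means initialization.
#' @return A [parcellation()] with exactly `n_clusters` non-empty
#'   clusters.
#' @export
ncut_parcellate <- function(affinity, n_clusters, seed = 1L) {
  if (!inherits(affinity, "affinity_graph"))
    stop("`affinity` must be an affinity_graph")
  A <- affinity$weights
  nv <- nrow(A)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || n_clusters > nv)
    stop("`n_clusters` must be between 1 and the number of voxels")
  if (n_clusters == nv) return(parcellation(seq_len(nv), nv))

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ncomp <- igraph::components(g)$no
  if (ncomp > n_clusters)
    stop("affinity graph has ", ncomp, " connected components but only ",
         n_clusters, " clusters were requested; increase `support_radius` ",
         "(or `sigma_d`) so the graph is better connected")

  d <- Matrix::rowSums(A)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  M <- Matrix::Diagonal(x = dis) %*% A %*% Matrix::Diagonal(x = dis)
  U <- spectral_embedding(M, n_clusters)

  # Ng-Jordan-Weiss row normalization
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn

  labels <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    km <- NULL
    for (attempt in 1:5) {
      km <- tryCatch(
        kmeans(U, centers = n_clusters, nstart = 10, iter.max = 100),
        error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km))
      stop("k-means failed to produce ", n_clusters, " clusters")
    km$cluster
  })
  labels <- repair_empty_clusters(labels, n_clusters, A)
  parcellation(labels, n_clusters)
}

# top-k eigenvectors of a symmetric sparse matrix; dense path for small
# graphs, Lanczos (ARPACK via igraph) otherwise
spectral_embedding <- function(M, k) {
  nv <- nrow(M)
  if (nv <= 1500L || k >= nv - 1L) {
    es <- eigen(as.matrix(Matrix::symmpart(M)), symmetric = TRUE)
    es$vectors[, seq_len(k), drop = FALSE]
  } else {
    fn <- function(x, extra = NULL) as.numeric(M %*% x)
    res <- igraph::arpack(fn, sym = TRUE,
                          options = list(n = nv, nev = k, which = "LA",
                                         ncv = min(nv, max(3L * k, 30L)),
                                         maxiter = 5000L))
    v <- res$vectors
    if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
    v[, seq_len(k), drop = FALSE]
  }
}

# if any requested cluster came back empty, split the largest cluster at
# its weakest internal connection (sign of the Fiedler vector of the
# cluster's subgraph) until all clusters are populated
repair_empty_clusters <- function(labels, n_clusters, A) {
  repeat {
    sizes <- tabulate(labels, nbins = n_clusters)
    empty <- which(sizes == 0L)
    if (length(empty) == 0L) return(labels)
    big <- which.max(sizes)
    mem <- which(labels == big)
    if (length(mem) < 2L) stop("cannot split a singleton cluster")
    sub <- as.matrix(A[mem, mem, drop = FALSE])
    d <- rowSums(sub)
    L <- diag(length(mem)) - diag(ifelse(d > 0, 1 / sqrt(d), 0)) %*%
      sub %*% diag(ifelse(d > 0, 1 / sqrt(d), 0))
    es <- eigen((L + t(L)) / 2, symmetric = TRUE)
    f <- es$vectors[, length(mem) - 1L]
    half <- f >= median(f)
    if (all(half) || !any(half)) half <- seq_along(mem) <= length(mem) / 2
    labels[mem[half]] <- empty[1]
  }
}
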