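#' Row-wise block soft-thresholding (proximal operator of the group norm)
#'
#' Maps each row \eqn{r} of `W` to \eqn{r \cdot \max(0, 1 - t/\|r\|_2)}:
#' rows whose l2 norm is at or below the threshold are zeroed, the rest
#' are shrunk radially. This is the proximal operator of
#' \eqn{t \sum_j \|W(j,:)\|_2} and the elementary step that zeroes whole
#' clusters jointly across subjects.
#'
#' @param W Numeric matrix (clusters x subjects).
#' @param threshold Non-negative scalar.
#' @return Matrix of the same shape.
#' @export
group_prox <- function(W, threshold) {
  stopifnot(is.matrix(W), threshold >= 0)
  nrm <- sqrt(rowSums(W^2))
  scale <- ifelse(nrm <= threshold, 0, 1 - threshold / nrm)
  W * scale
}

#' Mixed l1/l2 (group-lasso) logistic objective
#'
#' Evaluates
#' \deqn{\sum_i \sum_t \log(1+\exp(-y^i_t(D^i_{t,:}W_{:,i}+b_i))) +
#'       \lambda \sum_j \|W_{j,:}\|_2.}
#'
#' @param W Clusters x subjects weight matrix.
#' @param b Per-subject intercepts.
#' @param features List of `cluster_features` (or matrices), one per
#'   subject, sharing columns.
#' @param labels List of +1/-1 label vectors.
#' @param lambda Penalty weight.
#' @return The objective value (a scalar).
#' @export
group_objective <- function(W, b, features, labels, lambda) {
  if (!is.matrix(W)) W <- matrix(W, ncol = 1L)
  features <- as_feature_list(features)
  labels <- as_label_list(labels, length(features))
  f <- 0
  for (i in seq_along(features)) {
    D <- feature_matrix(features[[i]])
    m <- labels[[i]] * (drop(D %*% W[, i]) + b[i])
    f <- f + sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
  }
  f + lambda * sum(sqrt(rowSums(W^2)))
}

#' Smallest penalty that zeroes all cluster weights
#'
#' At the intercept-only optimum \eqn{b_i = \log(n^+_i/n^-_i)} the
#' gradient of the logistic loss with respect to row \eqn{j} of `W` has
#' l2 norm \eqn{g_j}; for any `lambda >= max_j g_j` the all-zero weight
#' matrix is the exact solution. Useful for building penalty grids.
#'
#' @inheritParams group_objective
#' @return The critical penalty value.
#' @export
lambda_max <- function(features, labels) {
  features <- as_feature_list(features)
  labels <- as_label_list(labels, length(features))
  G <- NULL
  for (i in seq_along(features)) {
    D <- feature_matrix(features[[i]])
    y <- labels[[i]]
    b <- log(sum(y > 0) / sum(y < 0))
    m <- y * b
    r <- -y / (1 + exp(m))
    g <- drop(crossprod(D, r))
    G <- cbind(G, g)
  }
  max(sqrt(rowSums(G^2)))
}

#' Fit the groupwise mixed l1/l2 logistic model
#'
#' Minimizes the [group_objective()] jointly over all subjects' weight
#' columns and (unpenalized) intercepts by monotone accelerated proximal
#' gradient (FISTA with backtracking), so whole clusters are selected or
#' discarded consistently across subjects. With a single subject the row
#' norm is `|w_j|` and the fit is the l1-penalized (lasso) logistic
#' model.
#'
#' Cluster features are matched on `cluster_ids`: only clusters present
#' for every subject are fitted.
#'
#' @inheritParams group_objective
#' @param lambda Non-negative penalty weight.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum number of proximal-gradient iterations.
#' @return An `shv_group_fit` with fields `W` (clusters x subjects,
#'   rownames = cluster ids), `b`, `lambda`, `objective_trace`
#'   (non-increasing), `objective`, `converged`, `iterations`,
#'   `cluster_ids`, `subject_ids`.
#' @export
fit_group_logistic <- function(features, labels, lambda,
                               tol = 1e-6, max_iter = 2000L) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1)
  features <- as_feature_list(features)
  labels <- as_label_list(labels, length(features))
  for (y in labels) {
    if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
      stop("labels must be +1/-1 with both classes present")
  }

  ids_list <- lapply(features, function(f) f$cluster_ids)
  common <- sort(Reduce(intersect, ids_list))
  if (length(common) == 0L) stop("no cluster is shared by all subjects")
  D_list <- lapply(features, function(f) {
    f$D[, match(common, f$cluster_ids), drop = FALSE]
  })
  for (i in seq_along(D_list)) {
    if (nrow(D_list[[i]]) != length(labels[[i]]))
      stop("labels and feature rows disagree for subject ", i)
  }

  res <- fit_group_logistic_cpp(D_list, labels, lambda, tol,
                                as.integer(max_iter))
  if (!res$converged)
    warning("solver did not converge within ", max_iter,
            " iterations; returning the best iterate")
  W <- res$W
  rownames(W) <- common
  sids <- vapply(seq_along(features), function(i) {
    f <- features[[i]]
    if (!is.null(f$subject_id)) as.character(f$subject_id) else paste0("s", i)
  }, character(1))
  colnames(W) <- sids
  structure(
    list(W = W, b = drop(res$b), lambda = lambda,
         objective_trace = res$objective_trace,
         objective = utils::tail(res$objective_trace, 1),
         converged = res$converged, iterations = res$iterations,
         cluster_ids = common, subject_ids = sids),
    class = "shv_group_fit")
}

#' Fit the single-subject l1-penalized (structured-sparsity) model
#'
#' Convenience wrapper around [fit_group_logistic()] with one subject,
#' where the group penalty reduces to the lasso penalty
#' \eqn{\lambda \sum_j |w_j|}. This is the per-subject baseline the
#' groupwise model is compared against.
#'
#' @param features A single `cluster_features` (or matrix).
#' @param labels A +1/-1 label vector.
#' @inheritParams fit_group_logistic
#' @export
fit_single_logistic <- function(features, labels, lambda,
                                tol = 1e-6, max_iter = 2000L) {
  fit_group_logistic(list(features), list(labels), lambda,
                     tol = tol, max_iter = max_iter)
}

#' Classification accuracy of a fitted model on given trials
#'
#' Predicts \eqn{sign(Dw + b)} (zero counts as +1) for one subject and
#' returns the fraction of correctly classified trials.
#'
#' @param fit An `shv_group_fit`.
#' @param features `cluster_features` (or matrix) whose `cluster_ids`
#'   cover the fit's clusters.
#' @param labels +1/-1 labels for the trials.
#' @param subject_index Column of `W` to use.
#' @return Accuracy in `[0, 1]`.
#' @export
predict_accuracy <- function(fit, features, labels, subject_index = 1L) {
  if (length(labels) == 0L) stop("empty trial set")
  D <- if (inherits(features, "cluster_features")) {
    idx <- match(fit$cluster_ids, features$cluster_ids)
    if (anyNA(idx)) stop("`features` is missing clusters present in `fit`")
    features$D[, idx, drop = FALSE]
  } else {
    features
  }
  eta <- drop(D %*% fit$W[, subject_index]) + fit$b[subject_index]
  pred <- ifelse(eta >= 0, 1, -1)
  mean(pred == labels)
}

#' @export
print.shv_group_fit <- function(x, ...) {
  cat(sprintf(paste0("<shv_group_fit> %d clusters x %d subjects, ",
                     "lambda = %g, %d active rows, %sconverged (%d it)\n"),
              nrow(x$W), ncol(x$W), x$lambda,
              sum(rowSums(abs(x$W)) > 0), if (x$converged) "" else "NOT ",
              x$iterations))
  invisible(x)
}

#' @export
tidy.shv_group_fit <- function(x, ...) {
  tibble(cluster_id = rep(x$cluster_ids, times = ncol(x$W)),
         subject = rep(x$subject_ids, each = nrow(x$W)),
         weight = as.vector(x$W))
}

#' @export
glance.shv_group_fit <- function(x, ...) {
  tibble(lambda = x$lambda, objective = x$objective,
         iterations = x$iterations, converged = x$converged,
         n_clusters = nrow(x$W), n_subjects = ncol(x$W),
         n_active_clusters = sum(rowSums(abs(x$W)) > 0))
}

# ---- internal coercers -----------------------------------------------

as_feature_list <- function(features) {
  if (inherits(features, "cluster_features") || is.matrix(features))
    features <- list(features)
  lapply(features, function(f) {
    if (inherits(f, "cluster_features")) return(f)
    if (is.matrix(f))
      return(structure(list(D = f, cluster_ids = seq_len(ncol(f)),
                            trial_ids = seq_len(nrow(f))),
                       class = "cluster_features"))
    stop("features must be cluster_features or matrices")
  })
}

as_label_list <- function(labels, n) {
  if (!is.list(labels)) labels <- list(labels)
  if (length(labels) != n)
    stop("need one label vector per subject")
  lapply(labels, as.numeric)
}

feature_matrix <- function(f) {
  if (inherits(f, "cluster_features")) f$D else f
}
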