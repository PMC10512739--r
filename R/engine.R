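#' Configuration of a stable-hierarchical-voting run
#'
#' Defaults follow the settings used for real 200-cluster decoding runs
#' (200 spatial randomizations of 1% of the voxels in 3 x 3 x 3 blocks,
#' 20 cross-verifications of 90% stratified trial subsamples, top-30%
#' quality control, 15 selected clusters). See [benchmark_config()] for
#' the reduced planted-signal benchmark settings.
#'
#' @param n_k Number of outer spatial randomization loops.
#' @param n_l Number of inner cross-verification loops.
#' @param alpha_col Voxel subsampling fraction in `(0, 1)`.
#' @param alpha_row Trial subsampling fraction in `(0, 1)`.
#' @param alpha_k Quality-control ratio in `(0, 1]`: the fraction of
#'   outer loops, ranked by verification accuracy, allowed to vote.
#' @param n_sel Number of clusters each selector marks.
#' @param lambda_grid Candidate penalty values for [select_lambda()];
#'   `NULL` derives a three-point grid from the critical penalty
#'   [lambda_max()] of the full data.
#' @param block_size Edge lengths of the voxel sampling blocks.
#' @param seed Master seed; every random draw of a run derives from it.
#' @param min_precision Optional minimum acceptable verification
#'   accuracy for a loop to vote.
#' @return An `shv_config` list.
#' @export
shv_config <- function(n_k = 200L, n_l = 20L, alpha_col = 0.01,
                       alpha_row = 0.9, alpha_k = 0.3, n_sel = 15L,
                       lambda_grid = NULL, block_size = c(3L, 3L, 3L),
                       seed = 1L, min_precision = NULL) {
  stopifnot(n_k >= 1, n_l >= 1, alpha_col > 0, alpha_col < 1,
            alpha_row > 0, alpha_row < 1, alpha_k > 0, alpha_k <= 1,
            n_sel >= 1, length(block_size) == 3L)
  structure(list(n_k = as.integer(n_k), n_l = as.integer(n_l),
                 alpha_col = alpha_col, alpha_row = alpha_row,
                 alpha_k = alpha_k, n_sel = as.integer(n_sel),
                 lambda_grid = lambda_grid,
                 block_size = as.integer(block_size),
                 seed = as.integer(seed), min_precision = min_precision),
            class = "shv_config")
}

#' Benchmark configuration for the reduced planted-signal study
#'
#' The desk-scale counterpart of the full synthetic study: 50 spatial
#' randomizations of 5% of the voxels, 10 cross-verifications, top-30%
#' quality control, 4 selected clusters.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [shv_config()].
#' @export
benchmark_config <- function(seed = 1L, ...) {
  args <- list(n_k = 50L, n_l = 10L, alpha_col = 0.05, alpha_row = 0.9,
               alpha_k = 0.3, n_sel = 4L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(shv_config, args)
}

# deterministic sampling plan shared by every penalty candidate and by
# the group and single-subject methods: all randomness is consumed here
build_sampling_plan <- function(mask, labels_list, config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(config$seed)
  voxel_sets <- vector("list", config$n_k)
  splits <- vector("list", config$n_k)
  for (k in seq_len(config$n_k)) {
    voxel_sets[[k]] <- block_subsample_voxels(mask, config$alpha_col,
                                              config$block_size)
    splits[[k]] <- lapply(seq_len(config$n_l), function(l) {
      lapply(labels_list, subsample_trials, alpha_row = config$alpha_row)
    })
  }
  list(voxel_sets = voxel_sets, splits = splits)
}

# z-score columns by training-row moments; verification rows reuse them
scale_by_train <- function(D, train) {
  mu <- colMeans(D[train, , drop = FALSE])
  s <- apply(D[train, , drop = FALSE], 2L, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(D, 2L, mu, "-"), 2L, s, "/")
}

#' Run stable hierarchical voting
#'
#' Executes the full nested stability-selection procedure: the outer
#' loop draws `n_k` constrained block subsamples of voxels and averages
#' them within clusters; the inner loop fits the penalized logistic
#' model on `n_l` stratified trial subsamples and measures verification
#' accuracy on the held-out trials; per subject, only the
#' top-`alpha_k` fraction of outer loops by accuracy vote. Votes are
#' aggregated hierarchically into cluster vote rates, per-voxel vote
#' rates, and the effective vote ratio (EVR) map.
#'
#' Cluster features are z-scored per subject on the training trials of
#' each inner split (verification trials reuse the training moments) so
#' one penalty is comparable across subsamples.
#'
#' @param data List of [subject_features()] over a common voxel space.
#' @param mask The [voxel_mask()] of that space.
#' @param parcellation A [parcellation()] of the space.
#' @param config An [shv_config()].
#' @param lambda Penalty weight for the model fits.
#' @param method `"group"` fits all subjects jointly with the mixed
#'   l1/l2 penalty; `"single"` fits each subject separately with the l1
#'   penalty on the *same* sampling plan (the comparison baseline).
#' @return An `shv_result` with `cluster_votes` (per-cluster groupwise
#'   vote rates), `voxel_votes` and `evr` (voxels x subjects matrices),
#'   `mean_evr`, `test_acc` (subjects x loops), `qualified_loops`,
#'   `scores` (clusters x subjects x loops array), plus the call
#'   settings.
#' @export
run_shv <- function(data, mask, parcellation, config, lambda,
                    method = c("group", "single")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "shv_config"))
  nv <- length(parcellation$labels)
  if (mask$n_voxels != nv)
    stop("mask and parcellation cover different voxel counts")
  for (s in data) {
    if (ncol(s$X) != nv) stop("subject feature columns must match the mask")
  }
  ns <- length(data)
  nc <- parcellation$n_clusters
  labels_list <- lapply(data, function(s) s$y)

  plan <- build_sampling_plan(mask, labels_list, config)

  scores <- array(0, dim = c(nc, ns, config$n_k))
  test_acc <- matrix(0, nrow = ns, ncol = config$n_k)

  for (k in seq_len(config$n_k)) {
    I <- plan$voxel_sets[[k]]
    feats <- lapply(data, average_features, parcellation = parcellation,
                    sampled_voxels = I)
    absW <- matrix(0, nrow = nc, ncol = ns)
    acc <- matrix(NA_real_, nrow = ns, ncol = config$n_l)
    n_ok <- 0L
    for (l in seq_len(config$n_l)) {
      sp <- plan$splits[[k]][[l]]
      Dz <- lapply(seq_len(ns), function(i)
        scale_by_train(feats[[i]]$D, sp[[i]]$train))
      fit_ok <- tryCatch({
        if (method == "group") {
          tr_feats <- lapply(seq_len(ns), function(i) {
            f <- feats[[i]]
            f$D <- Dz[[i]][sp[[i]]$train, , drop = FALSE]
            f
          })
          tr_labels <- lapply(seq_len(ns), function(i)
            labels_list[[i]][sp[[i]]$train])
          fit <- fit_group_logistic(tr_feats, tr_labels, lambda)
          for (i in seq_len(ns)) {
            te <- sp[[i]]$test
            acc[i, l] <- predict_accuracy(
              fit, Dz[[i]][te, match(fit$cluster_ids, feats[[i]]$cluster_ids),
                           drop = FALSE],
              labels_list[[i]][te], subject_index = i)
            absW[fit$cluster_ids, i] <- absW[fit$cluster_ids, i] +
              abs(fit$W[, i])
          }
        } else {
          for (i in seq_len(ns)) {
            f <- feats[[i]]
            tr <- sp[[i]]$train; te <- sp[[i]]$test
            ftr <- f; ftr$D <- Dz[[i]][tr, , drop = FALSE]
            fit <- fit_single_logistic(ftr, labels_list[[i]][tr], lambda)
            acc[i, l] <- predict_accuracy(
              fit, Dz[[i]][te, match(fit$cluster_ids, f$cluster_ids),
                           drop = FALSE],
              labels_list[[i]][te], subject_index = 1L)
            absW[fit$cluster_ids, i] <- absW[fit$cluster_ids, i] +
              abs(fit$W[, 1])
          }
        }
        TRUE
      }, error = function(e) FALSE)
      if (fit_ok) n_ok <- n_ok + 1L else acc[, l] <- NA_real_
    }
    if (n_ok > 0L) {
      scores[, , k] <- absW / n_ok
      test_acc[, k] <- rowMeans(acc, na.rm = TRUE)
    }  # a fully failed loop keeps accuracy 0 and casts no votes
  }
  test_acc[!is.finite(test_acc)] <- 0

  qualified <- lapply(seq_len(ns), function(i)
    select_qualified_loops(test_acc[i, ], config$alpha_k,
                           config$min_precision))

  cluster_votes <- cluster_vote_rate(
    lapply(seq_len(ns), function(i)
      matrix(scores[, i, qualified[[i]]], nrow = nc)),
    config$n_sel)

  voxel_votes <- vapply(seq_len(ns), function(i) {
    q <- qualified[[i]]
    voxel_vote_rate(plan$voxel_sets[q],
                    lapply(q, function(k)
                      top_n_selector(scores[, i, k], config$n_sel)),
                    parcellation)
  }, numeric(nv))

  evr <- vapply(seq_len(ns), function(i)
    effective_vote_ratio(voxel_votes[, i], cluster_votes, parcellation),
    numeric(nv))
  sids <- vapply(data, function(s) as.character(s$subject_id), character(1))
  colnames(voxel_votes) <- colnames(evr) <- sids

  structure(
    list(cluster_votes = cluster_votes, voxel_votes = voxel_votes,
         evr = evr, mean_evr = rowMeans(evr), test_acc = test_acc,
         qualified_loops = qualified, scores = scores, lambda = lambda,
         method = method, config = config, n_subjects = ns,
         subject_ids = sids, parcel_labels = parcellation$labels),
    class = "shv_result")
}

#' @export
print.shv_result <- function(x, ...) {
  cat(sprintf(paste0("<shv_result> %s method, lambda = %g: %d subjects, ",
                     "%d loops, %d clusters voted, mean qualified ",
                     "accuracy %.3f\n"),
              x$method, x$lambda, x$n_subjects, ncol(x$test_acc),
              sum(x$cluster_votes > 0), mean_qualified_accuracy(x)))
  invisible(x)
}

#' @export
tidy.shv_result <- function(x, ...) {
  tibble(cluster_id = seq_along(x$cluster_votes),
         vote_rate = x$cluster_votes)
}

#' @export
glance.shv_result <- function(x, ...) {
  tibble(method = x$method, lambda = x$lambda,
         n_subjects = x$n_subjects,
         mean_qualified_accuracy = mean_qualified_accuracy(x),
         n_clusters_voted = sum(x$cluster_votes > 0),
         n_voxels_mean_evr = sum(x$mean_evr > 0))
}

#' Mean verification accuracy over each subject's qualified loops
#'
#' The model-selection criterion for the penalty weight:
#' \eqn{\bar R = (1/N_S)\sum_i (1/N_i)\sum_k R^{test}_{i,k}} over
#' qualified loops.
#'
#' @param result An `shv_result`.
#' @return A scalar accuracy.
#' @export
mean_qualified_accuracy <- function(result) {
  mean(vapply(seq_len(result$n_subjects), function(i)
    mean(result$test_acc[i, result$qualified_loops[[i]]]),
    numeric(1)))
}

#' Choose the penalty weight by qualified verification accuracy
#'
#' Runs the full voting procedure once per candidate penalty with the
#' *same* master seed, so every candidate sees identical sampling plans
#' (common random numbers), and keeps the candidate maximizing the mean
#' qualified verification accuracy; ties go to the larger penalty (the
#' sparser model).
#'
#' @inheritParams run_shv
#' @return A list with `lambda` (the winner), `r_bar` (a tibble of
#'   candidate penalties and their accuracies) and `result` (the
#'   `shv_result` of the winning run).
#' @export
select_lambda <- function(data, mask, parcellation, config,
                          method = c("group", "single")) {
  method <- match.arg(method)
  grid <- config$lambda_grid
  if (is.null(grid))
    grid <- default_lambda_grid(data, parcellation)
  stopifnot(length(grid) >= 1L)
  grid <- sort(unique(grid))
  runs <- lapply(grid, function(lam)
    run_shv(data, mask, parcellation, config, lam, method = method))
  rbar <- vapply(runs, mean_qualified_accuracy, numeric(1))
  best <- max(which(rbar == max(rbar)))  # ties -> larger penalty
  list(lambda = grid[best],
       r_bar = tibble(lambda = grid, r_bar = rbar),
       result = runs[[best]])
}

# three-point grid anchored at the critical penalty of the full
# (unsubsampled, z-scored) cluster features
default_lambda_grid <- function(data, parcellation,
                                fractions = c(0.05, 0.2, 0.5)) {
  feats <- lapply(data, average_features, parcellation = parcellation)
  feats <- lapply(feats, function(f) {
    f$D <- scale_by_train(f$D, seq_len(nrow(f$D)))
    f
  })
  lmax <- lambda_max(feats, lapply(data, function(s) s$y))
  fractions * lmax
}
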