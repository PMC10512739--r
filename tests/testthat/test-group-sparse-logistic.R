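test_that("cluster averaging equals the loop-based group-mean oracle", {
  set.seed(1)
  p <- parcellation(c(1, 1, 2, 2, 2, 3, 3, 1), 3)
  X <- matrix(rnorm(8 * 6), 6, 8)
  samp <- c(1, 3, 4, 6, 8)
  cf <- average_features(X, p, samp)
  expect_equal(cf$cluster_ids, c(1L, 2L, 3L))
  for (j in seq_along(cf$cluster_ids)) {
    cols <- samp[p$labels[samp] == cf$cluster_ids[j]]
    expect_equal(cf$D[, j], rowMeans(X[, cols, drop = FALSE]))
  }
  # single sampled voxel: column is that voxel
  cf1 <- average_features(X, p, 6L)
  expect_equal(cf1$cluster_ids, 3L)
  expect_equal(drop(cf1$D), X[, 6])
  # mean of (1, 3) is 2
  X2 <- matrix(c(1, 3), 1, 2)
  expect_equal(drop(average_features(X2, parcellation(c(1, 1), 1))$D), 2)
  # clusters without sampled voxels are omitted
  expect_equal(average_features(X, p, c(1, 2))$cluster_ids, 1L)
  expect_error(average_features(X, p, integer(0)), "empty")
})

test_that("group_prox is the row-wise block soft threshold", {
  W <- rbind(c(3, 4), c(1, 0), c(0, 0))
  expect_equal(group_prox(W, 0), W)                    # identity
  expect_equal(group_prox(W, 5)[1, ], c(0, 0))         # boundary row
  expect_equal(group_prox(W, 2.5)[1, ], c(1.5, 2.0))   # 1 - 2.5/5 scaling
  # non-expansiveness on random pairs
  set.seed(2)
  for (rep in 1:20) {
    A <- matrix(rnorm(12), 4); B <- matrix(rnorm(12), 4)
    thr <- runif(1, 0, 2)
    expect_lte(sqrt(sum((group_prox(A, thr) - group_prox(B, thr))^2)),
               sqrt(sum((A - B)^2)) + 1e-12)
  }
})

test_that("at lambda >= lambda_max the fit is exactly the intercept model", {
  inst <- random_instance(n_subjects = 2, n_trials = 24, seed = 3)
  lmax <- lambda_max(inst$D, inst$y)
  for (lam in c(lmax, 2 * lmax)) {
    fit <- fit_group_logistic(inst$D, inst$y, lambda = lam)
    expect_true(all(fit$W == 0))
    expect_equal(fit$b, vapply(inst$y, function(y)
      log(sum(y > 0) / sum(y < 0)), 0), tolerance = 1e-10)
  }
  # support shrinks to empty as lambda approaches lambda_max
  n_active <- vapply(c(0.05, 0.3, 1) * lmax, function(lam) {
    f <- fit_group_logistic(inst$D, inst$y, lam, tol = 1e-9)
    sum(rowSums(abs(f$W)) > 0)
  }, 0)
  expect_true(all(diff(n_active) <= 0))
  expect_identical(n_active[[3]], 0)
})

test_that("lambda = 0 matches the unpenalized maximum-likelihood fit", {
  inst <- random_instance(n_subjects = 1, n_trials = 80, n_clusters = 5,
                          seed = 4, sd_noise = 3)
  fit <- fit_single_logistic(inst$D[[1]], inst$y[[1]], lambda = 0,
                             tol = 1e-12, max_iter = 20000)
  g <- glm(I(inst$y[[1]] == 1) ~ inst$D[[1]], family = binomial)
  obj_glm <- group_objective(matrix(coef(g)[-1], ncol = 1), coef(g)[1],
                             inst$D[1], inst$y[1], 0)
  expect_lt(abs(fit$objective - obj_glm) / obj_glm, 1e-4)
  expect_equal(unname(drop(fit$W)), unname(coef(g)[-1]), tolerance = 1e-3)
})

test_that("the single-subject model is the one-column group model", {
  inst <- random_instance(n_subjects = 1, n_trials = 40, seed = 5)
  f1 <- fit_single_logistic(inst$D[[1]], inst$y[[1]], lambda = 3)
  f2 <- fit_group_logistic(inst$D, inst$y, lambda = 3)
  expect_equal(f1$W, f2$W, tolerance = 1e-8)
  expect_equal(f1$b, f2$b, tolerance = 1e-8)
})

test_that("the l1 path agrees with glmnet on a single subject", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(n_subjects = 1, n_trials = 60, n_clusters = 6,
                          seed = 6, sd_noise = 2)
  D <- inst$D[[1]]; y <- inst$y[[1]]
  n <- length(y)
  for (lam in c(2, 6)) {
    fit <- fit_single_logistic(D, y, lam, tol = 1e-12, max_iter = 20000)
    gn <- glmnet::glmnet(D, factor(y), family = "binomial",
                         lambda = lam / n, standardize = FALSE,
                         thresh = 1e-14)
    w_gn <- matrix(as.numeric(gn$beta), ncol = 1)
    obj_gn <- group_objective(w_gn, as.numeric(gn$a0), inst$D, inst$y, lam)
    expect_lt(abs(fit$objective - obj_gn) / obj_gn, 1e-4)
  }
})

test_that("objective trace never increases and solver is equivariant", {
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(n_subjects = 2, n_trials = 25, seed = 70 + rep)
    fit <- fit_group_logistic(inst$D, inst$y, lambda = runif(1, 0.5, 5))
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
  # permuting cluster order permutes W rows identically
  inst <- random_instance(n_subjects = 2, n_trials = 30, seed = 8)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  f1 <- fit_group_logistic(inst$D, inst$y, 2, tol = 1e-11, max_iter = 10000)
  f2 <- fit_group_logistic(lapply(inst$D, function(d) d[, perm]),
                           inst$y, 2, tol = 1e-11, max_iter = 10000)
  expect_equal(unname(f2$W), unname(f1$W[perm, ]), tolerance = 1e-5)
})

test_that("cluster features are matched on shared cluster ids", {
  set.seed(9)
  p <- parcellation(rep(1:4, each = 3), 4)
  X1 <- matrix(rnorm(12 * 20), 20); X2 <- matrix(rnorm(12 * 20), 20)
  cf1 <- average_features(X1, p, 1:12)       # clusters 1..4
  cf2 <- average_features(X2, p, 1:9)        # clusters 1..3
  y <- rep(c(1, -1), 10)
  fit <- fit_group_logistic(list(cf1, cf2), list(y, y), 1)
  expect_equal(fit$cluster_ids, 1:3)
  expect_equal(nrow(fit$W), 3L)
})

test_that("predict_accuracy follows the sign rule and the chance law", {
  # all-positive labels with a positive intercept: always right
  f <- structure(list(W = matrix(0, 2, 1), b = 1, cluster_ids = 1:2),
                 class = "shv_group_fit")
  D <- matrix(rnorm(20), 10, 2)
  expect_equal(predict_accuracy(f, D, rep(1, 10)), 1.0)
  # perfectly separating weights on a noiseless toy
  set.seed(10)
  Dn <- matrix(rnorm(40), 20, 2)
  yn <- ifelse(Dn[, 1] >= 0, 1, -1)
  fs <- structure(list(W = matrix(c(1, 0), 2, 1), b = 0, cluster_ids = 1:2),
                  class = "shv_group_fit")
  expect_equal(predict_accuracy(fs, Dn, yn), 1.0)
  # random weights on balanced random labels: accuracy near 1/2
  set.seed(11)
  Db <- matrix(rnorm(2e4), 1e4, 2)
  yb <- rep(c(1, -1), 5e3)
  fr <- structure(list(W = matrix(rnorm(2), 2, 1), b = 0, cluster_ids = 1:2),
                  class = "shv_group_fit")
  expect_lt(abs(predict_accuracy(fr, Db, yb) - 0.5), 0.02)
  expect_error(predict_accuracy(fr, Db[0, , drop = FALSE], numeric(0)),
               "empty")
})

test_that("tidy and glance summarize a fit", {
  inst <- random_instance(seed = 12)
  fit <- fit_group_logistic(inst$D, inst$y, 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16L)
  expect_named(td, c("cluster_id", "subject", "weight"))
  gl <- glance(fit)
  expect_equal(gl$objective, fit$objective)
  expect_true(gl$converged)
})
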