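test_that("block subsampling draws whole anchored blocks to the target", {
  # a mask equal to one block: any target returns the whole block
  m1 <- voxel_mask(c(3, 3, 3))
  set.seed(1)
  expect_equal(block_subsample_voxels(m1, 0.9), 1:27)
  # a 4x4x4 grid with 4x4x4 blocks is a single block
  m2 <- voxel_mask(c(4, 4, 4))
  expect_equal(block_subsample_voxels(m2, 0.5, c(4L, 4L, 4L)), 1:64)
  # tiny alpha returns one block with a warning
  m3 <- voxel_mask(c(9, 9, 3))
  expect_warning(v <- block_subsample_voxels(m3, 0.01), "one whole block")
  expect_equal(length(v), 27L)
})

test_that("block draws are uniform over blocks", {
  m <- voxel_mask(c(9, 9, 3))  # 9 complete 3x3x3 blocks
  set.seed(2)
  n_rep <- 4000
  counts <- numeric(m$n_voxels)
  for (r in seq_len(n_rep)) {
    v <- block_subsample_voxels(m, 0.3)    # 3 of 9 blocks per draw
    counts[v] <- counts[v] + 1
  }
  freq <- counts / n_rep
  p <- 3 / 9
  se <- sqrt(p * (1 - p) / n_rep)
  expect_true(all(abs(freq - p) <= 4 * se))
})

test_that("trial subsampling is stratified with complementary test set", {
  y <- rep(c(1, -1), each = 20)
  set.seed(3)
  sp <- subsample_trials(y, 0.9)
  expect_equal(length(sp$train), 36L)
  expect_equal(sum(y[sp$train] == 1), 18L)
  expect_equal(sort(c(sp$train, sp$test)), 1:40)
  # train = n - 2 leaves one test trial per class
  sp2 <- subsample_trials(y, 0.95)
  expect_equal(length(sp2$test), 2L)
  expect_setequal(y[sp2$test], c(1, -1))
  expect_error(subsample_trials(c(1, 1, 1, -1), 0.5), "at least 2")
  # inclusion frequency matches alpha_row
  incl <- numeric(40)
  for (r in 1:2000) {
    tr <- subsample_trials(y, 0.8)$train
    incl[tr] <- incl[tr] + 1
  }
  freq <- incl / 2000
  se <- sqrt(0.8 * 0.2 / 2000)
  expect_true(all(abs(freq - 0.8) <= 4 * se))
})

test_that("score vectors average absolute weights with zeros for unsampled", {
  mk_fit <- function(W, ids) structure(
    list(W = W, cluster_ids = ids), class = "shv_group_fit")
  # single fit: |W|
  f <- mk_fit(matrix(c(-1, 2), 2, 1), c(2L, 5L))
  expect_equal(score_vector(list(f), 1, 6), c(0, 1, 0, 0, 2, 0))
  # +2 and -2 across loops average to 2 (absolute before mean)
  f1 <- mk_fit(matrix(2, 1, 1), 3L); f2 <- mk_fit(matrix(-2, 1, 1), 3L)
  expect_equal(score_vector(list(f1, f2), 1, 4)[3], 2)
  # random toy vs loop oracle
  set.seed(4)
  fits <- lapply(1:3, function(l) mk_fit(matrix(rnorm(8), 4, 2),
                                         c(1L, 3L, 4L, 7L)))
  s <- score_vector(fits, 2, 8)
  manual <- numeric(8)
  for (f in fits) manual[f$cluster_ids] <- manual[f$cluster_ids] +
    abs(f$W[, 2]) / 3
  expect_equal(s, manual)
  expect_error(score_vector(list(), 1, 3), "at least one")
})

test_that("top-n selector keeps nonzero leaders with low-id tie-breaks", {
  expect_equal(top_n_selector(rep(0, 4), 2), rep(0L, 4))
  expect_equal(sum(top_n_selector(c(0, 3, 0, 1), 4)), 2L)   # fewer nonzeros
  expect_equal(top_n_selector(c(5, 3, 3, 1), 2), c(1L, 1L, 0L, 0L))
  # never marks a zero entry even when n_sel exceeds the support
  set.seed(5)
  for (r in 1:25) {
    s <- round(runif(10), 1) * rbinom(10, 1, 0.5)
    sel <- top_n_selector(s, sample(1:10, 1))
    expect_true(all(s[sel == 1] > 0))
    expect_equal(sum(sel), min(sum(s > 0), sum(sel)))
  }
})

test_that("qualified-loop selection keeps the top fraction by accuracy", {
  expect_equal(select_qualified_loops(c(.5, .7, .6), 1), 1:3)
  expect_equal(length(select_qualified_loops(runif(200), 0.3)), 60L)
  # sort-based oracle with tie-break by loop order
  set.seed(6)
  acc <- sample(seq(0, 1, by = 0.05), 40, replace = TRUE)
  got <- select_qualified_loops(acc, 0.25)
  ord <- order(-acc, seq_along(acc))
  expect_equal(got, sort(ord[1:10]))
  # minimum precision filter, with fallback to the single best
  expect_equal(select_qualified_loops(c(.9, .4, .95, .2), 1,
                                      min_precision = 0.5), c(1L, 3L))
  expect_warning(
    got2 <- select_qualified_loops(c(.3, .4), 1, min_precision = 0.99),
    "single best")
  expect_equal(got2, 2L)
})

test_that("vote rates match the brute-force nested-loop oracles", {
  set.seed(7)
  nc <- 12; ns <- 3; n_sel <- 3
  score_mats <- lapply(1:ns, function(i) {
    nk <- sample(4:6, 1)
    matrix(round(runif(nc * nk), 2) * rbinom(nc * nk, 1, 0.6), nc, nk)
  })
  phiC <- cluster_vote_rate(score_mats, n_sel)
  expect_equal(phiC, oracle_cluster_vote(score_mats, n_sel))
  # entries are exact multiples of 1/n_subjects, support bounded
  expect_true(all(abs(phiC * ns - round(phiC * ns)) < 1e-12))
  expect_lte(sum(phiC > 0), n_sel * ns)

  # voxel vote rate vs indicator-sum oracle
  labels <- sample(1:nc, 40, replace = TRUE)
  p <- parcellation(c(labels, 1:nc), nc)  # ensure non-empty clusters
  nv <- length(p$labels)
  nk <- 5
  sampled <- lapply(1:nk, function(k) sort(sample(nv, 18)))
  sels <- lapply(1:nk, function(k)
    top_n_selector(runif(nc) * rbinom(nc, 1, 0.7), n_sel))
  vv <- voxel_vote_rate(sampled, sels, p)
  expect_equal(vv, oracle_voxel_vote(sampled, sels, p$labels))

  # EVR is the per-voxel product and bounded by both factors
  phiC2 <- phiC[seq_len(nc)]
  evr <- effective_vote_ratio(vv, phiC2, p)
  expect_equal(evr, vv * phiC2[p$labels])
  expect_true(all(evr >= 0 & evr <= vv + 1e-15 & evr <= 1))
  expect_true(all(evr <= phiC2[p$labels] + 1e-15))
  # direct product example: 0.8 * 2/3
  expect_equal(effective_vote_ratio(0.8, 2 / 3, parcellation(1L, 1L)),
               0.8 * 2 / 3)
})

test_that("simple vote-rate cases behave as the formulas dictate", {
  # all subjects always select the same clusters -> those rates are 1
  s <- matrix(0, 6, 4); s[c(2, 5), ] <- 1
  phiC <- cluster_vote_rate(list(s, s, s), 2)
  expect_equal(phiC, c(0, 1, 0, 0, 1, 0))
  # a single subject gives a binary vector with at most n_sel ones
  one <- cluster_vote_rate(list(matrix(runif(24), 6, 4)), 2)
  expect_true(all(one %in% c(0, 1)) && sum(one) <= 2)
  # sampled twice, selected once -> 1/2; always-selected cluster -> 1
  p <- parcellation(c(1, 2), 2)
  vv <- voxel_vote_rate(list(1:2, 1:2), list(c(1, 1), c(0, 1)), p)
  expect_equal(vv, c(0.5, 1.0))
  # cluster vote 0 zeroes its voxels' EVR
  expect_equal(effective_vote_ratio(c(1, 1), c(0, 1), p), c(0, 1))
})

test_that("the full run is deterministic and finds the separating cluster", {
  ds <- generate_dataset(toy_spec(n_subjects = 3, seed = 21))
  cfg <- shv_config(n_k = 4, n_l = 2, alpha_col = 0.3, alpha_row = 0.8,
                    alpha_k = 0.5, n_sel = 3, seed = 7,
                    block_size = c(2L, 2L, 2L))
  r1 <- run_shv(ds$subjects, ds$mask, ds$parcellation_truth, cfg, lambda = 2)
  r2 <- run_shv(ds$subjects, ds$mask, ds$parcellation_truth, cfg, lambda = 2)
  expect_identical(r1$cluster_votes, r2$cluster_votes)
  expect_identical(r1$evr, r2$evr)
  expect_identical(r1$test_acc, r2$test_acc)
  # EVR never exceeds its factors anywhere
  for (i in 1:3) {
    expect_true(all(r1$evr[, i] <= r1$voxel_votes[, i] + 1e-15))
    expect_true(all(r1$evr[, i] <=
                      r1$cluster_votes[ds$parcellation_truth$labels] + 1e-15))
  }
})

test_that("a noiseless two-cluster toy votes only for the signal cluster", {
  # cluster 1 carries the label, cluster 2 is noise
  set.seed(22)
  arr <- array(TRUE, c(4, 3, 1))
  mask <- voxel_mask(arr)
  p <- parcellation(rep(c(1, 2), each = 6), 2)
  subs <- lapply(1:2, function(i) {
    y <- rep(c(1, -1), each = 8)
    X <- cbind(matrix(y + rnorm(16 * 6, sd = 0.05), 16, 6),
               matrix(rnorm(16 * 6), 16, 6))
    subject_features(X, y, paste0("s", i))
  })
  cfg <- shv_config(n_k = 1, n_l = 1, alpha_col = 0.9, alpha_row = 0.75,
                    alpha_k = 1, n_sel = 1, seed = 5,
                    block_size = c(2L, 2L, 1L))
  res <- run_shv(subs, mask, p, cfg, lambda = 0.5)
  expect_true(all(res$evr[p$labels == 2, ] == 0))
  expect_gt(max(res$evr[p$labels == 1, ]), 0)
})

test_that("penalty selection maximizes qualified accuracy, ties to sparser", {
  ds <- generate_dataset(toy_spec(n_subjects = 2, seed = 23))
  cfg <- shv_config(n_k = 3, n_l = 2, alpha_col = 0.4, alpha_row = 0.8,
                    alpha_k = 1, n_sel = 2, seed = 9,
                    block_size = c(2L, 2L, 2L))
  # single candidate: returned as-is
  cfg$lambda_grid <- 1.5
  sel1 <- select_lambda(ds$subjects, ds$mask, ds$parcellation_truth, cfg)
  expect_equal(sel1$lambda, 1.5)
  # tiny vs enormous penalty: the informative model wins
  feats <- lapply(ds$subjects, average_features,
                  parcellation = ds$parcellation_truth)
  lmax <- lambda_max(feats, lapply(ds$subjects, `[[`, "y"))
  cfg$lambda_grid <- c(0.05 * lmax, 10 * lmax)
  sel2 <- select_lambda(ds$subjects, ds$mask, ds$parcellation_truth, cfg)
  expect_equal(sel2$lambda, 0.05 * lmax)
  # the reported criterion equals an independent re-average of test_acc
  res <- sel2$result
  rbar <- mean(vapply(seq_len(res$n_subjects), function(i)
    mean(res$test_acc[i, res$qualified_loops[[i]]]), 0))
  expect_equal(dplyr::filter(sel2$r_bar, lambda == sel2$lambda)$r_bar, rbar)
})
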