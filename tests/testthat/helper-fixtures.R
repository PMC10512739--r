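# Small fixtures built in code.

# a desk-toy planted benchmark: 8x8x4 grid, 8 regions, 3 planted
toy_spec <- function(n_subjects = 3L, n_trials_per_class = 10L, seed = 1L,
                     noise_sd = 1.0) {
  synthetic_spec("reduced",
                 grid_shape = c(8L, 8L, 4L), n_regions = 8L,
                 discriminative_regions = c(1L, 2L, 3L),
                 n_interference = 2L, interference_base = 4L,
                 interference_step = 1L,
                 n_subjects = n_subjects,
                 n_trials_per_class = n_trials_per_class,
                 noise_sd = noise_sd, seed = seed)
}

# random non-separable logistic instance
random_instance <- function(n_subjects = 2L, n_trials = 30L,
                            n_clusters = 8L, seed = 1L, sd_noise = 2) {
  set.seed(seed)
  D <- lapply(seq_len(n_subjects), function(i)
    matrix(rnorm(n_trials * n_clusters), n_trials, n_clusters))
  w <- c(1.5, -1, rep(0, n_clusters - 2L))
  y <- lapply(D, function(d) {
    lab <- sign(drop(d %*% w) + rnorm(n_trials, sd = sd_noise))
    lab[lab == 0] <- 1
    # guarantee both classes
    if (all(lab == 1)) lab[1] <- -1
    if (all(lab == -1)) lab[1] <- 1
    lab
  })
  list(D = D, y = y)
}
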