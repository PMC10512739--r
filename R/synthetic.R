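#' Specification of the planted-signal synthetic benchmark
#'
#' Parameterizes a multi-subject benchmark with known ground truth:
#' a 3D grid partitioned into atlas-like regions; three discriminative
#' regions shared by all subjects whose base values combine linearly
#' into the class signal; per-subject interference regions whose base
#' values correlate with the labels only weakly; and additive Gaussian
#' noise.
#'
#' At full scale the defaults mirror a whole-brain study: a
#' 53 x 63 x 52 grid (173,628 voxels) partitioned into 116 regions,
#' discriminative regions \{32, 44, 62\} with initial weights
#' \{1, 1, -2\}, 15 interference regions per subject (subject `i` gets
#' regions `72+3i` through `86+3i`), subject weight scalings drawn from
#' U(0.5, 1.5), 20 trials per class and unit noise. `scale = "reduced"`
#' is the same design at desk scale: a 20 x 22 x 20 grid, 40 regions
#' (about 220 voxels each), discriminative regions \{11, 15, 21\}, 5
#' interference regions per subject (`24+i` through `28+i`).
#'
#' For class +1 the discriminative signal \eqn{y_1 = \sum_j W_j M_j}
#' falls in the top `label_quantile_discr` of its unconditional
#' distribution and for class -1 in the bottom; each interference
#' region's base value falls in the top (resp. bottom)
#' `label_quantile_interf` of U(0, 1).
#'
#' @param scale `"full"` or `"reduced"`.
#' @param ... Named overrides of any field.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(scale = c("full", "reduced"), ...) {
  scale <- match.arg(scale)
  spec <- if (scale == "full") {
    list(grid_shape = c(53L, 63L, 52L), n_regions = 116L,
         discriminative_regions = c(32L, 44L, 62L),
         init_weights = c(1, 1, -2),
         n_interference = 15L, interference_base = 72L,
         interference_step = 3L)
  } else {
    list(grid_shape = c(20L, 22L, 20L), n_regions = 40L,
         discriminative_regions = c(11L, 15L, 21L),
         init_weights = c(1, 1, -2),
         n_interference = 5L, interference_base = 24L,
         interference_step = 1L)
  }
  spec <- c(spec,
            list(alpha_range = c(0.5, 1.5), n_subjects = 9L,
                 n_trials_per_class = 20L,
                 label_quantile_discr = 0.40,
                 label_quantile_interf = 0.80,
                 noise_sd = 1.0, n_pilot = 1e5L, max_draws = 1e6,
                 seed = 1L, scale = scale))
  override <- list(...)
  bad <- setdiff(names(override), names(spec))
  if (length(bad)) stop("unknown spec field(s): ", paste(bad, collapse = ", "))
  spec[names(override)] <- override
  validate_synthetic_spec(structure(spec, class = "synthetic_spec"))
}

validate_synthetic_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 1L),
            spec$n_regions >= 1L,
            length(spec$discriminative_regions) == length(spec$init_weights),
            spec$label_quantile_discr > 0, spec$label_quantile_discr <= 0.5,
            spec$label_quantile_interf > 0, spec$label_quantile_interf <= 1,
            spec$alpha_range[1] <= spec$alpha_range[2],
            spec$n_subjects >= 1L, spec$n_trials_per_class >= 1L,
            spec$noise_sd >= 0, all(is.finite(spec$init_weights)))
  for (i in seq_len(spec$n_subjects)) {
    g0 <- interference_regions(spec, i)
    if (any(g0 < 1L) || any(g0 > spec$n_regions))
      stop("interference rule yields region ids outside 1..n_regions ",
           "for subject ", i)
    if (length(intersect(g0, spec$discriminative_regions)))
      stop("interference and discriminative regions overlap for subject ", i)
  }
  spec
}

#' Interference region ids for one subject
#'
#' Subject `i` receives `n_interference` consecutive region ids starting
#' at `interference_base + interference_step * i`, so neighbouring
#' subjects' interference sets overlap but are not identical.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_index Subject number (1-based).
#' @export
interference_regions <- function(spec, subject_index) {
  start <- spec$interference_base + spec$interference_step * subject_index
  seq.int(start, start + spec$n_interference - 1L)
}

#' Contiguous space-filling region map
#'
#' Partitions a full 3D grid into `n_regions` contiguous regions by
#' balanced multi-source region growing from spread-out seed voxels
#' (greedy max-min seeding from a random candidate pool, then repeated
#' growth of the currently smallest region). Region sizes stay within
#' roughly +-50% of the mean. Deterministic given `seed`.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param n_regions Number of regions (at most the voxel count).
#' @param seed Integer seed.
#' @return Integer 3D array of region labels `1..n_regions`.
#' @export
make_region_map <- function(grid_shape, n_regions, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  nv <- prod(grid_shape)
  if (n_regions > nv) stop("`n_regions` exceeds the number of voxels")
  if (n_regions == 1L) return(array(1L, dim = grid_shape))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  coords <- arrayInd(seq_len(nv), .dim = grid_shape)
  # greedy max-min seed spreading over a random candidate pool
  pool <- sample(nv, min(nv, 50L * n_regions))
  seeds <- pool[1]
  dmin <- colSums((t(coords[pool, , drop = FALSE]) - coords[seeds, ])^2)
  while (length(seeds) < n_regions) {
    nxt <- pool[which.max(dmin)]
    seeds <- c(seeds, nxt)
    d2 <- colSums((t(coords[pool, , drop = FALSE]) - coords[nxt, ])^2)
    dmin <- pmin(dmin, d2)
  }

  labels <- integer(nv)
  labels[seeds] <- seq_len(n_regions)
  sizes <- rep(1L, n_regions)
  # 6-connected neighbour linear offsets with bounds checks via coords
  frontiers <- lapply(seq_len(n_regions), function(r)
    neighbor_ids(seeds[r], coords, grid_shape))
  n_assigned <- n_regions
  while (n_assigned < nv) {
    active <- which(lengths(frontiers) > 0L)
    if (length(active) == 0L) {
      # grid exhausted around current frontiers (cannot happen on a full
      # grid, kept as a safety net): assign leftovers to nearest seed
      left <- which(labels == 0L)
      for (v in left) {
        d2 <- colSums((t(coords[seeds, , drop = FALSE]) - coords[v, ])^2)
        labels[v] <- which.min(d2)
      }
      break
    }
    r <- active[which.min(sizes[active])]
    fr <- frontiers[[r]]
    v <- fr[1]
    frontiers[[r]] <- fr[-1]
    if (labels[v] == 0L) {
      labels[v] <- r
      sizes[r] <- sizes[r] + 1L
      n_assigned <- n_assigned + 1L
      nb <- neighbor_ids(v, coords, grid_shape)
      frontiers[[r]] <- c(frontiers[[r]], nb[labels[nb] == 0L])
    }
  }
  array(labels, dim = grid_shape)
}

neighbor_ids <- function(v, coords, shape) {
  p <- coords[v, ]
  out <- integer(0)
  if (p[1] > 1L) out <- c(out, v - 1L)
  if (p[1] < shape[1]) out <- c(out, v + 1L)
  if (p[2] > 1L) out <- c(out, v - shape[1])
  if (p[2] < shape[2]) out <- c(out, v + shape[1])
  sl <- shape[1] * shape[2]
  if (p[3] > 1L) out <- c(out, v - sl)
  if (p[3] < shape[3]) out <- c(out, v + sl)
  out
}

# draw one subject's region base values for n trials of one class.
# y1 rejection-samples against pilot quantiles; interference regions are
# truncated-uniform draws (their acceptance regions are exact U(0,1)
# quantiles, so this is distributionally identical to rejection).
draw_class_trials <- function(n, class_sign, weights, q_lo, q_hi,
                              interf_ids, q_interf, max_draws) {
  ng <- length(weights)
  M_disc <- matrix(0, nrow = n, ncol = ng)
  draws <- 0
  for (t in seq_len(n)) {
    repeat {
      draws <- draws + 1
      if (draws > max_draws)
        stop("rejection sampling exceeded ", max_draws,
             " draws; check the label quantiles")
      m <- runif(ng)
      y1 <- sum(weights * m)
      ok <- if (class_sign > 0) y1 >= q_hi else y1 <= q_lo
      if (ok) { M_disc[t, ] <- m; break }
    }
  }
  ni <- length(interf_ids)
  M_interf <- if (class_sign > 0) {
    matrix(runif(n * ni, min = 1 - q_interf, max = 1), nrow = n)
  } else {
    matrix(runif(n * ni, min = 0, max = q_interf), nrow = n)
  }
  list(disc = M_disc, interf = M_interf)
}

#' Generate one synthetic subject
#'
#' Draws the subject's personalized weight scalings, rejection-samples
#' per-trial region base values so the class conditions hold (class +1:
#' the discriminative combination \eqn{y_1} in its top
#' `label_quantile_discr`; class -1: in the bottom; interference base
#' values in the top/bottom `label_quantile_interf` of U(0,1)), assigns
#' each region's base value to all of its voxels, and adds independent
#' N(0, `noise_sd`^2) noise everywhere (non-region voxels are pure
#' noise). Trials are exactly balanced.
#'
#' Uses the current RNG state; [generate_dataset()] manages seeding.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_index Subject number (1-based).
#' @param region_map Integer 3D array from [make_region_map()].
#' @return List with `subject` (a [subject_features()]) and `truth`
#'   (realized scalings, weights and interference region ids).
#' @export
generate_subject <- function(spec, subject_index, region_map) {
  g1 <- spec$discriminative_regions
  g0 <- interference_regions(spec, subject_index)
  alpha <- runif(length(g1), spec$alpha_range[1], spec$alpha_range[2])
  weights <- spec$init_weights * alpha

  # pilot Monte-Carlo quantiles of the unconditional y1 distribution
  pm <- matrix(runif(spec$n_pilot * length(g1)), ncol = length(g1))
  y1_pilot <- drop(pm %*% weights)
  q <- quantile(y1_pilot, c(spec$label_quantile_discr,
                            1 - spec$label_quantile_discr), names = FALSE)

  npc <- spec$n_trials_per_class
  pos <- draw_class_trials(npc, +1, weights, q[1], q[2], g0,
                           spec$label_quantile_interf, spec$max_draws)
  neg <- draw_class_trials(npc, -1, weights, q[1], q[2], g0,
                           spec$label_quantile_interf, spec$max_draws)

  nv <- prod(spec$grid_shape)
  n_t <- 2L * npc
  X <- matrix(rnorm(n_t * nv, sd = spec$noise_sd), nrow = n_t)
  region_vox <- lapply(c(g1, g0), function(r) which(region_map == r))
  M_all <- cbind(rbind(pos$disc, neg$disc), rbind(pos$interf, neg$interf))
  for (jj in seq_along(region_vox)) {
    vox <- region_vox[[jj]]
    X[, vox] <- X[, vox] + M_all[, jj]
  }
  y <- rep(c(1, -1), each = npc)
  list(subject = subject_features(X, y,
                                  subject_id = paste0("s", subject_index)),
       truth = list(alpha = alpha, weights = weights,
                    interference_regions = g0,
                    y1_quantiles = q))
}

#' Generate the full multi-subject synthetic benchmark
#'
#' Builds the region map, then generates every subject: all subjects
#' share the same discriminative regions but have their own weight
#' scalings and their own interference region sets. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset` with `subjects` (list of
#'   [subject_features()]), `mask` (full-grid [voxel_mask()]),
#'   `parcellation_truth` (the region map as a [parcellation()]),
#'   `region_map`, `truth` (per-subject realized parameters plus the
#'   planted region ids) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)
  map_seed <- sample.int(.Machine$integer.max, 1)
  region_map <- make_region_map(spec$grid_shape, spec$n_regions,
                                seed = map_seed)
  subjects <- vector("list", spec$n_subjects)
  truths <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    g <- generate_subject(spec, i, region_map)
    subjects[[i]] <- g$subject
    truths[[i]] <- g$truth
  }
  mask <- voxel_mask(spec$grid_shape)
  structure(
    list(subjects = subjects, mask = mask,
         parcellation_truth = parcellation(as.vector(region_map),
                                           spec$n_regions),
         region_map = region_map,
         truth = list(discriminative_regions = spec$discriminative_regions,
                      subjects = truths),
         spec = spec),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %s scale: %d subjects, grid %s ",
                     "(%d voxels, %d regions), planted regions {%s}\n"),
              x$spec$scale, length(x$subjects),
              paste(x$spec$grid_shape, collapse = "x"),
              x$mask$n_voxels, x$spec$n_regions,
              paste(x$spec$discriminative_regions, collapse = ", ")))
  invisible(x)
}
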