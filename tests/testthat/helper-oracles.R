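# Independent oracles used to cross-check the implementation.

# plain proximal-gradient (ISTA) solver for the mixed l1/l2 logistic
# objective, with its own objective/gradient code and the textbook
# backtracking majorization condition; no acceleration, run to a very
# tight tolerance. Deliberately shares no code with the package solver.
oracle_objective <- function(W, b, D_list, y_list, lambda) {
  f <- 0
  for (i in seq_along(D_list)) {
    m <- y_list[[i]] * (drop(D_list[[i]] %*% W[, i]) + b[i])
    f <- f + sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
  }
  f + lambda * sum(sqrt(rowSums(W^2)))
}

oracle_ista <- function(D_list, y_list, lambda, iters = 50000,
                        tol = 1e-13) {
  S <- length(D_list)
  C <- ncol(D_list[[1]])
  W <- matrix(0, C, S)
  b <- vapply(y_list, function(y) log(sum(y > 0) / sum(y < 0)), 0)
  smooth_f <- function(W, b) {
    f <- 0
    for (i in seq_len(S)) {
      m <- y_list[[i]] * (drop(D_list[[i]] %*% W[, i]) + b[i])
      f <- f + sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m))))
    }
    f
  }
  prox_rows <- function(W, thr) {
    nrm <- sqrt(rowSums(W^2))
    sc <- ifelse(nrm <= thr, 0, 1 - thr / nrm)
    W * sc
  }
  L <- 1
  Fx <- oracle_objective(W, b, D_list, y_list, lambda)
  for (it in seq_len(iters)) {
    gW <- matrix(0, C, S)
    gb <- numeric(S)
    for (i in seq_len(S)) {
      m <- y_list[[i]] * (drop(D_list[[i]] %*% W[, i]) + b[i])
      r <- -y_list[[i]] / (1 + exp(m))
      gW[, i] <- drop(crossprod(D_list[[i]], r))
      gb[i] <- sum(r)
    }
    fz <- smooth_f(W, b)
    repeat {
      Wn <- prox_rows(W - gW / L, lambda / L)
      bn <- b - gb / L
      fn <- smooth_f(Wn, bn)
      q <- fz + sum(gW * (Wn - W)) + sum(gb * (bn - b)) +
        L / 2 * (sum((Wn - W)^2) + sum((bn - b)^2))
      if (fn <= q + 1e-12 * abs(q)) break
      L <- L * 2
    }
    Fn <- fn + lambda * sum(sqrt(rowSums(Wn^2)))
    done <- it > 200 && abs(Fx - Fn) <= tol * max(1, abs(Fx))
    W <- Wn; b <- bn; Fx <- Fn
    if (done) break
  }
  list(W = W, b = b, objective = Fx)
}

# brute-force hierarchical vote rate (Eq.-by-the-book nested loops)
oracle_selector <- function(s, n_sel) {
  sel <- numeric(length(s))
  pos <- which(s > 0)
  if (length(pos) == 0) return(sel)
  ord <- pos[order(-s[pos], pos)]
  sel[ord[seq_len(min(n_sel, length(ord)))]] <- 1
  sel
}

oracle_cluster_vote <- function(score_mats, n_sel) {
  ns <- length(score_mats)
  nc <- nrow(score_mats[[1]])
  total <- numeric(nc)
  for (i in seq_len(ns)) {
    S <- score_mats[[i]]
    freq <- numeric(nc)
    for (k in seq_len(ncol(S))) freq <- freq + oracle_selector(S[, k], n_sel)
    freq <- freq / ncol(S)
    total <- total + oracle_selector(freq, n_sel)
  }
  total / ns
}

oracle_voxel_vote <- function(sampled_sets, selectors, labels) {
  nv <- length(labels)
  out <- numeric(nv)
  for (m in seq_len(nv)) {
    num <- den <- 0
    for (k in seq_along(sampled_sets)) {
      if (m %in% sampled_sets[[k]]) {
        den <- den + 1
        if (selectors[[k]][labels[m]] == 1) num <- num + 1
      }
    }
    out[m] <- if (den > 0) num / den else 0
  }
  out
}
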