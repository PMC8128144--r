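# Fixture builders and independent naive oracles used across the suite.
# Oracles are literal, loop-level transcriptions of the method definitions,
# kept deliberately separate from the package's vectorized implementations.

# random binary network + symmetric unit-diagonal similarities
rand_instance <- function(seed, m = 6L, n = 5L, density = 0.3) {
  withr::with_seed(seed, {
    Y <- matrix(rbinom(m * n, 1L, density), m, n)
    if (sum(Y) == 0L) Y[sample(m * n, 2L)] <- 1L
    Sr <- rand_input_sim(m)
    Sd <- rand_input_sim(n)
    list(net = cmaf::dd_network(Y, paste0("dr", seq_len(m)),
                                paste0("di", seq_len(n))),
         S_r = cmaf::sim_matrix(Sr, paste0("dr", seq_len(m))),
         S_d = cmaf::sim_matrix(Sd, paste0("di", seq_len(n))))
  })
}

rand_input_sim <- function(p) {
  S <- matrix(runif(p * p), p, p)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# random row-stochastic zero-diagonal similarity (learned-graph shape)
rand_lns_sim <- function(p, ids = paste0("e", seq_len(p))) {
  S <- matrix(runif(p * p), p, p)
  diag(S) <- 0
  S <- S / rowSums(S)
  cmaf::sim_matrix(S, ids, kind = "linear_neighborhood")
}

# literal triple-loop WKNKN: per-entity neighbor search, per-rank decay
# weights, elementwise average and max
naive_wknkn <- function(Y, Sr, Sd, K = 5L, T = 0.5) {
  m <- nrow(Y); n <- ncol(Y)
  known_r <- which(rowSums(Y) > 0)
  known_d <- which(colSums(Y) > 0)
  Yr <- matrix(0, m, n)
  for (p in seq_len(m)) {
    cand <- setdiff(known_r, p)
    if (!length(cand)) next
    cand <- cand[order(-Sr[cand, p], cand)]
    cand <- cand[seq_len(min(K, length(cand)))]
    Q <- 0; acc <- numeric(n)
    for (i in seq_along(cand)) {
      s <- Sr[cand[i], p]
      acc <- acc + T^(i - 1) * s * Y[cand[i], ]
      Q <- Q + s
    }
    if (Q > 0) Yr[p, ] <- acc / Q
  }
  Yd <- matrix(0, m, n)
  for (q in seq_len(n)) {
    cand <- setdiff(known_d, q)
    if (!length(cand)) next
    cand <- cand[order(-Sd[cand, q], cand)]
    cand <- cand[seq_len(min(K, length(cand)))]
    Q <- 0; acc <- numeric(m)
    for (j in seq_along(cand)) {
      s <- Sd[cand[j], q]
      acc <- acc + T^(j - 1) * s * Y[, cand[j]]
      Q <- Q + s
    }
    if (Q > 0) Yd[, q] <- acc / Q
  }
  unname(pmax(Y, (Yr + Yd) / 2))
}

# literal per-pair network consistency projection
naive_ncp <- function(Y, Sr, Sd) {
  Yp <- Y
  Yp[Yp == 0] <- 1e-30
  m <- nrow(Y); n <- ncol(Y)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      ncp_r <- sum(Sr[i, ] * Yp[, j]) / sqrt(sum(Yp[, j]^2))
      ncp_d <- sum(Yp[i, ] * Sd[, j]) / sqrt(sum(Yp[i, ]^2))
      out[i, j] <- (ncp_r + ncp_d) /
        (sqrt(sum(Sr[i, ]^2)) + sqrt(sum(Sd[, j]^2)))
    }
  }
  out
}

# two-sided label propagation by naive fixed-point iteration
naive_lpria <- function(Y, Sr, Sd, alpha = 0.5, iters = 5000L) {
  iterate <- function(S, Y0) {
    Yt <- Y0
    for (i in seq_len(iters)) Yt <- alpha * S %*% Yt + (1 - alpha) * Y0
    Yt
  }
  (iterate(Sr, Y) + t(iterate(Sd, t(Y)))) / 2
}

# pairwise Mann-Whitney AUC with half credit for ties
mw_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# direct evaluation of the regularized NMF objective with symmetrized graphs
nmf_obj_direct <- function(Y, W, H, Ssym_r, Ssym_d, ll, lr, ld) {
  Lr <- diag(rowSums(Ssym_r)) - Ssym_r
  Ld <- diag(rowSums(Ssym_d)) - Ssym_d
  sum((Y - W %*% t(H))^2) + ll * (sum(W^2) + sum(H^2)) +
    lr * sum(diag(t(W) %*% Lr %*% W)) + ld * sum(diag(t(H) %*% Ld %*% H))
}

expect_tibble_names <- function(x, nms) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(nms %in% names(x)))
}
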