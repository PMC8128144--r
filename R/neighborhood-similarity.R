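# Linear neighborhood similarity learning.
#
# Each entity is reconstructed linearly from its K nearest neighbors in
# feature space; the reconstruction weights, constrained to the probability
# simplex and ridge-regularized, are found by quadratic programming and
# assembled row-wise into a directed similarity matrix.

#' Parameters for linear neighborhood similarity learning
#'
#' @param K neighborhood size (default 100); capped at `p - 1` entities when
#'   the dataset is smaller.
#' @param lambda ridge regularization weight (default 1).
#' @return A list of class `lns_params`.
#' @export
lns_params <- function(K = 100L, lambda = 1) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) {
    stop_cmaf("value", "K must be a positive integer")
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop_cmaf("value", "lambda must be non-negative")
  }
  structure(list(K = K, lambda = lambda), class = "lns_params")
}

#' Neighborhood Gram matrix of displacement inner products
#'
#' `G[j, l] = (x_i - x_j) . (x_i - x_l)` for the query feature vector `x_i`
#' and its K neighbor vectors: symmetric and positive semidefinite by
#' construction.
#'
#' @param x_i numeric feature vector of the query entity.
#' @param X_nbrs K x q matrix whose rows are the neighbors' feature vectors.
#' @return A K x K matrix.
#' @export
neighborhood_gram <- function(x_i, X_nbrs) {
  X_nbrs <- rbind(X_nbrs)
  if (ncol(X_nbrs) != length(x_i)) {
    stop_cmaf("shape", "neighbor features must match the query dimension")
  }
  D <- sweep(-X_nbrs, 2L, -x_i)  # row j = x_i - x_j
  tcrossprod(D)
}

#' Reconstruction weights on the probability simplex
#'
#' Minimizes `w' (G + lambda I) w` subject to `sum(w) = 1, w >= 0` by dual
#' active-set quadratic programming. For `lambda = 0` with singular `G` a
#' vanishing ridge is added so a feasible minimizer is always returned (the
#' optimum may be non-unique; only the objective is then meaningful).
#'
#' @param G_i K x K positive semidefinite Gram matrix from
#'   [neighborhood_gram()].
#' @param lambda ridge weight, >= 0.
#' @return A list with `weights` (length K, non-negative, summing to 1) and
#'   `objective` (the attained value of `w' (G + lambda I) w`).
#' @export
solve_neighbor_weights <- function(G_i, lambda = 1) {
  G_i <- rbind(G_i)
  K <- nrow(G_i)
  if (K == 1L) {
    return(list(weights = 1, objective = as.numeric(G_i[1L, 1L] + lambda)))
  }
  Q <- (G_i + t(G_i)) / 2 + diag(lambda, K)
  Amat <- cbind(rep(1, K), diag(K))
  bvec <- c(1, rep(0, K))
  sol <- NULL
  ridge <- 0
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = 2 * (Q + diag(ridge, K)), dvec = rep(0, K),
                         Amat = Amat, bvec = bvec, meq = 1L),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- if (ridge == 0) 1e-10 else ridge * 100
  }
  if (is.null(sol)) {
    stop_cmaf("numerical", "quadratic program for neighborhood weights failed")
  }
  w <- sol$solution
  if (any(w < -1e-10 - 1e-8)) {
    stop_cmaf("numerical", "QP returned infeasible weights")
  }
  w[w < 0] <- 0
  w <- w / sum(w)
  list(weights = w, objective = as.numeric(w %*% Q %*% w))
}

#' Learn a linear neighborhood similarity matrix
#'
#' For each entity, the K nearest neighbors by Euclidean distance in feature
#' space (self excluded, ties by ascending index) are found, the simplex-
#' constrained reconstruction QP is solved, and the weights are scattered
#' into the entity's row. The result is a directed similarity matrix whose
#' rows are probability vectors supported on at most K entries with zero
#' diagonal; it is used as produced, without symmetrization.
#'
#' @param X p x q feature matrix, one row per entity. In the association
#'   pipeline the features are the rows (drugs) or columns (diseases) of the
#'   WKNKN-completed association matrix.
#' @param params an [lns_params()]; `K` is capped at `p - 1`.
#' @param ids entity identifiers (default: rownames of `X`).
#' @return A [sim_matrix()] of kind `"linear_neighborhood"`.
#' @export
linear_neighborhood_similarity <- function(X, params = lns_params(),
                                           ids = rownames(X)) {
  X <- as.matrix(X)
  p <- nrow(X)
  if (p < 2L) stop_cmaf("value", "need at least 2 entities to learn neighborhoods")
  if (is.null(ids)) ids <- paste0("e", seq_len(p))
  K <- min(params$K, p - 1L)
  # squared Euclidean distances between all entity pairs
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  S <- matrix(0, p, p)
  for (i in seq_len(p)) {
    d <- D2[i, ]
    cand <- setdiff(seq_len(p), i)
    nbrs <- cand[order(d[cand], cand)][seq_len(K)]
    G <- neighborhood_gram(X[i, ], X[nbrs, , drop = FALSE])
    fit <- solve_neighbor_weights(G, params$lambda)
    S[i, nbrs] <- fit$weights
  }
  sim_matrix(S, ids = ids, kind = "linear_neighborhood")
}
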