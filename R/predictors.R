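# The three base predictors: label propagation (LPRIA), graph-regularized
# non-negative matrix factorization (NMFRIA), and network consistency
# projection (NCPRIA). All consume the WKNKN-completed association matrix and
# the learned linear neighborhood similarities.

#' Label propagation parameters
#'
#' @param alpha absorption probability in `(0, 1)`: at each step a node keeps
#'   its initial label with weight `1 - alpha` and absorbs its neighbors'
#'   labels with weight `alpha` (default 0.5).
#' @param mode `"closed_form"` solves the stationary system directly;
#'   `"iterative"` runs the diffusion to convergence (kept mainly as an
#'   independent check of the closed form).
#' @param tol,max_iter iterative-mode stopping rule (max-abs change).
#' @return A list of class `lp_params`.
#' @export
lp_params <- function(alpha = 0.5, mode = c("closed_form", "iterative"),
                      tol = 1e-10, max_iter = 10000L) {
  mode <- match.arg(mode)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_cmaf("value", "alpha must lie strictly in (0, 1)")
  }
  structure(list(alpha = alpha, mode = mode, tol = tol,
                 max_iter = as.integer(max_iter)), class = "lp_params")
}

#' Propagate labels over a row-stochastic similarity graph
#'
#' Computes the stationary point of `Y_{t+1} = alpha S Y_t + (1 - alpha) Y_0`,
#' i.e. `(1 - alpha) (I - alpha S)^{-1} Y_0`, via a linear solve (closed form)
#' or by iterating the diffusion. With `alpha < 1` and row-stochastic `S` the
#' system is strictly diagonally dominant, hence nonsingular, and outputs stay
#' in `[0, 1]` whenever `Y_0` does.
#'
#' @param S row-stochastic similarity matrix (a `sim_matrix` of kind
#'   `"linear_neighborhood"`, or a bare matrix with rows summing to 1).
#' @param Y0 initial label matrix (rows aligned with `S`).
#' @param params an [lp_params()].
#' @return Matrix of propagated labels, same shape as `Y0`.
#' @export
label_propagation <- function(S, Y0, params = lp_params()) {
  Sm <- if (inherits(S, "sim_matrix")) S$S else as.matrix(S)
  Y0 <- as.matrix(Y0)
  if (nrow(Sm) != ncol(Sm) || nrow(Sm) != nrow(Y0)) {
    stop_cmaf("shape", "similarity is ", nrow(Sm), "x", ncol(Sm),
              " but labels have ", nrow(Y0), " rows")
  }
  a <- params$alpha
  if (params$mode == "closed_form") {
    A <- diag(nrow(Sm)) - a * Sm
    out <- tryCatch(solve(A, (1 - a) * Y0),
                    error = function(e) stop_cmaf("numerical",
                      "label propagation system is singular: ",
                      conditionMessage(e)))
  } else {
    Yt <- Y0
    base <- (1 - a) * Y0
    for (it in seq_len(params$max_iter)) {
      Ynext <- a * (Sm %*% Yt) + base
      if (max(abs(Ynext - Yt)) < params$tol) {
        Yt <- Ynext
        break
      }
      Yt <- Ynext
    }
    out <- Yt
  }
  dimnames(out) <- dimnames(Y0)
  out
}

#' Label-propagation association prediction (two-sided)
#'
#' Propagates the completed association matrix over the drug neighborhood
#' graph (column by column) and, transposed, over the disease neighborhood
#' graph, and averages the two propagated matrices.
#'
#' @param net_completed WKNKN-completed [dd_network()].
#' @param Sr_star,Sd_star learned linear-neighborhood [sim_matrix()] objects
#'   for drugs and diseases.
#' @param params an [lp_params()].
#' @return A [score_matrix()] with `source = "LPRIA"`, entries in `[0, 1]`.
#' @export
lpria_predict <- function(net_completed, Sr_star, Sd_star,
                          params = lp_params()) {
  Sr_star <- align_similarity(Sr_star, net_completed$drug_ids, "drug")
  Sd_star <- align_similarity(Sd_star, net_completed$disease_ids, "disease")
  Y <- net_completed$Y
  Yr <- label_propagation(Sr_star, Y, params)
  Yd <- t(label_propagation(Sd_star, t(Y), params))
  R <- (Yr + Yd) / 2
  R[R < 0] <- 0
  R[R > 1] <- 1
  score_matrix(R, net_completed$drug_ids, net_completed$disease_ids,
               source = "LPRIA")
}

#' Graph-regularized NMF parameters
#'
#' @param k latent dimension (default 100); capped at `min(m, n) - 1`.
#' @param lambda_l Tikhonov weight on both factors (default 2).
#' @param lambda_r,lambda_d graph-regularization weights for the drug and
#'   disease similarity Laplacians (default 1e-4 each).
#' @param max_iter maximum multiplicative-update sweeps (default 2000).
#' @param rel_tol relative objective-change stopping threshold (default 1e-6).
#' @param seed integer seed for the random uniform initialization.
#' @return A list of class `nmf_params`.
#' @export
nmf_params <- function(k = 100L, lambda_l = 2, lambda_r = 1e-4,
                       lambda_d = 1e-4, max_iter = 2000L, rel_tol = 1e-6,
                       seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_cmaf("value", "latent dimension k must be >= 1")
  for (lam in c(lambda_l, lambda_r, lambda_d)) {
    if (!is.finite(lam) || lam < 0) stop_cmaf("value", "lambdas must be >= 0")
  }
  structure(list(k = k, lambda_l = lambda_l, lambda_r = lambda_r,
                 lambda_d = lambda_d, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, seed = as.integer(seed)),
            class = "nmf_params")
}

# symmetrized graph pieces used by the NMF regularizer: the learned
# neighborhood similarities are directed, so S_sym = (S + S')/2 keeps the
# Laplacian quadratic form Tr(W' L W) well-defined and non-negative
graph_pieces <- function(S) {
  S_sym <- (S + t(S)) / 2
  D <- diag(rowSums(S_sym), nrow(S_sym))
  list(S = S_sym, D = D, L = D - S_sym)
}

nmf_objective <- function(Y, W, H, params, gr, gd) {
  sum((Y - tcrossprod(W, H))^2) +
    params$lambda_l * (sum(W^2) + sum(H^2)) +
    params$lambda_r * sum(diag(crossprod(W, gr$L %*% W))) +
    params$lambda_d * sum(diag(crossprod(H, gd$L %*% H)))
}

#' Fit graph-regularized non-negative matrix factorization
#'
#' Factorizes the completed association matrix as `Y ~ W H'` with
#' non-negative factors, Tikhonov penalties on both factors, and Laplacian
#' smoothness over the (symmetrized) drug and disease neighborhood graphs,
#' using multiplicative updates with a denominator floor of 1e-12 until the
#' relative objective change drops below `rel_tol` or `max_iter` sweeps.
#' Factors are initialized uniformly on `[0, sqrt(mean(Y)/k)]` from the
#' params seed so runs are reproducible and scale-matched to `Y`.
#'
#' @inheritParams lpria_predict
#' @param params an [nmf_params()].
#' @param W0,H0 optional explicit initial factors (overriding the random
#'   initialization); dimensions m x k and n x k.
#' @return A list of class `factor_pair`: `W`, `H`, `objective_trace`,
#'   `iterations`, `converged`, plus the ids and params.
#' @export
nmfria_fit <- function(net_completed, Sr_star, Sd_star, params = nmf_params(),
                       W0 = NULL, H0 = NULL) {
  Sr_star <- align_similarity(Sr_star, net_completed$drug_ids, "drug")
  Sd_star <- align_similarity(Sd_star, net_completed$disease_ids, "disease")
  Y <- net_completed$Y
  m <- nrow(Y); n <- ncol(Y)
  k <- min(params$k, min(m, n) - 1L)
  if (k < 1L) k <- 1L
  gr <- graph_pieces(Sr_star$S)
  gd <- graph_pieces(Sd_star$S)
  if (is.null(W0) || is.null(H0)) {
    lim <- sqrt(max(mean(Y), 1e-12) / k)
    init <- with_seed(params$seed, list(
      W = matrix(runif(m * k, 0, lim), m, k),
      H = matrix(runif(n * k, 0, lim), n, k)))
    if (is.null(W0)) W0 <- init$W
    if (is.null(H0)) H0 <- init$H
  }
  W <- W0; H <- H0
  if (any(W < 0) || any(H < 0)) stop_cmaf("value", "initial factors must be >= 0")
  floor_ <- 1e-12
  obj <- nmf_objective(Y, W, H, params, gr, gd)
  trace <- numeric(params$max_iter + 1L)
  trace[1L] <- obj
  it <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    num_w <- Y %*% H + params$lambda_r * (gr$S %*% W)
    den_w <- W %*% crossprod(H) + params$lambda_l * W +
      params$lambda_r * (gr$D %*% W)
    W <- W * num_w / pmax(den_w, floor_)
    num_h <- crossprod(Y, W) + params$lambda_d * (gd$S %*% H)
    den_h <- H %*% crossprod(W) + params$lambda_l * H +
      params$lambda_d * (gd$D %*% H)
    H <- H * num_h / pmax(den_h, floor_)
    obj_new <- nmf_objective(Y, W, H, params, gr, gd)
    if (!is.finite(obj_new)) stop_cmaf("numerical", "NMF objective became non-finite")
    trace[it + 1L] <- obj_new
    if (abs(obj - obj_new) <= params$rel_tol * max(obj, .Machine$double.eps)) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  rownames(W) <- net_completed$drug_ids
  rownames(H) <- net_completed$disease_ids
  structure(list(W = W, H = H, objective_trace = trace[seq_len(it + 1L)],
                 iterations = it, converged = converged,
                 drug_ids = net_completed$drug_ids,
                 disease_ids = net_completed$disease_ids,
                 params = params),
            class = "factor_pair")
}

#' @export
print.factor_pair <- function(x, ...) {
  cat("<factor_pair> ", nrow(x$W), "x", ncol(x$W), " W, ", nrow(x$H), "x",
      ncol(x$H), " H; ", x$iterations, " iterations, objective ",
      format(utils::tail(x$objective_trace, 1L), digits = 6),
      if (x$converged) " (converged)" else " (max_iter)", "\n", sep = "")
  invisible(x)
}

#' Reconstruct prediction scores from fitted NMF factors
#'
#' @param factors a `factor_pair` from [nmfria_fit()].
#' @return A [score_matrix()] with `source = "NMFRIA"`; entries are
#'   non-negative and may exceed 1 (clip with [clip_unit()] before fusion).
#' @export
nmfria_predict <- function(factors) {
  score_matrix(tcrossprod(factors$W, factors$H), factors$drug_ids,
               factors$disease_ids, source = "NMFRIA")
}

#' Network consistency projection prediction
#'
#' Exact zeros of the (completed) association matrix are replaced with 1e-30
#' so no projection denominator vanishes; then the drug-space projection
#' `NCP_R(i,j) = S_r(i,.) . Y(.,j) / ||Y(.,j)||` and disease-space projection
#' `NCP_D(i,j) = Y(i,.) . S_d(.,j) / ||Y(i,.)||` are fused as
#' `(NCP_R + NCP_D) / (||S_r(i,.)|| + ||S_d(.,j)||)`. With all matrices
#' non-negative, Cauchy-Schwarz keeps every score in `[0, 1]`.
#'
#' @inheritParams lpria_predict
#' @return A [score_matrix()] with `source = "NCPRIA"`.
#' @export
ncpria_predict <- function(net_completed, Sr_star, Sd_star) {
  Sr_star <- align_similarity(Sr_star, net_completed$drug_ids, "drug")
  Sd_star <- align_similarity(Sd_star, net_completed$disease_ids, "disease")
  Y <- net_completed$Y
  Y[Y == 0] <- 1e-30
  Sr <- Sr_star$S
  Sd <- Sd_star$S
  col_norm <- sqrt(colSums(Y^2))
  row_norm <- sqrt(rowSums(Y^2))
  sr_norm <- sqrt(rowSums(Sr^2))
  sd_norm <- sqrt(colSums(Sd^2))
  denom <- outer(sr_norm, sd_norm, "+")
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1L, ]
    stop_cmaf("value", "zero similarity norms for drug '",
              net_completed$drug_ids[bad[1L]], "' and disease '",
              net_completed$disease_ids[bad[2L]],
              "': projection undefined")
  }
  ncp_r <- sweep(Sr %*% Y, 2L, col_norm, "/")
  ncp_d <- sweep(Y %*% Sd, 1L, row_norm, "/")
  R <- (ncp_r + ncp_d) / denom
  R[R < 0] <- 0
  R[R > 1] <- 1
  score_matrix(R, net_completed$drug_ids, net_completed$disease_ids,
               source = "NCPRIA")
}
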