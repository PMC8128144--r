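# Weighted K-nearest-known-neighbor completion of the association matrix.
#
# Zero entries of the binary matrix Y are replaced by interaction-likelihood
# estimates built from the profiles of the K most similar *known* entities
# (entities with at least one recorded association), discounted geometrically
# by rank with decay T and normalized by the summed similarities.

#' Parameters for weighted K-nearest-known-neighbor completion
#'
#' @param K positive integer; number of known neighbors used (default 5).
#' @param T decay factor in `(0, 1]` applied as `T^(rank-1)` to neighbor
#'   weights (default 0.5).
#' @return A list of class `wknkn_params`.
#' @export
wknkn_params <- function(K = 5L, T = 0.5) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) {
    stop_cmaf("value", "K must be a positive integer")
  }
  if (length(T) != 1L || !is.finite(T) || T <= 0 || T > 1) {
    stop_cmaf("value", "decay T must lie in (0, 1]")
  }
  structure(list(K = K, T = T), class = "wknkn_params")
}

#' K nearest known neighbors of a drug or disease
#'
#' Returns up to `K` entities, excluding the query itself, restricted to
#' entities whose interaction profile has at least one nonzero entry
#' ("known" entities), ordered by similarity to the query descending with
#' ties broken by ascending index.
#'
#' @param entity_index 1-based index of the query entity on its axis.
#' @param S a [sim_matrix()] over that axis's vocabulary.
#' @param net a [dd_network()].
#' @param axis `"drug"` (rows of Y) or `"disease"` (columns).
#' @param K maximum number of neighbors.
#' @return A tibble with columns `index` and `similarity`, possibly empty.
#' @export
known_neighbors <- function(entity_index, S, net, axis = c("drug", "disease"),
                            K = 5L) {
  axis <- match.arg(axis)
  p <- if (axis == "drug") nrow(net$Y) else ncol(net$Y)
  if (entity_index < 1L || entity_index > p) {
    stop_cmaf("value", "entity_index ", entity_index, " out of range for ", axis)
  }
  known <- if (axis == "drug") rowSums(net$Y) > 0 else colSums(net$Y) > 0
  cand <- setdiff(which(known), entity_index)
  if (!length(cand)) {
    return(tibble::tibble(index = integer(), similarity = double()))
  }
  sims <- S$S[cand, entity_index]
  ord <- order(-sims, cand)
  keep <- ord[seq_len(min(K, length(cand)))]
  tibble::tibble(index = cand[keep], similarity = unname(sims[keep]))
}

#' Interaction-likelihood profile from ranked known neighbors
#'
#' Computes `sum_i w_i * Y(neighbor_i) / Q` where `w_i = T^(i-1) * s_i`,
#' `s_i` is the similarity of the i-th ranked neighbor to the query, and
#' `Q = sum_i s_i`. Returns the zero profile when there are no neighbors or
#' all similarities are zero.
#'
#' @param neighbors tibble from [known_neighbors()] (descending similarity).
#' @param net a [dd_network()].
#' @param T decay factor.
#' @param axis `"drug"` for a row profile, `"disease"` for a column profile.
#' @return Numeric vector of length n (drug axis) or m (disease axis).
#' @export
likelihood_profile <- function(neighbors, net, T = 0.5,
                               axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  len <- if (axis == "drug") ncol(net$Y) else nrow(net$Y)
  if (nrow(neighbors) == 0L) return(numeric(len))
  Q <- sum(neighbors$similarity)
  if (Q <= 0) return(numeric(len))
  w <- T ^ (seq_len(nrow(neighbors)) - 1L) * neighbors$similarity
  profiles <- if (axis == "drug") {
    net$Y[neighbors$index, , drop = FALSE]
  } else {
    t(net$Y[, neighbors$index, drop = FALSE])
  }
  as.numeric(crossprod(profiles, w) / Q)
}

#' Complete a binary association network with WKNKN likelihoods
#'
#' Builds the drug-side likelihood matrix (one [likelihood_profile()] per
#' drug, stacked as rows) and the disease-side likelihood matrix (one per
#' disease, stacked as columns), averages them, and returns the elementwise
#' maximum with the original matrix, so known associations are preserved and
#' zero entries acquire neighbor-supported likelihoods in `[0, 1]`.
#'
#' @param net a binary [dd_network()].
#' @param S_r drug-drug input [sim_matrix()] (e.g. Tanimoto scores).
#' @param S_d disease-disease input [sim_matrix()] (e.g. phenotype scores).
#' @param params a [wknkn_params()].
#' @return A completed [dd_network()] (`completed = TRUE`).
#' @examples
#' net <- dd_network(matrix(c(1, 0, 0, 1, 0, 0), 3, 2,
#'                   dimnames = list(paste0("D", 1:3), c("om1", "om2"))))
#' S_r <- sim_matrix(outer(1:3, 1:3, function(i, j) ifelse(i == j, 1, 0.5)),
#'                   ids = paste0("D", 1:3))
#' S_d <- sim_matrix(diag(2), ids = c("om1", "om2"))
#' wknkn_complete(net, S_r, S_d, wknkn_params(K = 2))
#' @export
wknkn_complete <- function(net, S_r, S_d, params = wknkn_params()) {
  if (net$completed) {
    stop_cmaf("value", "network is already completed; refusing to re-complete")
  }
  S_r <- align_similarity(S_r, net$drug_ids, "drug")
  S_d <- align_similarity(S_d, net$disease_ids, "disease")
  m <- nrow(net$Y); n <- ncol(net$Y)
  Yr <- matrix(0, m, n)
  for (i in seq_len(m)) {
    nb <- known_neighbors(i, S_r, net, axis = "drug", K = params$K)
    Yr[i, ] <- likelihood_profile(nb, net, T = params$T, axis = "drug")
  }
  Yd <- matrix(0, m, n)
  for (j in seq_len(n)) {
    nb <- known_neighbors(j, S_d, net, axis = "disease", K = params$K)
    Yd[, j] <- likelihood_profile(nb, net, T = params$T, axis = "disease")
  }
  Yrd <- (Yr + Yd) / 2
  Ynew <- pmax(net$Y, Yrd)
  # guard against tiny floating excursions above 1
  Ynew[Ynew > 1] <- 1
  dd_network(Ynew, net$drug_ids, net$disease_ids, completed = TRUE)
}
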