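# Synthetic planted-structure generator.
#
# Emulates the structure of a curated drug-disease gold standard at desk
# scale: a sparse binary bipartite matrix driven by low-rank non-negative
# latent factors, plus two symmetric similarity matrices in [0, 1] with unit
# diagonal that are informative about the association pattern (cosine
# similarity of the latent factors, optionally corrupted by symmetric
# Gaussian noise). Structure and noise use independent seeded substreams so
# the noise level can vary with the planted structure held fixed.

#' Specification of a synthetic drug-disease instance
#'
#' @param m,n numbers of drugs and diseases.
#' @param r latent rank of the planted structure (`r <= min(m, n)`).
#' @param density target fraction of positive pairs, in `(0, 1)`.
#' @param similarity_noise standard deviation of the symmetric Gaussian
#'   noise added to the cosine similarities (>= 0).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 150L, n = 100L, r = 6L, density = 0.06,
                           similarity_noise = 0.1, seed = 1L) {
  m <- as.integer(m); n <- as.integer(n); r <- as.integer(r)
  if (m < 2L || n < 2L) stop_cmaf("value", "need at least 2 drugs and 2 diseases")
  if (r < 1L || r > min(m, n)) stop_cmaf("value", "rank r must satisfy 1 <= r <= min(m, n)")
  if (!is.finite(density) || density <= 0 || density >= 1) {
    stop_cmaf("value", "density must lie in (0, 1)")
  }
  if (!is.finite(similarity_noise) || similarity_noise < 0) {
    stop_cmaf("value", "similarity_noise must be >= 0")
  }
  structure(list(m = m, n = n, r = r, density = density,
                 similarity_noise = similarity_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one dominant group membership per entity plus uniform background loadings
cluster_factors <- function(p, r) {
  F <- matrix(runif(p * r, 0, 0.01), p, r)
  F[cbind(seq_len(p), sample.int(r, p, replace = TRUE))] <- runif(p, 0.6, 1)
  F
}

cosine_rows <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(U / nrm)
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

noisy_similarity <- function(S, sigma) {
  p <- nrow(S)
  if (sigma > 0) {
    E <- matrix(0, p, p)
    up <- upper.tri(E)
    E[up] <- rnorm(sum(up), 0, sigma)
    E <- E + t(E)
    S <- S + E
    S[S < 0] <- 0
    S[S > 1] <- 1
    diag(S) <- 1
  }
  S
}

#' Generate a synthetic drug-disease instance with planted structure
#'
#' Draws cluster-structured non-negative latent factors `U` (m x r) and `V`
#' (n x r): each entity belongs primarily to one of `r` latent groups, with
#' its main loading drawn from Unif(0.6, 1) and background loadings from
#' Unif(0, 0.01), so drug-disease pairs in matching groups carry most of the
#' association mass. `P = s * U V'` is rescaled so that `mean(pmin(P, 1))`
#' equals the target density exactly, `Y ~ Bernoulli(P)` is sampled
#' independently, and
#' builds drug/disease similarities as the cosine similarity of the factor
#' rows plus symmetric Gaussian noise, clipped to `[0, 1]` with unit
#' diagonal. If the sampled `Y` is degenerate (an all-zero matrix, or the
#' target density is unreachable after clipping), generation retries with a
#' fresh substream, failing after 10 attempts.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `net` (binary [dd_network()]), `S_r`, `S_d`
#'   ([sim_matrix()] of kind input), `truth` (the m x n probability matrix),
#'   and `spec`.
#' @export
simulate_network <- function(spec) {
  structure_seed <- derive_seed(spec$seed, "structure")
  noise_seed <- derive_seed(spec$seed, "noise")
  drug_ids <- sprintf("DRUG%04d", seq_len(spec$m))
  disease_ids <- sprintf("DIS%04d", seq_len(spec$n))
  for (attempt in 0:9) {
    draw <- with_seed((structure_seed + attempt) %% 2147483647, {
      U <- cluster_factors(spec$m, spec$r)
      V <- cluster_factors(spec$n, spec$r)
      P0 <- tcrossprod(U, V)
      reachable <- mean(P0 > 0) > spec$density
      P <- NULL
      if (reachable) {
        f <- function(s) mean(pmin(s * P0, 1)) - spec$density
        hi <- 1
        while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
        s <- uniroot(f, c(0, hi), tol = 1e-12)$root
        P <- pmin(s * P0, 1)
      }
      Y <- if (!is.null(P)) {
        matrix(rbinom(length(P), 1L, P), nrow(P), ncol(P))
      } else NULL
      list(U = U, V = V, P = P, Y = Y)
    })
    if (!is.null(draw$Y) && sum(draw$Y) > 0) break
    draw <- NULL
  }
  if (is.null(draw)) {
    stop_cmaf("value", "could not reach target density after 10 attempts")
  }
  S_r <- with_seed(noise_seed,
                   noisy_similarity(cosine_rows(draw$U), spec$similarity_noise))
  S_d <- with_seed((noise_seed + 1L) %% 2147483647,
                   noisy_similarity(cosine_rows(draw$V), spec$similarity_noise))
  dimnames(draw$P) <- list(drug_ids, disease_ids)
  list(net = dd_network(draw$Y, drug_ids, disease_ids),
       S_r = sim_matrix(S_r, ids = drug_ids, kind = "input"),
       S_d = sim_matrix(S_d, ids = disease_ids, kind = "input"),
       truth = draw$P,
       spec = spec)
}

#' Hide a random fraction of the known associations
#'
#' Uniformly removes `ceiling(fraction * positives)` known pairs from the
#' network (set to 0), returning both the masked training network and the
#' held-out pair list. At least one positive must remain.
#'
#' @param net a binary [dd_network()].
#' @param fraction fraction of positives to hide, in `(0, 1)`.
#' @param seed integer seed.
#' @return A list with `net` (masked [dd_network()]) and `held_out` (tibble
#'   `drug_id`, `disease_id`).
#' @export
mask_positives <- function(net, fraction, seed = 1L) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop_cmaf("value", "fraction must lie in (0, 1)")
  }
  pos <- which(net$Y == 1)
  if (!length(pos)) stop_cmaf("value", "network has no positives to mask")
  n_hold <- as.integer(ceiling(fraction * length(pos)))
  if (length(pos) - n_hold < 1L) {
    stop_cmaf("value", "masking ", n_hold, " of ", length(pos),
              " positives would leave an empty training network")
  }
  held <- with_seed(seed, sort(sample(pos, n_hold)))
  Ytr <- net$Y
  Ytr[held] <- 0
  m <- nrow(net$Y)
  held_out <- tibble::tibble(
    drug_id = net$drug_ids[(held - 1L) %% m + 1L],
    disease_id = net$disease_ids[(held - 1L) %/% m + 1L])
  list(net = dd_network(Ytr, net$drug_ids, net$disease_ids),
       held_out = held_out)
}
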