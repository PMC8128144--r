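# Noisy-OR fusion of the three base predictors, and the one-call pipeline
# (complete -> learn similarities -> three predictors -> fuse).

#' Clamp scores to the unit interval
#'
#' NMF reconstructions can exceed 1; fusion requires probabilities. Clipping
#' is local and parameter-free and only touches scores already expressing
#' near-certainty; the rank order of unclipped entries is preserved.
#' Entries below -1e-9 are an error (scores must be non-negative).
#'
#' @param scores a [score_matrix()].
#' @return A [score_matrix()] with entries in `[0, 1]`.
#' @export
clip_unit <- function(scores) {
  R <- scores$R
  if (any(R < -1e-9)) {
    stop_cmaf("value", "negative scores (min ", format(min(R)),
              ") cannot be clipped to [0, 1]")
  }
  R[R < 0] <- 0
  R[R > 1] <- 1
  score_matrix(R, scores$drug_ids, scores$disease_ids, source = scores$source)
}

#' Fuse three base score matrices with the noisy-OR rule
#'
#' `Rt = 1 - (1 - Y_lp)(1 - Y_nmf)(1 - Y_ncp)` elementwise: the probability
#' that at least one base predictor flags the pair, assuming independence.
#' The result dominates each input (`Rt >= max` elementwise), is monotone in
#' each argument, and stays in `[0, 1]`.
#'
#' @param lp,nmf,ncp [score_matrix()] objects over identical vocabularies,
#'   entries in `[0, 1]` (pass NMF scores through [clip_unit()] first).
#' @return A [score_matrix()] with `source = "CMAF"`.
#' @examples
#' ids <- list("DB1", "om1")
#' s <- function(v) score_matrix(matrix(v, 1, 1, dimnames = ids))
#' fuse_scores(s(0.5), s(0.5), s(0.5))$R  # 0.875
#' @export
fuse_scores <- function(lp, nmf, ncp) {
  for (s in list(nmf, ncp)) {
    if (!identical(s$drug_ids, lp$drug_ids) ||
        !identical(s$disease_ids, lp$disease_ids)) {
      stop_cmaf("identifier", "score matrices are not aligned to the same vocabularies")
    }
  }
  for (s in list(lp, nmf, ncp)) {
    if (any(s$R < -1e-9) || any(s$R > 1 + 1e-9)) {
      stop_cmaf("value", s$source, " scores must lie in [0, 1] before fusion")
    }
  }
  Rt <- 1 - (1 - pmin(pmax(lp$R, 0), 1)) * (1 - pmin(pmax(nmf$R, 0), 1)) *
    (1 - pmin(pmax(ncp$R, 0), 1))
  score_matrix(Rt, lp$drug_ids, lp$disease_ids, source = "CMAF")
}

#' Fit the full ensemble association-prediction pipeline
#'
#' Runs the four stages on a binary association network and its two input
#' similarity matrices: (1) WKNKN completion, (2) linear neighborhood
#' similarity learning on the completed profiles (rows for drugs, columns for
#' diseases), (3) the three base predictors, (4) noisy-OR fusion. Returns a
#' fitted object holding every intermediate artifact; `tidy()` extracts a
#' per-pair score tibble and `glance()` a one-row fit summary.
#'
#' @param net binary [dd_network()].
#' @param S_r,S_d input [sim_matrix()] objects for drugs and diseases.
#' @param wknkn a [wknkn_params()].
#' @param lns_r,lns_d [lns_params()] for the drug and disease neighborhood
#'   learners.
#' @param lp an [lp_params()].
#' @param nmf an [nmf_params()].
#' @return An object of class `cmaf_fit` with elements `completed`,
#'   `Sr_star`, `Sd_star`, `scores` (named list LPRIA/NMFRIA/NCPRIA/CMAF),
#'   `factors`, and the parameter set.
#' @examples
#' sim <- simulate_network(synthetic_spec(m = 20, n = 12, r = 3,
#'                                        density = 0.15, seed = 7))
#' fit <- cmaf(sim$net, sim$S_r, sim$S_d)
#' glance(fit)
#' @export
cmaf <- function(net, S_r, S_d,
                 wknkn = wknkn_params(),
                 lns_r = lns_params(), lns_d = lns_params(),
                 lp = lp_params(), nmf = nmf_params()) {
  completed <- wknkn_complete(net, S_r, S_d, wknkn)
  Sr_star <- linear_neighborhood_similarity(completed$Y, lns_r,
                                            ids = completed$drug_ids)
  Sd_star <- linear_neighborhood_similarity(t(completed$Y), lns_d,
                                            ids = completed$disease_ids)
  lp_scores <- lpria_predict(completed, Sr_star, Sd_star, lp)
  factors <- nmfria_fit(completed, Sr_star, Sd_star, nmf)
  nmf_scores <- nmfria_predict(factors)
  ncp_scores <- ncpria_predict(completed, Sr_star, Sd_star)
  fused <- fuse_scores(lp_scores, clip_unit(nmf_scores), ncp_scores)
  structure(list(net = net, completed = completed,
                 Sr_star = Sr_star, Sd_star = Sd_star,
                 scores = list(LPRIA = lp_scores, NMFRIA = nmf_scores,
                               NCPRIA = ncp_scores, CMAF = fused),
                 factors = factors,
                 params = list(wknkn = wknkn, lns_r = lns_r, lns_d = lns_d,
                               lp = lp, nmf = nmf)),
            class = "cmaf_fit")
}

#' @export
print.cmaf_fit <- function(x, ...) {
  cat("<cmaf_fit> ", length(x$net$drug_ids), " drugs x ",
      length(x$net$disease_ids), " diseases; ", sum(x$net$Y),
      " known associations\n", sep = "")
  cat("  fused score range [", format(min(x$scores$CMAF$R), digits = 4), ", ",
      format(max(x$scores$CMAF$R), digits = 4), "]\n", sep = "")
  invisible(x)
}
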