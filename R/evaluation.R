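# Evaluation harness: repeated 10-fold cross-validation over known pairs,
# de-novo drug hold-out, ROC/AUC, masked-recovery checks and ranked candidate
# export.
#
# Ranking convention throughout: held-out (test) associations are scored
# against all pairs that are unknown in the full matrix; training positives
# are excluded from both sides. AUC is the trapezoidal area under the ROC
# swept over distinct score thresholds, which equals the Mann-Whitney
# probability that a random positive outranks a random negative with ties
# half-credited.

#' Build a repeated cross-validation fold plan over known pairs
#'
#' Within each repeat the known (drug, disease) pairs are randomly
#' partitioned into `n_folds` parts whose sizes differ by at most one.
#' The plan records the pairs themselves, so downstream code never needs to
#' re-read the association matrix to find the positives.
#'
#' @param net a binary [dd_network()].
#' @param n_folds number of folds (default 10).
#' @param repeats number of independent repetitions (default 10).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return An object of class `cmaf_fold_plan`: `pairs` (tibble of the known
#'   pairs with indices and ids) and `assignments` (tibble with columns
#'   `repeat_`, `fold`, `pair` indexing into `pairs`).
#' @export
make_folds <- function(net, n_folds = 10L, repeats = 10L, seed = 1L) {
  pos <- which(net$Y == 1, arr.ind = TRUE)
  P <- nrow(pos)
  if (P < n_folds) {
    stop_cmaf("value", "only ", P, " known pairs but ", n_folds, " folds requested")
  }
  pairs <- tibble::tibble(
    pair = seq_len(P),
    drug = as.integer(pos[, 1L]), disease = as.integer(pos[, 2L]),
    drug_id = net$drug_ids[pos[, 1L]],
    disease_id = net$disease_ids[pos[, 2L]])
  assignments <- with_seed(seed, purrr::map_dfr(seq_len(repeats), function(r) {
    perm <- sample.int(P)
    tibble::tibble(repeat_ = r,
                   fold = rep_len(seq_len(n_folds), P),
                   pair = perm)
  }))
  structure(list(pairs = pairs, assignments = assignments,
                 n_folds = as.integer(n_folds), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 dim = dim(net$Y),
                 drug_ids = net$drug_ids, disease_ids = net$disease_ids),
            class = "cmaf_fold_plan")
}

#' @export
print.cmaf_fold_plan <- function(x, ...) {
  cat("<cmaf_fold_plan> ", nrow(x$pairs), " known pairs, ", x$n_folds,
      " folds x ", x$repeats, " repeats (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' ROC curve from positive and negative score sets
#'
#' Sweeps the decision threshold over the distinct observed scores in
#' descending order; at each threshold a pair is called positive when its
#' score is at or above the threshold, giving TP/FP/TN/FN counts and the
#' true- and false-positive rates.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors of scores for the
#'   known-positive and candidate (negative) pairs.
#' @return A tibble with columns `threshold`, `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `fpr`, starting at (FPR, TPR) = (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores)) {
    stop_cmaf("value", "both score sets must be non-empty")
  }
  if (any(!is.finite(c(pos_scores, neg_scores)))) {
    stop_cmaf("value", "scores must be finite")
  }
  P <- length(pos_scores); N <- length(neg_scores)
  s <- c(pos_scores, neg_scores)
  l <- rep(c(1, 0), c(P, N))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; l <- l[o]
  ends <- c(which(diff(s) != 0), length(s))
  tp <- c(0, cumsum(l)[ends])
  fp <- c(0, ends) - tp
  tibble::tibble(
    threshold = c(Inf, s[ends]),
    tp = tp, fp = fp,
    tn = N - fp, fn = P - tp,
    tpr = tp / P, fpr = fp / N)
}

#' Area under an ROC curve
#'
#' Trapezoidal integration of TPR over FPR; equal to the tie-half-credited
#' Mann-Whitney statistic of the underlying score sets.
#'
#' @param roc a tibble from [roc_curve()].
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' AUC directly from two score sets
#'
#' @inheritParams roc_curve
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_scores <- function(pos_scores, neg_scores) {
  auc(roc_curve(pos_scores, neg_scores))
}

cv_default_params <- function() {
  list(wknkn = wknkn_params(), lns_r = lns_params(), lns_d = lns_params(),
       lp = lp_params(), nmf = nmf_params())
}

fit_and_score <- function(net_train, S_r, S_d, params) {
  fit <- cmaf(net_train, S_r, S_d, wknkn = params$wknkn,
              lns_r = params$lns_r, lns_d = params$lns_d,
              lp = params$lp, nmf = params$nmf)
  list(LPRIA = fit$scores$LPRIA$R,
       NMFRIA = clip_unit(fit$scores$NMFRIA)$R,
       NCPRIA = fit$scores$NCPRIA$R,
       CMAF = fit$scores$CMAF$R)
}

#' Repeated cross-validation of the pipeline and its base predictors
#'
#' For every fold of every repeat, the test pairs are removed from the
#' training matrix (which is rebuilt from the fold plan's pair list, so the
#' pipeline never reads the held-out cells), the full pipeline is re-run on
#' the training matrix alone (completion and similarity learning included),
#' and a pooled AUC is computed per method with the held-out pairs as
#' positives and every pair unknown in the full matrix as negatives.
#' Fold AUCs are averaged within each repeat and then across repeats.
#'
#' @param net a binary [dd_network()].
#' @param S_r,S_d input similarity matrices.
#' @param plan a [make_folds()] plan built on `net`.
#' @param params named list of stage parameters (`wknkn`, `lns_r`, `lns_d`,
#'   `lp`, `nmf`); missing entries take the stage defaults.
#' @param methods which score matrices to evaluate.
#' @return An object of class `cmaf_cv`: `folds` (tibble `repeat_`, `fold`,
#'   `method`, `auc`, `n_pos`, `n_neg`), `repeat_means`, and `summary`
#'   (grand mean AUC per method).
#' @export
cross_validate <- function(net, S_r, S_d, plan, params = list(),
                           methods = c("LPRIA", "NMFRIA", "NCPRIA", "CMAF")) {
  methods <- match.arg(methods, several.ok = TRUE)
  params <- modifyList(cv_default_params(), params)
  dims <- plan$dim
  known_idx <- (plan$pairs$disease - 1L) * dims[1L] + plan$pairs$drug
  neg_idx <- setdiff(seq_len(prod(dims)), known_idx)
  folds <- purrr::map_dfr(seq_len(plan$repeats), function(r) {
    asg <- plan$assignments[plan$assignments$repeat_ == r, ]
    purrr::map_dfr(seq_len(plan$n_folds), function(f) {
      test_pairs <- asg$pair[asg$fold == f]
      train_idx <- setdiff(known_idx, known_idx[test_pairs])
      Ytr <- matrix(0, dims[1L], dims[2L])
      Ytr[train_idx] <- 1
      net_train <- dd_network(Ytr, plan$drug_ids, plan$disease_ids)
      sc <- fit_and_score(net_train, S_r, S_d, params)
      purrr::map_dfr(methods, function(mth) {
        R <- sc[[mth]]
        tibble::tibble(repeat_ = r, fold = f, method = mth,
                       auc = auc_scores(R[known_idx[test_pairs]], R[neg_idx]),
                       n_pos = length(test_pairs), n_neg = length(neg_idx))
      })
    })
  })
  repeat_means <- folds |>
    dplyr::group_by(.data$repeat_, .data$method) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop")
  summary <- repeat_means |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop")
  structure(list(folds = folds, repeat_means = repeat_means,
                 summary = summary, plan = plan),
            class = "cmaf_cv")
}

#' @export
print.cmaf_cv <- function(x, ...) {
  cat("<cmaf_cv> ", x$plan$repeats, " x ", x$plan$n_folds,
      "-fold cross-validation\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' De-novo drug hold-out evaluation
#'
#' For each drug with at least one known association (optionally a subset),
#' all of the drug's associations are deleted from the training matrix, the
#' full pipeline is re-run, and the drug's removed associations are ranked
#' against its unknown diseases. Per-drug AUCs are reported alongside a
#' pooled AUC over all drugs' positive and negative score sets.
#'
#' @inheritParams cross_validate
#' @param drugs optional character vector of drug ids to test (default: all
#'   drugs with at least one association).
#' @return An object of class `cmaf_denovo` with `per_drug` (tibble
#'   `drug_id`, `method`, `n_pos`, `n_neg`, `auc`) and `pooled` (tibble
#'   `method`, `auc`).
#' @export
de_novo_drug_test <- function(net, S_r, S_d, params = list(), drugs = NULL,
                              methods = c("LPRIA", "NMFRIA", "NCPRIA", "CMAF")) {
  methods <- match.arg(methods, several.ok = TRUE)
  params <- modifyList(cv_default_params(), params)
  known_drugs <- net$drug_ids[rowSums(net$Y) > 0]
  if (length(known_drugs) < 2L) {
    stop_cmaf("value", "need at least 2 drugs with known associations")
  }
  if (is.null(drugs)) drugs <- known_drugs
  bad <- setdiff(drugs, known_drugs)
  if (length(bad)) {
    stop_cmaf("identifier", "not drugs with known associations: ",
              paste(head(bad, 5L), collapse = ", "))
  }
  pooled_pos <- pooled_neg <- setNames(vector("list", length(methods)), methods)
  per_drug <- purrr::map_dfr(drugs, function(d) {
    i <- match(d, net$drug_ids)
    Ytr <- net$Y
    Ytr[i, ] <- 0
    net_train <- dd_network(Ytr, net$drug_ids, net$disease_ids)
    sc <- fit_and_score(net_train, S_r, S_d, params)
    pos_j <- which(net$Y[i, ] == 1)
    neg_j <- which(net$Y[i, ] == 0)
    purrr::map_dfr(methods, function(mth) {
      ps <- sc[[mth]][i, pos_j]
      ns <- sc[[mth]][i, neg_j]
      pooled_pos[[mth]] <<- c(pooled_pos[[mth]], list(ps))
      pooled_neg[[mth]] <<- c(pooled_neg[[mth]], list(ns))
      tibble::tibble(drug_id = d, method = mth,
                     n_pos = length(ps), n_neg = length(ns),
                     auc = if (length(ns)) auc_scores(ps, ns) else NA_real_)
    })
  })
  pooled <- purrr::map_dfr(methods, function(mth) {
    tibble::tibble(method = mth,
                   auc = auc_scores(unlist(pooled_pos[[mth]]),
                                    unlist(pooled_neg[[mth]])))
  })
  structure(list(per_drug = per_drug, pooled = pooled),
            class = "cmaf_denovo")
}

#' @export
print.cmaf_denovo <- function(x, ...) {
  cat("<cmaf_denovo> ", length(unique(x$per_drug$drug_id)),
      " drugs held out in turn; pooled AUC:\n", sep = "")
  print(x$pooled)
  invisible(x)
}

#' Masked-recovery evaluation outside the CV harness
#'
#' Hides a fraction of the known associations with [mask_positives()],
#' refits the pipeline on the masked matrix, and scores the hidden pairs
#' against all pairs unknown in the original matrix (pooled AUC per method).
#'
#' @inheritParams cross_validate
#' @param fraction fraction of positives to hide, in `(0, 1)`.
#' @param seed seed for the random mask.
#' @return A tibble with columns `method` and `auc`.
#' @export
holdout_recovery <- function(net, S_r, S_d, fraction = 0.1, seed = 1L,
                             params = list(),
                             methods = c("LPRIA", "NMFRIA", "NCPRIA", "CMAF")) {
  methods <- match.arg(methods, several.ok = TRUE)
  params <- modifyList(cv_default_params(), params)
  masked <- mask_positives(net, fraction, seed)
  sc <- fit_and_score(masked$net, S_r, S_d, params)
  m <- nrow(net$Y)
  held_idx <- (match(masked$held_out$disease_id, net$disease_ids) - 1L) * m +
    match(masked$held_out$drug_id, net$drug_ids)
  neg_idx <- which(net$Y == 0)
  purrr::map_dfr(methods, function(mth) {
    tibble::tibble(method = mth,
                   auc = auc_scores(sc[[mth]][held_idx], sc[[mth]][neg_idx]))
  })
}

#' Top-ranked candidate diseases for one drug
#'
#' Ranks the drug's unknown diseases (known associations are excluded) by
#' predicted score, descending, with ties broken by ascending disease id,
#' and returns the first `n`.
#'
#' @param scores a [score_matrix()].
#' @param net the binary [dd_network()] defining which pairs are known.
#' @param drug_id drug identifier present in the vocabulary.
#' @param n maximum number of candidates returned (default 10).
#' @return A tibble with columns `drug_id`, `disease_id`, `score`, `rank`.
#' @export
top_candidates <- function(scores, net, drug_id, n = 10L) {
  i <- match(drug_id, scores$drug_ids)
  if (is.na(i)) stop_cmaf("identifier", "unknown drug id '", drug_id, "'")
  if (!identical(scores$disease_ids, net$disease_ids) ||
      !identical(scores$drug_ids, net$drug_ids)) {
    stop_cmaf("identifier", "score matrix and network vocabularies differ")
  }
  cand <- which(net$Y[i, ] == 0)
  if (!length(cand)) {
    return(tibble::tibble(drug_id = character(), disease_id = character(),
                          score = double(), rank = integer()))
  }
  sc <- scores$R[i, cand]
  ids <- scores$disease_ids[cand]
  ord <- order(-sc, ids)
  keep <- ord[seq_len(min(n, length(ord)))]
  tibble::tibble(drug_id = drug_id, disease_id = ids[keep],
                 score = unname(sc[keep]), rank = seq_along(keep))
}
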