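# broom-style accessors for the fitted pipeline and the evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pipeline into a per-pair score table
#'
#' @param x a `cmaf_fit` from [cmaf()].
#' @param ... unused.
#' @return A tibble with one row per (drug, disease) pair: `drug_id`,
#'   `disease_id`, `known` (the binary input), `completed` (the WKNKN
#'   likelihood), and one column of scores per method (`lpria`, `nmfria`,
#'   `ncpria`, `cmaf`).
#' @method tidy cmaf_fit
#' @export
tidy.cmaf_fit <- function(x, ...) {
  grid <- tidyr::expand_grid(disease_id = x$net$disease_ids,
                             drug_id = x$net$drug_ids)
  tibble::tibble(
    drug_id = grid$drug_id,
    disease_id = grid$disease_id,
    known = as.integer(x$net$Y),
    completed = as.numeric(x$completed$Y),
    lpria = as.numeric(x$scores$LPRIA$R),
    nmfria = as.numeric(x$scores$NMFRIA$R),
    ncpria = as.numeric(x$scores$NCPRIA$R),
    cmaf = as.numeric(x$scores$CMAF$R)) |>
    dplyr::arrange(.data$drug_id, .data$disease_id)
}

#' One-row summary of a fitted pipeline
#'
#' @inheritParams tidy.cmaf_fit
#' @return A one-row tibble: dimensions, number of known pairs, NMF
#'   iterations and final objective, and the fused score range.
#' @method glance cmaf_fit
#' @export
glance.cmaf_fit <- function(x, ...) {
  tibble::tibble(
    n_drugs = length(x$net$drug_ids),
    n_diseases = length(x$net$disease_ids),
    n_known = sum(x$net$Y),
    nmf_iterations = x$factors$iterations,
    nmf_objective = utils::tail(x$factors$objective_trace, 1L),
    nmf_converged = x$factors$converged,
    cmaf_min = min(x$scores$CMAF$R),
    cmaf_max = max(x$scores$CMAF$R))
}

#' Per-fold AUC table of a cross-validation report
#'
#' @param x a `cmaf_cv` from [cross_validate()].
#' @param ... unused.
#' @return The per-fold tibble (`repeat_`, `fold`, `method`, `auc`, ...).
#' @method tidy cmaf_cv
#' @export
tidy.cmaf_cv <- function(x, ...) x$folds

#' Grand-mean AUC summary of a cross-validation report
#'
#' @inheritParams tidy.cmaf_cv
#' @return A one-row tibble with one `<method>_auc` column per evaluated
#'   method plus fold/repeat counts.
#' @method glance cmaf_cv
#' @export
glance.cmaf_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$auc),
                          paste0(tolower(x$summary$method), "_auc"))
  tibble::as_tibble(c(wide, list(n_folds = x$plan$n_folds,
                                 repeats = x$plan$repeats)))
}

#' Per-drug AUC table of a de-novo evaluation
#'
#' @param x a `cmaf_denovo` from [de_novo_drug_test()].
#' @param ... unused.
#' @return The per-drug tibble.
#' @method tidy cmaf_denovo
#' @export
tidy.cmaf_denovo <- function(x, ...) x$per_drug

#' Pooled AUC summary of a de-novo evaluation
#'
#' @inheritParams tidy.cmaf_denovo
#' @return A one-row tibble with one `<method>_auc` column per method.
#' @method glance cmaf_denovo
#' @export
glance.cmaf_denovo <- function(x, ...) {
  tibble::as_tibble(stats::setNames(as.list(x$pooled$auc),
                                    paste0(tolower(x$pooled$method), "_auc")))
}
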