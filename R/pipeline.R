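# Config-driven end-to-end runner: one flat key = value config file wires
# the whole pipeline, and a manifest records everything needed to reproduce
# a run.

pipeline_defaults <- function() {
  list(association = NULL, drug_similarity = NULL, disease_similarity = NULL,
       out_dir = ".",
       seed = 1L,
       wknkn_k = 5L, wknkn_t = 0.5,
       lns_k = 100L, lns_lambda = 1,
       lp_alpha = 0.5,
       nmf_k = 100L, nmf_lambda_l = 2, nmf_lambda_r = 1e-4,
       nmf_lambda_d = 1e-4, nmf_max_iter = 2000L, nmf_tol = 1e-6,
       cv_folds = 10L, cv_repeats = 10L)
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines are `key = value`; `#` starts a comment; unknown keys are an error.
#' Unset keys take the pipeline defaults (the standard parameterization:
#' K = 5, T = 0.5 for completion; K = 100, lambda = 1 for similarity
#' learning; alpha = 0.5; NMF rank 100 with lambda_l = 2 and
#' lambda_r = lambda_d = 1e-4; 10 x 10-fold cross-validation).
#'
#' @param path config file path.
#' @return A named list of class `pipeline_config` with all stage parameter
#'   objects validated.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_cmaf("io", "config file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_defaults()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop_cmaf("format", "cannot parse config line: ", ln)
    key <- kv[2L]; val <- trimws(kv[3L])
    if (!key %in% names(cfg)) stop_cmaf("value", "unknown config key: ", key)
    cfg[[key]] <- if (key %in% c("association", "drug_similarity",
                                 "disease_similarity", "out_dir")) {
      val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop_cmaf("value", "config key ", key,
                                " must be numeric, got '", val, "'")
      num
    }
  }
  config_params(cfg)  # validate eagerly so bad values fail before any work
  structure(cfg, class = "pipeline_config")
}

config_params <- function(cfg) {
  list(wknkn = wknkn_params(cfg$wknkn_k, cfg$wknkn_t),
       lns_r = lns_params(cfg$lns_k, cfg$lns_lambda),
       lns_d = lns_params(cfg$lns_k, cfg$lns_lambda),
       lp = lp_params(cfg$lp_alpha),
       nmf = nmf_params(cfg$nmf_k, cfg$nmf_lambda_l, cfg$nmf_lambda_r,
                        cfg$nmf_lambda_d, cfg$nmf_max_iter, cfg$nmf_tol,
                        seed = derive_seed(cfg$seed, "nmf_init")))
}

load_config_inputs <- function(cfg) {
  for (key in c("association", "drug_similarity", "disease_similarity")) {
    if (is.null(cfg[[key]])) stop_cmaf("value", "config key ", key, " is required")
  }
  net <- load_association_network(cfg$association)
  list(net = net,
       S_r = load_similarity_matrix(cfg$drug_similarity, net$drug_ids),
       S_d = load_similarity_matrix(cfg$disease_similarity, net$disease_ids))
}

#' Run the full pipeline from a configuration and write all artifacts
#'
#' Executes completion, similarity learning, the three base predictors and
#' fusion, writing every intermediate and final matrix as labeled TSV into
#' the configured output directory together with a JSON run manifest
#' (config echo, seed, stage timings in seconds, package and R versions).
#'
#' @param config a `pipeline_config` from [read_pipeline_config()], or the
#'   path of a config file.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, the `cmaf_fit`, with the output directory attached as
#'   attribute `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (verbose) message("[cmaf] ", ...)
  params <- config_params(config)
  inputs <- load_config_inputs(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say(stage, " done in ", timings[[stage]], "s")
    res
  }
  completed <- clock("wknkn", wknkn_complete(inputs$net, inputs$S_r,
                                             inputs$S_d, params$wknkn))
  Sr_star <- clock("lns_drug",
                   linear_neighborhood_similarity(completed$Y, params$lns_r,
                                                  ids = completed$drug_ids))
  Sd_star <- clock("lns_disease",
                   linear_neighborhood_similarity(t(completed$Y), params$lns_d,
                                                  ids = completed$disease_ids))
  lp_scores <- clock("lpria", lpria_predict(completed, Sr_star, Sd_star,
                                            params$lp))
  factors <- clock("nmfria", nmfria_fit(completed, Sr_star, Sd_star,
                                        params$nmf))
  nmf_scores <- nmfria_predict(factors)
  ncp_scores <- clock("ncpria", ncpria_predict(completed, Sr_star, Sd_star))
  fused <- clock("fuse", fuse_scores(lp_scores, clip_unit(nmf_scores),
                                     ncp_scores))
  fit <- structure(list(net = inputs$net, completed = completed,
                        Sr_star = Sr_star, Sd_star = Sd_star,
                        scores = list(LPRIA = lp_scores, NMFRIA = nmf_scores,
                                      NCPRIA = ncp_scores, CMAF = fused),
                        factors = factors, params = params),
                   class = "cmaf_fit")
  write_matrix(completed, file.path(out, "completed.tsv"))
  write_matrix(Sr_star, file.path(out, "similarity_drug.tsv"))
  write_matrix(Sd_star, file.path(out, "similarity_disease.tsv"))
  write_matrix(lp_scores, file.path(out, "scores_lpria.tsv"))
  write_matrix(nmf_scores, file.path(out, "scores_nmfria.tsv"))
  write_matrix(ncp_scores, file.path(out, "scores_ncpria.tsv"))
  write_matrix(fused, file.path(out, "scores_cmaf.tsv"))
  manifest <- list(config = unclass(config), timings = timings,
                   package_version = as.character(utils::packageVersion("cmaf")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("artifacts written to ", out)
  attr(fit, "out_dir") <- out
  invisible(fit)
}
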