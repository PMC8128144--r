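#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rgamma rbinom runif uniroot median setNames
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom rlang .data
NULL

# ---- constructors -----------------------------------------------------------

#' Drug-disease association network
#'
#' A labeled m x n association matrix `Y` whose rows are drugs and columns are
#' diseases. On load the matrix is strictly binary (1 = known association);
#' after weighted K-nearest-known-neighbor completion (see [wknkn_complete()])
#' entries are interaction likelihoods in `[0, 1]`.
#'
#' @param Y numeric matrix with entries in `[0, 1]`.
#' @param drug_ids,disease_ids character vectors of unique identifiers; taken
#'   from `dimnames(Y)` when omitted.
#' @param completed logical; `TRUE` marks a likelihood-completed (fractional)
#'   matrix, `FALSE` a strictly binary one.
#' @return An object of class `dd_network` with fields `Y`, `drug_ids`,
#'   `disease_ids`, `completed`.
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("DB01", "DB02"), c("168600", "125320")))
#' net <- dd_network(Y)
#' @export
dd_network <- function(Y, drug_ids = rownames(Y), disease_ids = colnames(Y),
                       completed = FALSE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  check_ids(drug_ids, "drug")
  check_ids(disease_ids, "disease")
  if (length(drug_ids) != nrow(Y) || length(disease_ids) != ncol(Y)) {
    stop_cmaf("shape", "Y is ", nrow(Y), "x", ncol(Y), " but ",
              length(drug_ids), " drug and ", length(disease_ids),
              " disease identifiers were supplied")
  }
  if (nrow(Y) == 0L || ncol(Y) == 0L) {
    stop_cmaf("format", "association matrix must have at least one drug and one disease")
  }
  if (any(!is.finite(Y))) {
    bad <- which(!is.finite(Y), arr.ind = TRUE)[1L, ]
    stop_cmaf("value", "non-finite entry at drug '", drug_ids[bad[1L]],
              "', disease '", disease_ids[bad[2L]], "'")
  }
  nonbin <- !(Y == 0 | Y == 1)
  if (!completed && any(nonbin)) {
    bad <- which(nonbin, arr.ind = TRUE)[1L, ]
    stop_cmaf("value", "association matrix must be binary; entry ",
              format(Y[bad[1L], bad[2L]]), " at drug '", drug_ids[bad[1L]],
              "', disease '", disease_ids[bad[2L]], "'")
  }
  if (completed && (any(Y < 0) || any(Y > 1))) {
    stop_cmaf("value", "completed association entries must lie in [0, 1]")
  }
  dimnames(Y) <- list(drug_ids, disease_ids)
  structure(list(Y = Y, drug_ids = as.character(drug_ids),
                 disease_ids = as.character(disease_ids),
                 completed = isTRUE(completed)),
            class = "dd_network")
}

#' Pairwise similarity matrix
#'
#' A labeled square matrix of entity similarities in `[0, 1]`. Two kinds are
#' distinguished: `"input"` similarities (chemical Tanimoto scores between
#' drugs, phenotype similarities between diseases), which must be symmetric
#' with unit diagonal, and `"linear_neighborhood"` similarities learned by
#' [linear_neighborhood_similarity()], whose rows are probability vectors with
#' zero diagonal and which need not be symmetric.
#'
#' @param S square numeric matrix.
#' @param ids character vector of entity identifiers (defaults to rownames).
#' @param kind `"input"` or `"linear_neighborhood"`.
#' @return An object of class `sim_matrix` with fields `S`, `ids`, `kind`.
#' @export
sim_matrix <- function(S, ids = rownames(S),
                       kind = c("input", "linear_neighborhood")) {
  kind <- match.arg(kind)
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  check_ids(ids, "entity")
  if (nrow(S) != ncol(S) || length(ids) != nrow(S)) {
    stop_cmaf("shape", "similarity matrix must be square with one id per row")
  }
  if (any(!is.finite(S))) stop_cmaf("value", "similarity entries must be finite")
  if (any(S < -1e-9) || any(S > 1 + 1e-9)) {
    bad <- which(S < -1e-9 | S > 1 + 1e-9, arr.ind = TRUE)[1L, ]
    stop_cmaf("value", "similarity entry ", format(S[bad[1L], bad[2L]]),
              " for ('", ids[bad[1L]], "', '", ids[bad[2L]],
              "') lies outside [0, 1]")
  }
  S[S < 0] <- 0
  S[S > 1] <- 1
  if (kind == "input") {
    asym <- max(abs(S - t(S)))
    if (asym > 1e-6) {
      stop_cmaf("value", "input similarity matrix is asymmetric (max |S - t(S)| = ",
                format(asym), ")")
    }
    S <- (S + t(S)) / 2
    diag(S) <- 1
  } else {
    if (max(abs(diag(S))) > 1e-12) {
      stop_cmaf("value", "linear neighborhood similarity must have zero diagonal")
    }
    rs <- rowSums(S)
    if (any(abs(rs - 1) > 1e-8)) {
      stop_cmaf("value", "linear neighborhood similarity rows must sum to 1")
    }
  }
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, ids = as.character(ids), kind = kind),
            class = "sim_matrix")
}

#' Prediction score matrix
#'
#' An m x n real-valued matrix of predicted association scores aligned to a
#' network's drug and disease vocabularies. Scores from label propagation,
#' network consistency projection and the fused ensemble are probabilities in
#' `[0, 1]`; raw NMF reconstructions may exceed 1.
#'
#' @param R numeric matrix of scores.
#' @param drug_ids,disease_ids identifier vectors (default: dimnames of `R`).
#' @param source one of `"LPRIA"`, `"NMFRIA"`, `"NCPRIA"`, `"CMAF"`,
#'   `"external"`.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(R, drug_ids = rownames(R), disease_ids = colnames(R),
                         source = c("external", "LPRIA", "NMFRIA", "NCPRIA", "CMAF")) {
  source <- match.arg(source)
  R <- as.matrix(R)
  storage.mode(R) <- "double"
  check_ids(drug_ids, "drug")
  check_ids(disease_ids, "disease")
  if (length(drug_ids) != nrow(R) || length(disease_ids) != ncol(R)) {
    stop_cmaf("shape", "score matrix dimensions do not match identifier lengths")
  }
  if (any(!is.finite(R))) stop_cmaf("value", "scores must be finite")
  if (source %in% c("LPRIA", "NCPRIA", "CMAF") &&
      (any(R < -1e-9) || any(R > 1 + 1e-9))) {
    stop_cmaf("value", source, " scores must lie in [0, 1]")
  }
  dimnames(R) <- list(drug_ids, disease_ids)
  structure(list(R = R, drug_ids = as.character(drug_ids),
                 disease_ids = as.character(disease_ids), source = source),
            class = "score_matrix")
}

# ---- validation helpers -----------------------------------------------------

check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop_cmaf("identifier", "missing ", what, " identifiers")
  }
  if (anyDuplicated(ids)) {
    stop_cmaf("identifier", "duplicate ", what, " identifier '",
              ids[duplicated(ids)][1L], "'")
  }
  invisible(ids)
}

stop_cmaf <- function(class, ...) {
  stop(structure(class = c(paste0("cmaf_", class, "_error"), "cmaf_error",
                           "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' @export
print.dd_network <- function(x, ...) {
  cat("<dd_network> ", length(x$drug_ids), " drugs x ", length(x$disease_ids),
      " diseases, ", if (x$completed) "completed (fractional)" else
        paste0(sum(x$Y), " known associations"), "\n", sep = "")
  invisible(x)
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("<sim_matrix> ", length(x$ids), " entities, kind = ", x$kind, "\n", sep = "")
  invisible(x)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", length(x$drug_ids), " x ", length(x$disease_ids),
      ", source = ", x$source, ", range [", format(min(x$R), digits = 4), ", ",
      format(max(x$R), digits = 4), "]\n", sep = "")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

read_labeled_tsv <- function(path) {
  if (!file.exists(path)) stop_cmaf("io", "file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
               check.names = FALSE, colClasses = "character",
               stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_cmaf("format", "cannot parse TSV '", path, "': ",
                                  conditionMessage(e)))
  if (ncol(df) < 2L || nrow(df) < 1L) {
    stop_cmaf("format", "'", path, "' must have a header row of column ids and ",
              "a first column of row ids")
  }
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  M <- matrix(vals, nrow = nrow(df), ncol = length(col_ids))
  if (any(is.na(M))) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop_cmaf("value", "cell at row '", row_ids[bad[1L]], "', column '",
              col_ids[bad[2L]], "' of '", path, "' is not numeric")
  }
  dimnames(M) <- list(row_ids, col_ids)
  M
}

#' Read a binary association matrix from a labeled TSV
#'
#' The file must have a header row of disease identifiers, a first column of
#' drug identifiers, and strictly binary 0/1 cells. Fractional (completed)
#' matrices are a distinct artifact and are rejected here; use
#' `completed = TRUE` to read one written by the completion stage.
#'
#' @param path path to a UTF-8, tab-separated file.
#' @param completed logical; allow fractional entries in `[0, 1]`.
#' @return A [dd_network()].
#' @export
load_association_network <- function(path, completed = FALSE) {
  M <- read_labeled_tsv(path)
  dd_network(M, completed = completed)
}

#' Read a similarity matrix from a labeled TSV, aligned to expected ids
#'
#' The file's identifiers must be a superset of `expected_ids`; rows and
#' columns are subset and reordered to match. Near-symmetric input matrices
#' (max asymmetry at most 1e-6) are symmetrized as `(S + t(S))/2`; larger
#' asymmetries are an error.
#'
#' @param path path to a labeled square TSV.
#' @param expected_ids identifiers the matrix must cover, in the desired order;
#'   `NULL` keeps the file's own order.
#' @param kind similarity kind, see [sim_matrix()].
#' @return A [sim_matrix()].
#' @export
load_similarity_matrix <- function(path, expected_ids = NULL, kind = "input") {
  M <- read_labeled_tsv(path)
  if (nrow(M) != ncol(M)) {
    stop_cmaf("format", "similarity matrix in '", path, "' is not square")
  }
  if (!identical(rownames(M), colnames(M))) {
    if (!setequal(rownames(M), colnames(M))) {
      stop_cmaf("identifier", "row and column identifiers differ in '", path, "'")
    }
    M <- M[, rownames(M), drop = FALSE]
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, rownames(M))
    if (length(missing)) {
      stop_cmaf("identifier", "similarity matrix '", path, "' lacks ids: ",
                paste(head(missing, 5L), collapse = ", "))
    }
    M <- M[expected_ids, expected_ids, drop = FALSE]
  }
  sim_matrix(M, kind = kind)
}

#' Read a score matrix from a labeled TSV
#'
#' @inheritParams load_association_network
#' @param source provenance tag, see [score_matrix()].
#' @return A [score_matrix()].
#' @export
load_score_matrix <- function(path, source = "external") {
  M <- read_labeled_tsv(path)
  score_matrix(M, source = source)
}

#' Write a labeled matrix object as TSV
#'
#' Writes any of the three matrix containers (association network, similarity
#' matrix, score matrix) as a UTF-8 tab-separated file with a header row of
#' column identifiers and a leading column of row identifiers, at full double
#' precision, preserving row and column order. `write_matrix()` followed by
#' the matching loader is the identity.
#'
#' @param x a [dd_network()], [sim_matrix()] or [score_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  M <- matrix_of(x)
  if (nrow(M) == 0L || ncol(M) == 0L) {
    stop_cmaf("format", "refusing to write an empty matrix")
  }
  cells <- matrix(sprintf("%.17g", M), nrow = nrow(M),
                  dimnames = dimnames(M))
  df <- data.frame(id = rownames(M), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- ""
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_cmaf("io", "cannot write '", path, "'")
  invisible(path)
}

# the raw labeled matrix inside any container
matrix_of <- function(x) {
  if (inherits(x, "dd_network")) return(x$Y)
  if (inherits(x, "sim_matrix")) return(x$S)
  if (inherits(x, "score_matrix")) return(x$R)
  if (is.matrix(x)) return(x)
  stop_cmaf("value", "not a matrix container")
}

# align a sim_matrix to a network's vocabulary on one axis
align_similarity <- function(S, ids, axis = c("drug", "disease")) {
  axis <- match.arg(axis)
  if (identical(S$ids, as.character(ids))) return(S)
  missing <- setdiff(ids, S$ids)
  if (length(missing)) {
    stop_cmaf("identifier", axis, " similarity matrix lacks ids: ",
              paste(head(missing, 5L), collapse = ", "))
  }
  sim_matrix(S$S[ids, ids, drop = FALSE], kind = S$kind)
}
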