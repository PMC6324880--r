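#' Read and write cohort tables
#'
#' Cohort tables are UTF-8 tab-separated files with one row per subject.
#' Required columns: `subject_id` (unique) and `diagnosis`; all other columns
#' (site, age, sex, confounds, scores) pass through unchanged.
#'
#' @param path file path.
#' @return `read_cohort_table`: a data.frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in c("subject_id", "diagnosis"))
    if (!col %in% names(tab)) stop("missing required column: ", col)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) stop("duplicate subject ids: ", paste(unique(dup), collapse = ", "))
  tab
}

#' @rdname read_cohort_table
#' @param cohort a cohort data.frame (must contain `subject_id`, `diagnosis`).
#' @return `write_cohort_table`: the path, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  for (col in c("subject_id", "diagnosis"))
    if (!col %in% names(cohort)) stop("missing required column: ", col)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write labelled numeric matrices as TSV
#'
#' Subjects x features matrices (e.g. FC tables) are written with the feature
#' labels as header and the row labels in a leading `subject_id` column, so
#' `read_matrix_tsv(write_matrix_tsv(x)) == x` including label order.
#'
#' @param m numeric matrix with rownames (subjects) and colnames (features).
#' @param path file path.
#' @return `write_matrix_tsv`: the path, invisibly; `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("row_%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("col_%04d", seq_len(ncol(m)))
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "subject_id") stop("missing required column: subject_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$subject_id
  m
}

#' Serialize a fitted model to JSON and back
#'
#' The JSON stores weights, support labels, standardization parameters and
#' fit diagnostics at full precision, so a round-tripped model predicts
#' identically.
#'
#' @param model a `wma_model`.
#' @param path file path.
#' @return `write_model_json`: the path, invisibly; `read_model_json`: the
#'   `wma_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "wma_model"))
  obj <- unclass(model)
  obj$ard_precisions <- NULL  # Inf is not representable in JSON
  obj$ard_log10_precisions <- as.list(log10(model$ard_precisions))
  # named vectors serialize as JSON objects so labels survive the round trip
  for (f in c("weights", "x_mean", "x_sd")) obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$ard_precisions <- 10^unlist(obj$ard_log10_precisions)
  obj$ard_log10_precisions <- NULL
  for (f in c("weights", "ard_precisions", "x_mean", "x_sd"))
    obj[[f]] <- unlist(obj[[f]])
  obj$support <- as.integer(obj$support)
  structure(obj, class = "wma_model")
}

#' Write the ground truth of a synthetic cohort to JSON
#'
#' Records the planted weights, support, intercept, noise levels, diagnosis
#' shifts and seed, for later verification of recovery.
#'
#' @param gt a `wma_ground_truth`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "wma_ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
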