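#' Read and write pipeline tables
#'
#' Plain-text interchange formats used by every stage: Ct tables and
#' survival tables as CSV, expression matrices as TSV with the sample
#' id in the first column, ground truth and fitted models as JSON.
#'
#' @param table,matrix,x object to write.
#' @param path file path.
#' @return readers return the object; writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_ct_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "o2_percent", "replicate", "feature_id",
            "feature_class", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' @rdname pipeline_io
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix),
                   as.data.frame(matrix, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname pipeline_io
#' @export
write_survival_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_survival_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "endpoint", "time_months", "event")
  if (!all(need %in% names(tab)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname pipeline_io
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  y <- unclass(x)
  if (!is.null(y$induced_in))
    y$induced_in <- as.data.frame(y$induced_in)
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_score_result <- function(x, path) {
  stopifnot(inherits(x, "score_result"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_cox_fit <- function(x, path) {
  stopifnot(inherits(x, "cox_fit"))
  df <- as.data.frame(x)
  df$n <- attr(x, "n")
  df$n_events <- attr(x, "n_events")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
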