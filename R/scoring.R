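new_score_result <- function(sample_id, score, coverage = 1) {
  out <- data.frame(sample_id = sample_id, score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- coverage
  class(out) <- c("score_result", "data.frame")
  out
}

matrix_features <- function(matrix) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)),
            !is.null(rownames(matrix)))
  if (anyDuplicated(colnames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("expression matrix has duplicated sample or feature ids")
  colnames(matrix)
}

intersect_features <- function(matrix, wanted, what) {
  present <- intersect(wanted, matrix_features(matrix))
  if (!length(present))
    stop("no ", what, " signature features found in the matrix; missing: ",
         paste(wanted, collapse = ", "))
  present
}

#' Score samples by mean signature expression
#'
#' Per-sample mean of log2 expression over the signature features
#' present in the matrix. Features absent from the matrix are dropped
#' and the retained fraction reported as coverage (with a warning), the
#' usual convention when a platform lacks probes for part of a
#' signature.
#'
#' @param matrix samples x features numeric matrix of log2 expression
#'   with sample and feature names.
#' @param signature an unsigned [gene_signature()] or a character vector
#'   of feature ids.
#' @return a `score_result` data frame (sample_id, score) with a
#'   `"coverage"` attribute.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
#' score_mean_expression(m, c("a", "b"))$score
#' @export
score_mean_expression <- function(matrix, signature) {
  genes <- if (inherits(signature, "gene_signature"))
    signature_features(signature) else as.character(signature)
  present <- intersect_features(matrix, genes, "any")
  coverage <- length(present) / length(genes)
  if (coverage < 1)
    warning("signature coverage ", round(coverage, 3), ": missing ",
            paste(setdiff(genes, present), collapse = ", "))
  new_score_result(rownames(matrix),
                   rowMeans(matrix[, present, drop = FALSE]), coverage)
}

#' Score samples with a signed signature
#'
#' `score = mean(positive features present) - mean(negative features
#' present)`: up-regulated hypoxia miRNAs push the score up,
#' down-regulated ones pull it down. Missing features are dropped with
#' coverage recorded; at least one feature must survive on each side.
#'
#' @param matrix samples x features log2 expression matrix.
#' @param signature a signed [gene_signature()].
#' @return a `score_result` data frame with a `"coverage"` attribute.
#' @examples
#' m <- matrix(c(4, 6, 1, 3), 1, 4,
#'             dimnames = list("s1", c("p1", "p2", "n1", "n2")))
#' sig <- gene_signature("toy", c("p1", "p2"), c("n1", "n2"))
#' score_signed_signature(m, sig)$score  # (4+6)/2 - (1+3)/2 = 3
#' @export
score_signed_signature <- function(matrix, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  if (!length(signature$negative))
    stop("signature has no negative features; use score_mean_expression()")
  pos <- intersect_features(matrix, signature$positive, "positive")
  neg <- intersect_features(matrix, signature$negative, "negative")
  coverage <- (length(pos) + length(neg)) / length(signature)
  if (coverage < 1)
    warning("signature coverage ", round(coverage, 3), ": missing ",
            paste(setdiff(signature_features(signature), c(pos, neg)),
                  collapse = ", "))
  score <- rowMeans(matrix[, pos, drop = FALSE]) -
    rowMeans(matrix[, neg, drop = FALSE])
  new_score_result(rownames(matrix), score, coverage)
}

#' Dichotomise signature scores at a quantile cut-off
#'
#' Labels a sample `hypoxic` when its score strictly exceeds the
#' cut-off; ties go to `normoxic` (conservative hypoxia calls). The
#' cut-off is the median, lower or upper quartile of the scores — or of
#' `reference_scores` when a cut-off learned in another cohort is being
#' transferred — computed with linear interpolation (R quantile type 7)
#' so it is reproducible across platforms. An `external` numeric
#' cut-off can be supplied directly.
#'
#' @param scores a `score_result` or numeric vector of scores (named or
#'   not).
#' @param cutoff_type one of "median", "lower_quartile",
#'   "upper_quartile", "external".
#' @param reference_scores optional scores from a reference cohort whose
#'   quantile defines the cut-off.
#' @param cutoff_value numeric cut-off, required for
#'   `cutoff_type = "external"`.
#' @return a `score_result` data frame with `cutoff_type`,
#'   `cutoff_value` and `label` columns.
#' @examples
#' classify_by_quantile(c(a = 1, b = 2, c = 3, d = 4), "median")
#' @export
classify_by_quantile <- function(scores,
                                 cutoff_type = c("median", "lower_quartile",
                                                 "upper_quartile", "external"),
                                 reference_scores = NULL,
                                 cutoff_value = NULL) {
  cutoff_type <- match.arg(cutoff_type)
  if (inherits(scores, "score_result")) {
    ids <- scores$sample_id
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    ids <- if (!is.null(names(scores))) names(scores)
           else sprintf("sample_%d", seq_along(s))
  }
  ref <- if (!is.null(reference_scores)) {
    if (inherits(reference_scores, "score_result")) reference_scores$score
    else as.numeric(reference_scores)
  } else s
  if (cutoff_type == "external") {
    if (is.null(cutoff_value) || !is.finite(cutoff_value))
      stop("external cutoff_type requires a numeric cutoff_value")
    cut <- cutoff_value
  } else {
    q <- c(median = 0.5, lower_quartile = 0.25, upper_quartile = 0.75)[
      cutoff_type]
    if (length(ref) < 4 && cutoff_type != "median")
      stop("quartile cut-offs need at least 4 reference samples")
    cut <- unname(quantile(ref, q, type = 7, names = FALSE))
  }
  out <- new_score_result(ids, s)
  out$cutoff_type <- cutoff_type
  out$cutoff_value <- cut
  out$label <- ifelse(s > cut, "hypoxic", "normoxic")
  out
}

#' Combine two hypoxia classifications
#'
#' A sample is hypoxic under the combined call only when both input
#' classifications label it hypoxic — the conjunction used to isolate
#' the most hypoxic tumours when two signatures are available.
#'
#' @param a,b `score_result` objects carrying `label` columns for the
#'   same samples.
#' @return data frame (sample_id, label_a, label_b, label).
#' @export
combine_classifications <- function(a, b) {
  stopifnot(inherits(a, "score_result"), inherits(b, "score_result"),
            !is.null(a$label), !is.null(b$label))
  if (!setequal(a$sample_id, b$sample_id))
    stop("classifications cover different sample sets")
  b <- b[match(a$sample_id, b$sample_id), ]
  data.frame(sample_id = a$sample_id,
             label_a = a$label, label_b = b$label,
             label = ifelse(a$label == "hypoxic" & b$label == "hypoxic",
                            "hypoxic", "normoxic"),
             stringsAsFactors = FALSE)
}
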