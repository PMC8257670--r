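#' Stratified train/test split
#'
#' Splits samples into training and test sets balanced for the label
#' proportions. The total training size is `round(train_fraction * n)`,
#' allocated to the label strata by largest remainder so every stratum's
#' share is within one sample of `train_fraction` — this reproduces the
#' conventional 70:30 counts (e.g. 405 samples split 284/121) for any
#' near-balanced dichotomisation, including odd median splits.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels classification labels aligned with `sample_ids`.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed for the within-stratum draw.
#' @return list with `train` and `test` id vectors (disjoint,
#'   exhaustive).
#' @examples
#' sp <- split_train_test(sprintf("s%03d", 1:100),
#'                        rep(c("a", "b"), 50), seed = 1)
#' lengths(sp)
#' @export
split_train_test <- function(sample_ids, labels, train_fraction = 0.7,
                             seed = 1L) {
  stopifnot(length(sample_ids) == length(labels),
            !anyDuplicated(sample_ids),
            train_fraction > 0, train_fraction < 1)
  n <- length(sample_ids)
  n_train <- round(train_fraction * n)
  strata <- split(sample_ids, as.character(labels))
  quota <- vapply(strata, length, integer(1)) * train_fraction
  take <- floor(quota)
  rem <- n_train - sum(take)
  if (rem > 0) {
    frac_order <- order(quota - take, decreasing = TRUE)
    take[frac_order[seq_len(rem)]] <- take[frac_order[seq_len(rem)]] + 1
  } else if (rem < 0) {
    frac_order <- order(quota - take)
    take[frac_order[seq_len(-rem)]] <- take[frac_order[seq_len(-rem)]] - 1
  }
  train <- with_seed(seed, {
    unlist(mapply(function(ids, k) sample(ids, k), strata, take,
                  SIMPLIFY = FALSE), use.names = FALSE)
  })
  list(train = sample_ids[sample_ids %in% train],
       test = sample_ids[!sample_ids %in% train])
}

#' Drop features with no/low expression
#'
#' Removes features whose log2 value is exactly 0 (a raw count of 0 on
#' a log2(x+1) platform) in at least `max_zero_fraction` of the samples.
#'
#' @param matrix samples x features log2 expression matrix.
#' @param features feature ids to screen (default all columns).
#' @param max_zero_fraction zero-fraction at or above which a feature is
#'   dropped (default 0.5).
#' @return retained feature ids; attribute `"dropped"` lists removals.
#' @export
filter_unexpressed <- function(matrix, features = colnames(matrix),
                               max_zero_fraction = 0.5) {
  features <- intersect(features, matrix_features(matrix))
  zero_frac <- colMeans(matrix[, features, drop = FALSE] == 0)
  keep <- features[zero_frac < max_zero_fraction]
  attr(keep, "dropped") <- setdiff(features, keep)
  keep
}

#' Spearman correlation filter against a continuous anchor score
#'
#' Per feature: Spearman rho (average ranks for ties) against the
#' anchor scores, two-sided p-value from the asymptotic t
#' approximation, Benjamini-Hochberg adjustment across all tested
#' features, and selection at `q < q_threshold` with the sign of rho
#' recorded. Constant features have undefined rank correlation and are
#' excluded with a warning.
#'
#' @param X samples x features numeric matrix.
#' @param scores continuous per-sample anchor scores (same length/order
#'   as rows of `X`, or a `score_result`).
#' @param q_threshold FDR threshold (default 0.05).
#' @return a `correlation_filter` data frame (feature_id, rho, p_value,
#'   q_value, selected, sign).
#' @export
spearman_filter <- function(X, scores, q_threshold = 0.05) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (inherits(scores, "score_result")) {
    stopifnot(identical(scores$sample_id, rownames(X)))
    scores <- scores$score
  }
  stopifnot(length(scores) == nrow(X))
  constant <- apply(X, 2, function(v) sd(v) == 0)
  if (any(constant))
    warning("excluding constant feature(s): ",
            paste(colnames(X)[constant], collapse = ", "))
  feats <- colnames(X)[!constant]
  res <- lapply(feats, function(f) {
    ct <- suppressWarnings(
      cor.test(X[, f], scores, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  q <- p.adjust(res[, "p"], method = "BH")
  out <- data.frame(feature_id = feats, rho = res[, "rho"],
                    p_value = res[, "p"], q_value = q,
                    selected = q < q_threshold,
                    sign = ifelse(res[, "rho"] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  attr(out, "excluded_constant") <- colnames(X)[constant]
  class(out) <- c("correlation_filter", "data.frame")
  out
}

#' Derive a signed miRNA signature from seed features
#'
#' The supervised derivation chain, run on a training cohort with
#' matched mRNA and miRNA data: (1) score every sample with the unsigned
#' mRNA anchor signature and dichotomise at the cohort median into
#' hypoxic/normoxic labels; (2) run [boruta()] on the seed miRNAs
#' against those labels; (3) Spearman-filter the surviving miRNAs
#' (confirmed plus tentative by default) against the continuous anchor
#' scores; (4) assemble the significant miRNAs into a signed
#' [gene_signature()] — positively correlated features form the positive
#' set, negatively correlated the negative set.
#'
#' @param seed_features candidate (seed) miRNA ids.
#' @param mrna,mirna training samples x features log2 matrices with
#'   identical row order.
#' @param anchor unsigned [gene_signature()] of anchor mRNA genes.
#' @param name name for the derived signature.
#' @param n_trees,max_iter,alpha Boruta parameters (see [boruta()]).
#' @param q_threshold Spearman filter FDR threshold.
#' @param include_tentative pass Boruta-tentative features to the
#'   correlation filter (default TRUE); FALSE keeps confirmed only.
#' @param max_zero_fraction passed to [filter_unexpressed()].
#' @param seed integer seed for Boruta's forests.
#' @return a signed `gene_signature` with the per-feature Spearman
#'   statistics attached; attributes `"boruta"`,
#'   `"correlation_filter"`, `"anchor_scores"`, `"labels"` and
#'   `"seed_features_used"` hold every intermediate result.
#' @export
derive_signature <- function(seed_features, mrna, mirna, anchor,
                             name = "mirna-hypoxia",
                             n_trees = 500, max_iter = 1000, alpha = 0.05,
                             q_threshold = 0.05, include_tentative = TRUE,
                             max_zero_fraction = 0.5, seed = 1L) {
  stopifnot(identical(rownames(mrna), rownames(mirna)))
  usable <- filter_unexpressed(mirna, seed_features, max_zero_fraction)
  if (!length(usable)) stop("no seed features expressed in the cohort")
  anchor_scores <- score_mean_expression(mrna, anchor)
  labels <- classify_by_quantile(anchor_scores, "median")
  b <- boruta(mirna[, usable, drop = FALSE], labels$label,
              n_trees = n_trees, max_iter = max_iter, alpha = alpha,
              seed = seed)
  kept <- boruta_selected(b, if (include_tentative)
    c("confirmed", "tentative") else "confirmed")
  if (!length(kept)) {
    flt <- NULL
    sig <- NULL
  } else {
    flt <- spearman_filter(mirna[, kept, drop = FALSE], anchor_scores,
                           q_threshold = q_threshold)
    hit <- flt[flt$selected, ]
    sig <- if (nrow(hit))
      gene_signature(name,
                     positive = hit$feature_id[hit$sign == "+"],
                     negative = hit$feature_id[hit$sign == "-"],
                     provenance = "derived",
                     statistics = hit[, c("feature_id", "rho", "q_value")])
      else NULL
  }
  if (is.null(sig)) {
    # null outcome: no feature survived selection
    sig <- structure(list(name = name, positive = character(0),
                          negative = character(0), provenance = "derived",
                          statistics = NULL), class = "gene_signature")
  }
  attr(sig, "boruta") <- b
  attr(sig, "correlation_filter") <- flt
  attr(sig, "anchor_scores") <- anchor_scores
  attr(sig, "labels") <- labels
  attr(sig, "seed_features_used") <- usable
  sig
}
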