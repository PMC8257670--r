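#' Exclude features at or above the qPCR detection limit
#'
#' A target miRNA is removed from a cell line's comparison when its Ct is
#' >= `threshold` cycles, or undetermined (NA), in *every* replicate of
#' both conditions being compared — the permissive reading under which a
#' single detected replicate keeps the feature. Endogenous controls are
#' never removed.
#'
#' @param table a `ct_table` data frame (see [generate_ct_table()]).
#' @param threshold Ct detection threshold (default 30 cycles).
#' @param hypoxia_o2,normoxia_o2 the two O2 conditions compared, as
#'   percentages. If `hypoxia_o2` is NULL, a feature must be undetected
#'   in every replicate of every condition of a line to be removed.
#' @return the filtered `ct_table`; attribute `"excluded"` holds a log
#'   data frame (cell_line, feature_id) of removed features, and
#'   attribute `"exclusion_rule"` records the rule applied.
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 24))
#' kept <- exclude_low_expression(sim$ct_table, hypoxia_o2 = 0.2)
#' attr(kept, "excluded")
#' @export
exclude_low_expression <- function(table, threshold = 30,
                                   hypoxia_o2 = NULL,
                                   normoxia_o2 = max(table$o2_percent)) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) return(table)
  tab <- table
  conds <- if (is.null(hypoxia_o2)) unique(tab$o2_percent)
           else c(normoxia_o2, hypoxia_o2)
  sub <- tab[tab$o2_percent %in% conds & tab$feature_class == "target", ]
  undetected <- is.na(sub$ct) | sub$ct >= threshold
  drop <- stats::aggregate(undetected,
                           by = list(cell_line = sub$cell_line,
                                     feature_id = sub$feature_id),
                           FUN = all)
  drop <- drop[drop$x, c("cell_line", "feature_id")]
  if (nrow(drop)) {
    key <- paste(tab$cell_line, tab$feature_id)
    tab <- tab[!(key %in% paste(drop$cell_line, drop$feature_id) &
                   tab$feature_class == "target"), ]
    rownames(tab) <- NULL
  }
  # warn when a feature is missing replicates in the compared conditions
  n_rep <- table(paste(sub$cell_line, sub$feature_id))
  expected <- max(n_rep)
  if (length(n_rep) && any(n_rep < expected))
    warning(sum(n_rep < expected),
            " feature(s) have missing replicates; judged on present replicates")
  attr(tab, "excluded") <- drop
  attr(tab, "exclusion_rule") <- sprintf(
    "Ct >= %g or undetermined in all replicates of %s", threshold,
    if (is.null(hypoxia_o2)) "all conditions"
    else sprintf("both %g%% and %g%% O2", normoxia_o2, hypoxia_o2))
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Choose the most stable endogenous-control subset
#'
#' Evaluates every non-empty subset of the candidate controls and
#' returns the one whose per-sample geometric-mean Ct has the smallest
#' standard deviation across the samples of the experiment (or of one
#' cell line when `scope = "cell_line"`). Ties favour the larger subset,
#' then lexicographic order of the sorted ids — so when all controls are
#' equally stable the full panel is used.
#'
#' @param table a `ct_table`.
#' @param candidates control feature ids to consider; defaults to every
#'   feature with `feature_class == "control"`.
#' @param scope evaluate stability across the whole experiment
#'   (default) or separately per cell line (returns a named list).
#' @return character vector of selected control ids (or a named list of
#'   them when `scope = "cell_line"`), with attribute `"stability_sd"`.
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 24))
#' select_controls(sim$ct_table)
#' @export
select_controls <- function(table, candidates = NULL,
                            scope = c("experiment", "cell_line")) {
  scope <- match.arg(scope)
  ctrl <- table[table$feature_class == "control", ]
  if (is.null(candidates)) candidates <- sort(unique(ctrl$feature_id))
  if (!length(candidates)) stop("no candidate control features")
  if (!all(candidates %in% ctrl$feature_id))
    stop("candidates must be control features present in the table")
  if (scope == "cell_line") {
    res <- lapply(split(ctrl, ctrl$cell_line), select_controls_one, candidates)
    return(res)
  }
  select_controls_one(ctrl, candidates)
}

select_controls_one <- function(ctrl, candidates) {
  sample_key <- paste(ctrl$cell_line, ctrl$o2_percent, ctrl$replicate)
  wide <- tapply(ctrl$ct, list(sample_key, ctrl$feature_id), mean)
  wide <- wide[, candidates, drop = FALSE]
  if (anyNA(wide))
    stop("every candidate control must be measured in every sample")
  subsets <- unlist(lapply(seq_along(candidates), function(k)
    combn(sort(candidates), k, simplify = FALSE)), recursive = FALSE)
  sds <- vapply(subsets, function(s) {
    gm <- apply(wide[, s, drop = FALSE], 1, geometric_mean)
    sd(gm)
  }, numeric(1))
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  ord <- order(sds, -sizes, keys)
  best <- subsets[[ord[1]]]
  attr(best, "stability_sd") <- sds[ord[1]]
  best
}

#' Normalise Ct values to the geometric mean of endogenous controls
#'
#' Per sample (cell line x condition x replicate), computes
#' `delta_ct = Ct(target) - reference(controls)`. The default reference
#' is the geometric mean of the control *abundances* (2^-Ct), i.e. the
#' arithmetic mean of the control Ct values — the geNorm convention,
#' which makes delta-Ct exactly invariant to a constant Ct shift of the
#' whole sample. `control_mean = "geomean_ct"` instead takes the
#' geometric mean of the Ct values themselves, as some array-card
#' protocols word it; that variant is only approximately
#' shift-invariant. Undetermined target Cts propagate as undetermined
#' delta-Cts.
#'
#' @param table a `ct_table`.
#' @param controls control feature ids, present in every sample.
#' @param control_mean control-averaging convention (see above).
#' @return data frame of target rows with a `delta_ct` column.
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 24))
#' dct <- normalize_delta_ct(sim$ct_table, c("RNU48", "RNU44", "U6snRNA"))
#' head(dct)
#' @export
normalize_delta_ct <- function(table, controls,
                               control_mean = c("geomean_abundance",
                                                "geomean_ct")) {
  control_mean <- match.arg(control_mean)
  stopifnot(length(controls) >= 1)
  ctrl <- table[table$feature_class == "control" &
                  table$feature_id %in% controls, ]
  if (any(ctrl$ct <= 0, na.rm = TRUE) || anyNA(ctrl$ct))
    stop("control Ct values must be positive and determined")
  sample_key <- function(d) paste(d$cell_line, d$o2_percent, d$replicate,
                                  sep = "\r")
  avg <- if (control_mean == "geomean_ct") geometric_mean else mean
  ref <- tapply(ctrl$ct, sample_key(ctrl), avg)
  if (length(unique(table(sample_key(ctrl)))) > 1 ||
      unique(table(sample_key(ctrl))) != length(controls))
    stop("every control must be measured exactly once per sample")
  tgt <- table[table$feature_class == "target", ]
  key <- sample_key(tgt)
  if (!all(key %in% names(ref)))
    stop("controls missing for some samples")
  tgt$delta_ct <- tgt$ct - as.vector(ref[key])
  rownames(tgt) <- NULL
  attr(tgt, "control_features") <- sort(controls)
  attr(tgt, "control_mean") <- control_mean
  tgt
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `ddct = mean(hypoxia delta-Cts) - mean(normoxia delta-Cts)` and
#' `fold_change = 2^(-ddct)`, so a 1-cycle drop under hypoxia is a
#' two-fold induction. At least two determined replicates are required
#' on each side; otherwise the feature is flagged not evaluable.
#'
#' @param norm_reps,hyp_reps delta-Ct replicate values for the normoxic
#'   and hypoxic condition (NAs dropped).
#' @return list with `delta_delta_ct`, `fold_change` and `evaluable`.
#' @examples
#' delta_delta_ct(c(9, 9, 9), c(8, 8, 8))  # fold change 2
#' @export
delta_delta_ct <- function(norm_reps, hyp_reps) {
  norm_reps <- norm_reps[!is.na(norm_reps)]
  hyp_reps <- hyp_reps[!is.na(hyp_reps)]
  if (length(norm_reps) < 2 || length(hyp_reps) < 2)
    return(list(delta_delta_ct = NA_real_, fold_change = NA_real_,
                evaluable = FALSE))
  ddct <- mean(hyp_reps) - mean(norm_reps)
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct), evaluable = TRUE)
}

#' Welch's unequal-variance t test on delta-Ct replicates
#'
#' Two-sided p-value with Welch–Satterthwaite degrees of freedom. The
#' degenerate all-constant cases follow the natural limits: both groups
#' constant and equal means gives p = 1; constant and unequal means
#' gives p = 0.
#'
#' @param x,y replicate values for the two conditions (NAs dropped; at
#'   least two determined values per group).
#' @return two-sided p-value.
#' @examples
#' welch_test(c(9.1, 8.9, 9.0), c(7.6, 7.4, 7.5))
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welch_test needs at least two determined replicates per group")
  if (var(x) == 0 && var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  t.test(x, y, var.equal = FALSE)$p.value
}

#' Call differentially induced features
#'
#' Flags a feature as induced when `p_value < p_threshold` and
#' `fold_change > fc_threshold` (both strict, no multiple-testing
#' correction — the screen convention for small-replicate array cards,
#' where an FDR cut-off is too stringent given intra-group variation).
#'
#' @param results data frame with `p_value` and `fold_change` columns
#'   (e.g. from [qpcr_differential_expression()]).
#' @param p_threshold,fc_threshold decision thresholds (defaults 0.05
#'   and 1.0).
#' @return `results` with an `induced` logical column.
#' @export
call_differential <- function(results, p_threshold = 0.05, fc_threshold = 1.0) {
  stopifnot(all(c("p_value", "fold_change") %in% names(results)))
  results$induced <- !is.na(results$p_value) & !is.na(results$fold_change) &
    results$p_value < p_threshold & results$fold_change > fc_threshold
  attr(results, "thresholds") <- c(p = p_threshold, fc = fc_threshold)
  results
}

#' Per-cell-line delta-delta-Ct differential expression
#'
#' Runs the full qPCR analysis for one hypoxic condition against
#' normoxia, separately in each cell line: detection-limit exclusion,
#' control selection (unless `controls` is given), geometric-mean
#' normalisation, delta-delta-Ct fold changes, Welch tests, and the
#' induced call.
#'
#' @param table a `ct_table`.
#' @param hypoxia_o2 hypoxic condition to compare (percent O2).
#' @param normoxia_o2 normoxic condition (default: the maximum present).
#' @param controls control feature ids; NULL selects the most stable
#'   subset with [select_controls()].
#' @param control_scope scope for automatic control selection.
#' @param control_mean control-averaging convention, see
#'   [normalize_delta_ct()].
#' @param ct_threshold detection-limit Ct for [exclude_low_expression()].
#' @param p_threshold,fc_threshold thresholds for [call_differential()].
#' @return a `differential_result` data frame with one row per (cell
#'   line, feature): mean delta-Cts, `delta_delta_ct`, `fold_change`,
#'   `p_value`, `induced`. Attributes record controls used and excluded
#'   features.
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 48))
#' res <- qpcr_differential_expression(sim$ct_table, hypoxia_o2 = 0.2)
#' head(res[res$induced, ])
#' @export
qpcr_differential_expression <- function(table, hypoxia_o2,
                                         normoxia_o2 = max(table$o2_percent),
                                         controls = NULL,
                                         control_scope = c("experiment",
                                                           "cell_line"),
                                         control_mean = c("geomean_abundance",
                                                          "geomean_ct"),
                                         ct_threshold = 30,
                                         p_threshold = 0.05,
                                         fc_threshold = 1.0) {
  control_scope <- match.arg(control_scope)
  control_mean <- match.arg(control_mean)
  stopifnot(hypoxia_o2 %in% table$o2_percent,
            normoxia_o2 %in% table$o2_percent)
  tab <- table[table$o2_percent %in% c(hypoxia_o2, normoxia_o2), ]
  tab <- exclude_low_expression(tab, threshold = ct_threshold,
                                hypoxia_o2 = hypoxia_o2,
                                normoxia_o2 = normoxia_o2)
  excluded <- attr(tab, "excluded")
  if (is.null(controls)) {
    sel <- select_controls(tab, scope = control_scope)
    ctrl_by_line <- if (control_scope == "experiment")
      setNames(rep(list(sel), length(unique(tab$cell_line))),
               unique(tab$cell_line)) else sel
  } else {
    ctrl_by_line <- setNames(rep(list(controls),
                                 length(unique(tab$cell_line))),
                             unique(tab$cell_line))
  }
  out <- list()
  for (cl in names(ctrl_by_line)) {
    sub <- tab[tab$cell_line == cl, ]
    if (!all(c(hypoxia_o2, normoxia_o2) %in% sub$o2_percent)) next
    dct <- normalize_delta_ct(sub, ctrl_by_line[[cl]], control_mean)
    for (f in unique(dct$feature_id)) {
      nr <- dct$delta_ct[dct$feature_id == f & dct$o2_percent == normoxia_o2]
      hr <- dct$delta_ct[dct$feature_id == f & dct$o2_percent == hypoxia_o2]
      dd <- delta_delta_ct(nr, hr)
      p <- if (dd$evaluable) welch_test(nr, hr) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        feature_id = f, cell_line = cl, o2_percent = hypoxia_o2,
        mean_dct_normoxia = mean(nr, na.rm = TRUE),
        mean_dct_hypoxia = mean(hr, na.rm = TRUE),
        delta_delta_ct = dd$delta_delta_ct, fold_change = dd$fold_change,
        p_value = p, evaluable = dd$evaluable, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- call_differential(res, p_threshold, fc_threshold)
  attr(res, "controls") <- ctrl_by_line
  attr(res, "excluded") <- excluded
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Select seed miRNAs induced in multiple cell lines
#'
#' A feature becomes a seed when it is called induced in at least
#' `min_lines` cell lines at the stated hypoxic condition. The attribute
#' `"line_counts"` reports, for each threshold 2..max, how many features
#' clear it.
#'
#' @param results a `differential_result` (one hypoxic condition) or the
#'   output of [call_differential()].
#' @param min_lines minimum number of cell lines (default 2).
#' @return sorted character vector of seed feature ids with attributes
#'   `"induced_lines"` (per-feature counts) and `"line_counts"`.
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 48))
#' res <- qpcr_differential_expression(sim$ct_table, hypoxia_o2 = 0.2)
#' seeds <- select_seeds(res)
#' attr(seeds, "line_counts")
#' @export
select_seeds <- function(results, min_lines = 2L) {
  stopifnot(all(c("feature_id", "cell_line", "induced") %in% names(results)))
  hits <- results[results$induced, ]
  counts <- table(hits$feature_id)
  seeds <- sort(names(counts)[counts >= min_lines])
  n_lines <- length(unique(results$cell_line))
  line_counts <- vapply(2:max(2L, n_lines),
                        function(k) sum(counts >= k), integer(1))
  names(line_counts) <- paste0(">=", 2:max(2L, n_lines))
  attr(seeds, "induced_lines") <- counts
  attr(seeds, "line_counts") <- line_counts
  seeds
}
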