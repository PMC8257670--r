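#' Boruta all-relevant feature selection
#'
#' Shadow-feature wrapper around a random forest: each iteration the
#' real features are joined by one independently shuffled "shadow" copy
#' per original feature, a seeded forest is fitted on the combined
#' matrix, and a real feature scores a *hit* when its importance
#' exceeds the maximum shadow importance of that iteration. Importance
#' is the Z-scored out-of-bag permutation importance (mean accuracy
#' decrease divided by its standard error — the classic Boruta
#' measure): in-bag impurity importance rewards features whose chance
#' correlation with the outcome is merely the largest among many, and
#' an importance that overfits the sample in that way confirms noise
#' features at well above the nominal rate. After every iteration each
#' undecided feature's hit count
#' is tested against Binomial(iterations, 1/2), two-sided with
#' Bonferroni correction over the currently undecided features:
#' significantly more hits confirms the feature, significantly fewer
#' rejects it and removes it from the model. Confirmed features stay in
#' the forest; decisions are final. Iteration stops at `max_iter` or
#' when nothing is undecided; survivors are left `tentative`.
#'
#' @param X samples x features numeric matrix with column names.
#' @param y binary outcome (two-level factor or coercible); balanced
#'   class weights are used in the forest.
#' @param n_trees trees per forest (default 500).
#' @param max_iter maximum iterations (default 1000).
#' @param alpha significance level of the binomial test (default 0.05).
#' @param seed integer seed; forests are seeded per iteration from it.
#' @return a `boruta_result`: `decision` (named factor
#'   confirmed/tentative/rejected), `hits`, `iteration_decided`,
#'   `importance_history` (iterations x features, NA once removed),
#'   `zscore_history` (importances additionally standardised against
#'   the shadow mean/sd per iteration — reporting only, decisions
#'   compare importances to shadowMax), `shadow_stats` (min/mean/max shadow
#'   importance per iteration), `iterations_run`, `params`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 60, 10,
#'             dimnames = list(NULL, paste0("f", 1:10)))
#' y <- rbinom(60, 1, plogis(2 * X[, 1]))
#' b <- boruta(X, y, n_trees = 100, max_iter = 25, seed = 1)
#' table(b$decision)
#' @export
boruta <- function(X, y, n_trees = 500, max_iter = 1000, alpha = 0.05,
                   seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) >= 2)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("outcome must have two classes")
  y <- droplevels(y)
  features <- colnames(X)
  p <- length(features)
  decision <- setNames(rep("tentative", p), features)
  hits <- setNames(rep(0L, p), features)
  decided_at <- setNames(rep(NA_integer_, p), features)
  imp_hist <- list()
  z_hist <- list()
  shadow_stats <- list()
  cw <- as.numeric(length(y) / (2 * table(y)))  # balanced class weights
  iter <- 0L
  while (iter < max_iter && any(decision == "tentative")) {
    iter <- iter + 1L
    surviving <- features[decision != "rejected"]
    Xs <- X[, surviving, drop = FALSE]
    # one shuffled shadow per *original* feature: rejected features leave
    # the forest, but the chance bar stays the maximum over p null
    # copies, so late-stage hits are judged against the same selection
    # burden as early ones (a shrinking shadow pool lets features with
    # persistent chance correlation clear a collapsed bar)
    shadow <- with_seed(sub_seed(seed, 2L * iter), {
      apply(X, 2, sample)
    })
    colnames(shadow) <- paste0("shadow_", features)
    fit <- ranger::ranger(x = cbind(Xs, shadow), y = y,
                          num.trees = n_trees, importance = "permutation",
                          scale.permutation.importance = TRUE,
                          class.weights = cw,
                          seed = sub_seed(seed, 2L * iter + 1L),
                          num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
    real_imp <- imp[surviving]
    shadow_imp <- imp[colnames(shadow)]
    s_max <- max(shadow_imp)
    s_mean <- mean(shadow_imp)
    s_sd <- sd(shadow_imp)
    shadow_stats[[iter]] <- c(min = min(shadow_imp), mean = s_mean,
                              max = s_max, sd = s_sd)
    row <- setNames(rep(NA_real_, p), features)
    row[surviving] <- real_imp
    imp_hist[[iter]] <- row
    zrow <- setNames(rep(NA_real_, p), features)
    zrow[surviving] <- if (is.finite(s_sd) && s_sd > 0)
      (real_imp - s_mean) / s_sd else NA_real_
    z_hist[[iter]] <- zrow
    hit_now <- surviving[real_imp > s_max]
    hits[hit_now] <- hits[hit_now] + 1L
    undecided <- features[decision == "tentative"]
    m <- length(undecided)
    for (f in undecided) {
      p_more <- pbinom(hits[f] - 1L, iter, 0.5, lower.tail = FALSE)
      p_less <- pbinom(hits[f], iter, 0.5)
      p2 <- min(1, 2 * min(p_more, p_less))
      if (p2 * m < alpha) {
        decision[f] <- if (hits[f] > iter / 2) "confirmed" else "rejected"
        decided_at[f] <- iter
      }
    }
  }
  imp_hist <- if (length(imp_hist)) do.call(rbind, imp_hist)
    else matrix(numeric(0), 0, p, dimnames = list(NULL, features))
  z_hist <- if (length(z_hist)) do.call(rbind, z_hist)
    else matrix(numeric(0), 0, p, dimnames = list(NULL, features))
  shadow_stats <- if (length(shadow_stats)) do.call(rbind, shadow_stats)
    else matrix(numeric(0), 0, 4,
                dimnames = list(NULL, c("min", "mean", "max", "sd")))
  structure(list(
    decision = factor(decision, levels = c("confirmed", "tentative",
                                           "rejected")),
    hits = hits, iteration_decided = decided_at,
    importance_history = imp_hist, zscore_history = z_hist,
    shadow_stats = shadow_stats, iterations_run = iter,
    params = list(n_trees = n_trees, max_iter = max_iter, alpha = alpha,
                  correction = "bonferroni", seed = seed)),
    class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat("Boruta run:", x$iterations_run, "iterations\n")
  cat("  confirmed:", tab[["confirmed"]],
      " tentative:", tab[["tentative"]],
      " rejected:", tab[["rejected"]], "\n")
  invisible(x)
}

#' Extract features by Boruta decision
#'
#' @param result a [boruta()] result.
#' @param which decisions to keep (default confirmed + tentative, the
#'   inclusive convention when tentative features are carried into a
#'   downstream filter).
#' @return character vector of feature ids.
#' @export
boruta_selected <- function(result,
                            which = c("confirmed", "tentative")) {
  stopifnot(inherits(result, "boruta_result"))
  names(result$decision)[result$decision %in% which]
}

#' Importance boxplots of a Boruta run
#'
#' Z-score boxplots per feature (importance standardised against the
#' shadow mean/sd of each iteration), coloured green/yellow/red for
#' confirmed/tentative/rejected, alongside blue boxes for the minimum,
#' mean and maximum shadow importances.
#'
#' @param x a [boruta()] result.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the plotted z-score matrix.
#' @export
plot_boruta <- function(x, ...) {
  stopifnot(inherits(x, "boruta_result"))
  if (x$iterations_run == 0) stop("nothing to plot: no iterations run")
  z <- x$zscore_history
  sh <- x$shadow_stats
  s <- ifelse(is.finite(sh[, "sd"]) & sh[, "sd"] > 0, sh[, "sd"], NA)
  zsh <- (sh[, c("min", "mean", "max"), drop = FALSE] - sh[, "mean"]) / s
  ord <- order(colMeans(z, na.rm = TRUE))
  cols <- c(confirmed = "forestgreen", tentative = "gold",
            rejected = "firebrick")[as.character(x$decision[ord])]
  dat <- c(list(shadowMin = zsh[, "min"], shadowMean = zsh[, "mean"],
                shadowMax = zsh[, "max"]),
           lapply(colnames(z)[ord], function(f) z[, f]))
  names(dat) <- c("shadowMin", "shadowMean", "shadowMax", colnames(z)[ord])
  graphics::boxplot(dat, las = 2, col = c(rep("steelblue", 3), cols),
                    ylab = "importance (z-score vs shadows)",
                    cex.axis = 0.6, ...)
  invisible(z)
}

#' Rank features by random-forest Gini importance
#'
#' Mean impurity-decrease importance from a single seeded forest,
#' sorted decreasing. Deterministic given the seed.
#'
#' @param X samples x features numeric matrix with column names.
#' @param y binary outcome.
#' @param n_trees trees (default 500).
#' @param seed forest seed.
#' @return data frame (feature_id, importance, rank), best first.
#' @export
rank_gini <- function(X, y, n_trees = 500, seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("outcome must have two classes")
  cw <- as.numeric(length(y) / (2 * table(y)))
  fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                        importance = "impurity", class.weights = cw,
                        seed = seed, num.threads = 1, verbose = FALSE)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  data.frame(feature_id = names(imp), importance = unname(imp),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}
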