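# Independent oracle implementations used to cross-check the package.
# These are written from the textbook formulas and deliberately share no
# code with the implementation under test.

# Welch two-sample t: statistic, Welch-Satterthwaite df, two-sided p.
welch_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - sum(x) / nx)^2) / (nx - 1)
  vy <- sum((y - sum(y) / ny)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (sum(x) / nx - sum(y) / ny) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# average ranks without rank(): #smaller + (#tied + 1)/2
rank_oracle <- function(v) {
  vapply(v, function(z) sum(v < z) + (sum(v == z) + 1) / 2, numeric(1))
}

# Spearman rho as Pearson correlation of average ranks, via raw sums
spearman_rho_oracle <- function(x, y) {
  rx <- rank_oracle(x); ry <- rank_oracle(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

# rank-separation AUC of a score against binary truth
auc_oracle <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small Ct table builder for hand-crafted qPCR cases: one cell line,
# two conditions, explicit replicate values
toy_ct_table <- function(target_norm, target_hyp,
                         control_norm = list(RNU48 = c(16, 16, 16)),
                         control_hyp = control_norm,
                         cell_line = "T24") {
  rows <- list()
  add <- function(o2, feats, class) {
    for (f in names(feats)) {
      v <- feats[[f]]
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_line = cell_line, o2_percent = o2,
        replicate = seq_along(v), feature_id = f, feature_class = class,
        ct = v, stringsAsFactors = FALSE)
    }
  }
  add(21, target_norm, "target");  add(21, control_norm, "control")
  add(0.2, target_hyp, "target");  add(0.2, control_hyp, "control")
  tab <- do.call(rbind, rows)
  class(tab) <- c("ct_table", "data.frame")
  tab
}

# compact simulation configs for fast module tests
small_sim <- function(seed = 1, ...) {
  args <- list(seed = seed, n_target_features = 48, n_planted_induced = 16,
               cohort_n = 120, anchor_gene_count = 40, filler_gene_count = 20,
               trial_n_per_arm = 60)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
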