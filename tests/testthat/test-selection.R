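test_that("stratified splits honour the 70:30 convention", {
  sp <- split_train_test(sprintf("s%03d", 1:100), rep(c("a", "b"), 50),
                         seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  lab <- setNames(rep(c("a", "b"), 50), sprintf("s%03d", 1:100))
  expect_equal(sum(lab[sp$train] == "a"), 35)
  # degenerate single-label input still splits 70:30
  sp1 <- split_train_test(sprintf("s%03d", 1:100), rep("a", 100), seed = 1)
  expect_length(sp1$train, 70)
  # the canonical 405-sample cohort splits 284/121 for a median split
  sp405 <- split_train_test(sprintf("s%03d", 1:405),
                            rep(c("hyp", "norm"), c(202, 203)), seed = 3)
  expect_length(sp405$train, 284)
  expect_length(sp405$test, 121)
  expect_setequal(c(sp405$train, sp405$test), sprintf("s%03d", 1:405))
  expect_length(intersect(sp405$train, sp405$test), 0)
})

test_that("unexpressed features are dropped at the zero-fraction rule", {
  m <- cbind(allzero = rep(0, 10), full = rnorm(10) + 5,
             half = rep(c(0, 1), 5), most = c(rep(0, 4), rnorm(6) + 5))
  rownames(m) <- paste0("s", 1:10)
  kept <- filter_unexpressed(m)
  expect_false("allzero" %in% kept)
  expect_true("full" %in% kept)
  expect_false("half" %in% kept)   # exactly half zero: dropped (>= rule)
  expect_true("most" %in% kept)
  expect_setequal(attr(kept, "dropped"), c("allzero", "half"))
})

test_that("Spearman filter agrees with the rank-formula oracle", {
  set.seed(17)
  scores <- rnorm(30)
  X <- cbind(exact = scores, mono = -exp(scores),
             noise = rnorm(30), tied = round(scores * 2) / 2)
  rownames(X) <- paste0("s", 1:30)
  flt <- spearman_filter(X, scores)
  expect_equal(flt$rho[flt$feature_id == "exact"], 1)
  expect_equal(flt$rho[flt$feature_id == "mono"], -1)
  for (f in colnames(X))
    expect_equal(flt$rho[flt$feature_id == f],
                 spearman_rho_oracle(X[, f], scores), tolerance = 1e-10)
  # constant feature excluded with a warning
  Xc <- cbind(X, flat = rep(1, 30))
  expect_warning(flt2 <- spearman_filter(Xc, scores), "constant")
  expect_false("flat" %in% flt2$feature_id)
  # selection invariant under strictly monotone transforms of the scores
  flt_up <- spearman_filter(X, exp(scores))
  expect_equal(flt$rho, flt_up$rho, tolerance = 1e-12)
  expect_identical(flt$selected, flt_up$selected)
  flt_dn <- spearman_filter(X, -scores^3)
  expect_identical(flt$selected, flt_dn$selected)
  expect_equal(flt$rho, -flt_dn$rho, tolerance = 1e-12)
})

test_that("boruta confirms a planted predictor and honours max_iter", {
  set.seed(5)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  X <- cbind(signal = y + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  for (s in 1:3) {
    b <- boruta(X, y, n_trees = 150, max_iter = 30, seed = s)
    expect_identical(as.character(b$decision["signal"]), "confirmed")
    expect_lte(b$iteration_decided["signal"], 30)
  }
  # decisions partition the feature set and histories are recorded
  b <- boruta(X, y, n_trees = 150, max_iter = 30, seed = 9)
  expect_identical(sort(names(b$decision)), sort(colnames(X)))
  expect_equal(nrow(b$importance_history), b$iterations_run)
  expect_equal(nrow(b$shadow_stats), b$iterations_run)
  # rejected features stay out: no importance recorded after rejection
  rej <- names(b$decision)[b$decision == "rejected"]
  for (f in rej) {
    it <- b$iteration_decided[f]
    if (it < b$iterations_run)
      expect_true(all(is.na(b$importance_history[(it + 1):b$iterations_run, f])))
  }
  # max_iter = 0 leaves everything tentative
  b0 <- boruta(X, y, n_trees = 50, max_iter = 0, seed = 1)
  expect_equal(b0$iterations_run, 0)
  expect_true(all(b0$decision == "tentative"))
  expect_error(boruta(X, rep(1, n), seed = 1), "two classes")
})

test_that("Gini ranking is deterministic and finds the planted predictor", {
  set.seed(8)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  X <- cbind(signal = y + rnorm(n, 0, 0.4),
             matrix(rnorm(n * 15), n, 15,
                    dimnames = list(NULL, paste0("noise", 1:15))))
  r1 <- rank_gini(X, y, n_trees = 300, seed = 4)
  r2 <- rank_gini(X, y, n_trees = 300, seed = 4)
  expect_identical(r1, r2)
  expect_identical(r1$feature_id[1], "signal")
  expect_equal(r1$rank, seq_len(ncol(X)))
  expect_true(all(diff(r1$importance) <= 0))
})

test_that("derived signatures are confined to the seed features", {
  cfg <- small_sim(seed = 6)
  cohort <- generate_cohort(cfg)
  gt <- cohort$ground_truth$signature_truth
  seeds <- c(gt$positive, gt$negative,
             sample(setdiff(colnames(cohort$mirna),
                            c(gt$positive, gt$negative)), 6))
  sig <- derive_signature(seeds, cohort$mrna, cohort$mirna,
                          cohort$anchor_signature,
                          n_trees = 300, max_iter = 60, seed = 2)
  members <- c(sig$positive, sig$negative)
  expect_true(all(members %in% seeds))
  expect_gt(length(members), 0)
  # intermediates attached for audit
  expect_s3_class(attr(sig, "boruta"), "boruta_result")
  expect_s3_class(attr(sig, "correlation_filter"), "correlation_filter")
})

test_that("a null cohort yields an empty or near-empty signature", {
  cfg <- small_sim(seed = 13, mirna_effect_log2 = 0)
  cohort <- generate_cohort(cfg)
  gt <- cohort$ground_truth$signature_truth
  seeds <- c(gt$positive, gt$negative)
  sig <- derive_signature(seeds, cohort$mrna, cohort$mirna,
                          cohort$anchor_signature,
                          n_trees = 300, max_iter = 60, seed = 2)
  expect_lte(length(sig), 2)
})
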