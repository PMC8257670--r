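test_that("detection-limit exclusion follows the all-replicates rule", {
  tab <- toy_ct_table(
    target_norm = list(gone = c(31, 32, 33), stays = c(31, 31, 31),
                       fine = c(25, 25, 25)),
    target_hyp = list(gone = c(30, 31, 35), stays = c(29, 31, 31),
                      fine = c(24, 24, 24)))
  out <- exclude_low_expression(tab, hypoxia_o2 = 0.2)
  expect_false("gone" %in% out$feature_id)     # >= 30 in all six replicates
  expect_true("stays" %in% out$feature_id)     # one replicate below 30
  expect_true("fine" %in% out$feature_id)
  expect_equal(attr(out, "excluded")$feature_id, "gone")
  # controls are never removed even at high Ct
  tab2 <- toy_ct_table(target_norm = list(a = c(25, 25, 25)),
                       target_hyp = list(a = c(24, 24, 24)),
                       control_norm = list(RNU48 = c(31, 31, 31)))
  out2 <- exclude_low_expression(tab2, hypoxia_o2 = 0.2)
  expect_true("RNU48" %in% out2$feature_id)
  # undetermined (NA) counts as undetected
  tab3 <- toy_ct_table(target_norm = list(a = c(NA, NA, NA)),
                       target_hyp = list(a = c(NA, 31, 33)))
  expect_false("a" %in% exclude_low_expression(tab3, hypoxia_o2 = 0.2)$feature_id)
  # empty table is returned unchanged
  empty <- tab[0, ]
  expect_identical(nrow(exclude_low_expression(empty)), 0L)
})

test_that("control selection matches brute-force subset enumeration", {
  set.seed(9)
  # crafted: 3 controls over 12 samples with different stabilities
  n <- 12
  vals <- list(RNU48 = 16 + rnorm(n, 0, 0.05),
               RNU44 = 17 + rnorm(n, 0, 0.6),
               U6snRNA = 15 + rnorm(n, 0, 0.3))
  rows <- do.call(rbind, lapply(names(vals), function(f)
    data.frame(cell_line = "T24", o2_percent = rep(c(21, 0.2), each = n / 2),
               replicate = rep(1:(n / 2), 2), feature_id = f,
               feature_class = "control", ct = vals[[f]])))
  class(rows) <- c("ct_table", "data.frame")
  picked <- select_controls(rows)
  # oracle: enumerate all 7 subsets explicitly
  ids <- names(vals)
  subsets <- list(ids[1], ids[2], ids[3], ids[1:2], ids[c(1, 3)],
                  ids[2:3], ids)
  sds <- sapply(subsets, function(s) {
    gm <- exp(colMeans(log(do.call(rbind, vals[s]))))
    sd(gm)
  })
  expect_setequal(picked, subsets[[which.min(sds)]])

  # a perfectly constant control beats noisy ones
  vals2 <- list(A = rep(16, n), B = 16 + rnorm(n, 0, 0.4),
                C = 16 + rnorm(n, 0, 0.4))
  rows2 <- do.call(rbind, lapply(names(vals2), function(f)
    data.frame(cell_line = "T24", o2_percent = rep(c(21, 0.2), each = n / 2),
               replicate = rep(1:(n / 2), 2), feature_id = f,
               feature_class = "control", ct = vals2[[f]])))
  class(rows2) <- c("ct_table", "data.frame")
  picked2 <- select_controls(rows2)
  expect_equal(as.character(picked2), "A")
  expect_equal(attr(picked2, "stability_sd"), 0)

  # all controls identical across samples: tie broken by larger subset
  vals3 <- list(A = rep(16, n), B = rep(17, n), C = rep(15, n))
  rows3 <- do.call(rbind, lapply(names(vals3), function(f)
    data.frame(cell_line = "T24", o2_percent = rep(c(21, 0.2), each = n / 2),
               replicate = rep(1:(n / 2), 2), feature_id = f,
               feature_class = "control", ct = vals3[[f]])))
  class(rows3) <- c("ct_table", "data.frame")
  expect_setequal(select_controls(rows3), c("A", "B", "C"))
})

test_that("delta-Ct normalisation reproduces hand arithmetic", {
  tab <- toy_ct_table(target_norm = list(tgt = c(25, 25, 25)),
                      target_hyp = list(tgt = c(23.5, 23.5, 23.5)),
                      control_norm = list(A = c(16, 16, 16),
                                          B = c(16, 16, 16),
                                          C = c(16, 16, 16)))
  dct <- normalize_delta_ct(tab, c("A", "B", "C"))
  expect_equal(unique(dct$delta_ct[dct$o2_percent == 21]), 9)
  # geometric-mean-of-Ct variant against the hand value
  tab2 <- toy_ct_table(target_norm = list(tgt = c(25, 25, 25)),
                       target_hyp = list(tgt = c(23.5, 23.5, 23.5)),
                       control_norm = list(A = c(15, 15, 15),
                                           B = c(16, 16, 16),
                                           C = c(17, 17, 17)))
  gm <- (15 * 16 * 17)^(1 / 3)
  dct2 <- normalize_delta_ct(tab2, c("A", "B", "C"),
                             control_mean = "geomean_ct")
  expect_equal(unique(dct2$delta_ct[dct2$o2_percent == 21]), 25 - gm,
               tolerance = 1e-12)
  expect_equal(geometric_mean(c(15, 16, 17)), gm, tolerance = 1e-12)
  # undetermined target propagates; non-positive control errors
  tab$ct[tab$feature_id == "tgt"][1] <- NA
  expect_true(is.na(normalize_delta_ct(tab, c("A", "B", "C"))$delta_ct[1]))
  tab$ct[tab$feature_id == "A"][1] <- -1
  expect_error(normalize_delta_ct(tab, c("A", "B", "C")), "positive")
})

test_that("delta-delta-Ct and fold change follow 2^(-ddCt)", {
  expect_equal(delta_delta_ct(c(9, 9, 9), c(9, 9, 9)),
               list(delta_delta_ct = 0, fold_change = 1, evaluable = TRUE))
  r <- delta_delta_ct(c(9, 9, 9), c(8, 8, 8))
  expect_equal(r$delta_delta_ct, -1)
  expect_equal(r$fold_change, 2)
  r2 <- delta_delta_ct(c(9.1, 8.9, 9.0), c(7.6, 7.4, 7.5))
  expect_equal(r2$fold_change, 2^1.5, tolerance = 1e-12)
  expect_equal(r2$fold_change, 2^(-r2$delta_delta_ct), tolerance = 1e-12)
  # under two valid replicates: not evaluable
  expect_false(delta_delta_ct(c(9, NA, NA), c(8, 8, 8))$evaluable)
})

test_that("Welch p-values match the from-formula oracle", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-9)
  p <- welch_test(c(9.1, 8.9, 9.0), c(7.6, 7.4, 7.5))
  expect_equal(p, welch_p_oracle(c(9.1, 8.9, 9.0), c(7.6, 7.4, 7.5)),
               tolerance = 1e-10)
  # degenerate zero-variance limits
  expect_equal(welch_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(welch_test(c(2, 2, 2), c(3, 3, 3)), 0)
  set.seed(31)
  for (i in 1:200) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx, sd = runif(1, 0.1, 3)); y <- rnorm(ny, sd = runif(1, 0.1, 3))
    expect_equal(welch_test(x, y), welch_p_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("differential calls use strict thresholds without correction", {
  res <- data.frame(p_value = c(0.049, 0.05, 0.01, 0.049),
                    fold_change = c(1.01, 2.0, 0.9, 1.0))
  out <- call_differential(res)
  expect_identical(out$induced, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("fold-change reciprocity and per-sample shift invariance hold", {
  cfg <- small_sim(seed = 21)
  sim <- generate_ct_table(cfg)
  res <- qpcr_differential_expression(sim$ct_table, hypoxia_o2 = 0.2)
  # swapping condition labels inverts FC and negates ddCt, p unchanged
  swapped <- sim$ct_table
  swapped$o2_percent[sim$ct_table$o2_percent == 0.2] <- 21
  swapped$o2_percent[sim$ct_table$o2_percent == 21] <- 0.2
  res_sw <- qpcr_differential_expression(
    swapped[swapped$o2_percent %in% c(21, 0.2), ], hypoxia_o2 = 0.2)
  key <- paste(res$feature_id, res$cell_line)
  key_sw <- paste(res_sw$feature_id, res_sw$cell_line)
  m <- match(key, key_sw)
  ok <- res$evaluable & res_sw$evaluable[m]
  expect_equal(res$fold_change[ok], 1 / res_sw$fold_change[m][ok],
               tolerance = 1e-9)
  expect_equal(res$delta_delta_ct[ok], -res_sw$delta_delta_ct[m][ok],
               tolerance = 1e-9)
  expect_equal(res$p_value[ok], res_sw$p_value[m][ok], tolerance = 1e-9)
})

test_that("seed selection is monotone in the cell-line threshold", {
  cfg <- small_sim(seed = 2)
  sim <- generate_ct_table(cfg)
  res <- qpcr_differential_expression(sim$ct_table, hypoxia_o2 = 0.2)
  s2 <- select_seeds(res, min_lines = 2)
  s3 <- select_seeds(res, min_lines = 3)
  s4 <- select_seeds(res, min_lines = 4)
  expect_true(all(s3 %in% s2))
  expect_true(all(s4 %in% s3))
  counts <- attr(s2, "line_counts")
  expect_identical(unname(counts[1]), length(s2))
  # a feature induced in exactly one line is excluded at min_lines = 2
  one_line <- names(attr(s2, "induced_lines"))[attr(s2, "induced_lines") == 1]
  expect_false(any(one_line %in% s2))
})
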