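toy_matrix <- function(vals, samples, features) {
  matrix(vals, nrow = length(samples), ncol = length(features),
         dimnames = list(samples, features))
}

test_that("mean-expression scores are row means over present features", {
  m <- toy_matrix(c(1, 2, 3, 5, 6, 7), paste0("s", 1:3), c("a", "b"))
  sc <- score_mean_expression(m, c("a", "b"))
  expect_equal(sc$score, c(3, 4, 5))
  # constant features give a constant score
  mc <- toy_matrix(rep(4, 6), paste0("s", 1:3), c("a", "b"))
  expect_true(all(score_mean_expression(mc, c("a", "b"))$score == 4))
  # missing feature dropped with coverage 5/6, a warning, and mean over rest
  m6 <- toy_matrix(rep(1:5, each = 2), paste0("s", 1:2),
                   paste0("g", 1:5))
  expect_warning(sc6 <- score_mean_expression(m6, paste0("g", 1:6)),
                 "coverage")
  expect_equal(attr(sc6, "coverage"), 5 / 6)
  expect_equal(sc6$score, unname(rowMeans(m6)))
  expect_error(score_mean_expression(m, c("x", "y")), "x")
})

test_that("signed scores equal mean(positive) - mean(negative)", {
  m <- toy_matrix(c(4, 6, 1, 3), "s1", c("p1", "p2", "n1", "n2"))
  sig <- gene_signature("toy", c("p1", "p2"), c("n1", "n2"))
  expect_equal(score_signed_signature(m, sig)$score, 3)
  # all features equal => score 0
  mc <- toy_matrix(rep(7, 4), "s1", c("p1", "p2", "n1", "n2"))
  expect_equal(score_signed_signature(mc, sig)$score, 0)
  # location invariance under per-sample shifts
  m2 <- toy_matrix(rnorm(40), paste0("s", 1:10), c("p1", "p2", "n1", "n2"))
  shift <- rnorm(10)
  expect_equal(score_signed_signature(m2 + shift, sig)$score,
               score_signed_signature(m2, sig)$score, tolerance = 1e-12)
  # equivariance under global scaling
  expect_equal(score_signed_signature(m2 * 3, sig)$score,
               3 * score_signed_signature(m2, sig)$score, tolerance = 1e-12)
  # one side absent entirely is an error
  m3 <- toy_matrix(rnorm(20), paste0("s", 1:10), c("p1", "p2"))
  expect_error(score_signed_signature(m3, sig), "negative")
})

test_that("quantile classification uses strict > with interpolated cut-offs", {
  cl <- classify_by_quantile(setNames(1:10, paste0("s", 1:10)), "median")
  expect_equal(sum(cl$label == "hypoxic"), 5)
  cl2 <- classify_by_quantile(setNames(1:100, paste0("s", 1:100)),
                              "upper_quartile")
  expect_equal(sum(cl2$label == "hypoxic"), 25)
  # all-equal scores: nothing exceeds the cut-off
  cl3 <- classify_by_quantile(rep(2, 8), "median")
  expect_equal(sum(cl3$label == "hypoxic"), 0)
  # external cut-off requires a value
  expect_error(classify_by_quantile(1:10, "external"), "cutoff_value")
  # raising one sample's score never flips it hypoxic -> normoxic
  cl4 <- classify_by_quantile(1:10, "external", cutoff_value = 4.5)
  cl5 <- classify_by_quantile(c(1:9, 20), "external", cutoff_value = 4.5)
  flipped <- cl4$label == "hypoxic" & cl5$label == "normoxic"
  expect_false(any(flipped))
})

test_that("reference-cohort cut-offs transfer as stored thresholds", {
  set.seed(4)
  ref <- rnorm(60)
  new <- rnorm(35)
  a <- classify_by_quantile(new, "upper_quartile", reference_scores = ref)
  thr <- unname(quantile(ref, 0.75, type = 7))
  b <- classify_by_quantile(new, "external", cutoff_value = thr)
  expect_equal(a$label, b$label)
  expect_equal(unique(a$cutoff_value), thr)
})

test_that("the built-in 14-miRNA signature matches its published form", {
  sig <- published_mirna_signature()
  expect_length(sig$positive, 7)
  expect_length(sig$negative, 7)
  expect_length(intersect(sig$positive, sig$negative), 0)
  expect_true("miR-210-3p" %in% sig$positive)
  expect_equal(sig$statistics$rho[sig$statistics$feature_id == "miR-210-3p"],
               0.30)
  expect_true(all(sig$statistics$fdr >= 0 & sig$statistics$fdr <= 1))
})

test_that("combined classification is the conjunction of its inputs", {
  mk <- function(labels) {
    sc <- classify_by_quantile(seq_along(labels), "external", cutoff_value = 0)
    sc$sample_id <- paste0("s", seq_along(labels))
    sc$label <- labels
    sc
  }
  a <- mk(c("hypoxic", "hypoxic", "normoxic", "normoxic"))
  b <- mk(c("hypoxic", "normoxic", "hypoxic", "normoxic"))
  comb <- combine_classifications(a, b)
  expect_equal(comb$label, c("hypoxic", "normoxic", "normoxic", "normoxic"))
  # idempotence and the disjoint case
  expect_equal(combine_classifications(a, a)$label, a$label)
  d <- mk(c("normoxic", "normoxic", "hypoxic", "hypoxic"))
  expect_equal(sum(combine_classifications(a, d)$label == "hypoxic"), 0)
  # mismatched sample sets are rejected
  b2 <- b; b2$sample_id[1] <- "zz"
  expect_error(combine_classifications(a, b2), "sample sets")
})

test_that("signatures round-trip through GMT with signed records", {
  sig <- gene_signature("hyp", c("a", "b", "c"), c("d", "e"))
  plain <- gene_signature("anchor", c("g1", "g2"))
  d <- withr::local_tempdir()
  p <- write_gmt(list(sig, plain), file.path(d, "sets.gmt"))
  back <- read_gmt(p)
  expect_setequal(back$hyp$positive, sig$positive)
  expect_setequal(back$hyp$negative, sig$negative)
  expect_setequal(back$anchor$positive, plain$positive)
  expect_length(back$anchor$negative, 0)
})
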