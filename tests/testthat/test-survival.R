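sim_surv <- function(n, rate, censor_rate = 0, horizon = Inf,
                     group = NULL) {
  t_ev <- rexp(n, rate)
  t_c <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  obs <- pmin(t_ev, t_c, horizon)
  out <- data.frame(sample_id = paste0("s", seq_len(n)),
                    time_months = obs,
                    event = as.integer(t_ev <= pmin(t_c, horizon)))
  if (!is.null(group)) out$group <- group
  out
}

test_that("administrative censoring truncates strictly beyond the horizon", {
  tab <- data.frame(time_months = c(72, 60, 59.5, 61), event = c(1, 1, 1, 0))
  out <- censor_at(tab, 60)
  expect_equal(out$time_months, c(60, 60, 59.5, 60))
  expect_equal(out$event, c(0, 1, 1, 0))
  expect_true(all(out$time_months <= 60))
  # a table already inside the horizon is unchanged
  tab2 <- data.frame(time_months = c(10, 20), event = c(1, 0))
  expect_identical(censor_at(tab2, 60), tab2)
  # event count never increases
  expect_lte(sum(out$event), sum(tab$event))
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # 5 patients: events at 1, 2, 4; censored at 3 and 5
  tab <- data.frame(time_months = 1:5, event = c(1, 1, 0, 1, 0))
  km <- km_estimate(tab, rep("all", 5))
  s <- km$curves$survival[km$curves$n_event == 1]
  expect_equal(s, c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2),
               tolerance = 1e-12)
  # single event among n at t: S(t) = (n-1)/n
  tab2 <- data.frame(time_months = c(2, 3, 3, 3), event = c(1, 0, 0, 0))
  km2 <- km_estimate(tab2, rep("all", 4))
  expect_equal(km2$curves$survival[1], 3 / 4)
  # no events: survival identically 1
  tab3 <- data.frame(time_months = 1:6, event = rep(0, 6))
  expect_true(all(km_estimate(tab3, rep("all", 6))$curves$survival == 1))
})

test_that("log-rank p equals the Cox score test on two untied groups", {
  set.seed(12)
  for (i in 1:5) {
    g <- rep(c("a", "b"), each = 40)
    tab <- sim_surv(80, rate = ifelse(g == "a", 0.03, 0.05),
                    censor_rate = 0.01, group = g)
    km <- km_estimate(tab, tab$group)
    cx <- cox_univariable(tab, "group")
    expect_equal(km$logrank_p, cx$p[1], tolerance = 1e-6)
  }
})

test_that("univariable Cox recovers a planted hazard ratio", {
  set.seed(22)
  hrs <- replicate(40, {
    x <- rbinom(300, 1, 0.5)
    tab <- sim_surv(300, rate = 0.04 * 2^x, censor_rate = 0.02)
    tab$x <- factor(x)
    cox_univariable(tab, "x")$hr[1]
  })
  expect_gt(mean(hrs), 1.7)
  expect_lt(mean(hrs), 2.3)
  # degenerate inputs come back flagged, never silent numbers
  tab0 <- data.frame(time_months = 1:10, event = rep(0, 10),
                     x = rep(c("a", "b"), 5))
  f0 <- cox_univariable(tab0, "x")
  expect_false(attr(f0, "converged"))
  expect_true(is.na(f0$hr[1]))
  tabc <- data.frame(time_months = 1:10, event = rep(1, 10),
                     x = rep("a", 10))
  expect_false(attr(cox_univariable(tabc, "x"), "converged"))
})

test_that("the multivariable entry rule screens at p < 0.1", {
  set.seed(33)
  x <- rbinom(400, 1, 0.5)
  tab <- sim_surv(400, rate = 0.03 * 2.5^x, censor_rate = 0.01)
  tab$strong <- factor(x)
  tab$null1 <- rnorm(400)
  tab$null2 <- factor(rbinom(400, 1, 0.5))
  fit <- cox_multivariable(tab, c("strong", "null1", "null2"))
  expect_true("strong" %in% attr(fit, "entered"))
  expect_true(any(grepl("strong", fit$term)))
  expect_gt(fit$hr[grepl("strong", fit$term)], 1.5)
  # entry_p = 1 admits every candidate
  fit_all <- cox_multivariable(tab, c("strong", "null1", "null2"),
                               entry_p = 1)
  expect_setequal(attr(fit_all, "entered"), c("strong", "null1", "null2"))
  # all-null candidates usually yield the empty-model marker
  tabn <- sim_surv(200, rate = 0.03, censor_rate = 0.01)
  tabn$a <- rnorm(200); tabn$b <- rnorm(200)
  fitn <- cox_multivariable(tabn, c("a", "b"))
  if (!length(attr(fitn, "entered"))) {
    expect_equal(nrow(fitn), 0)
    expect_match(attr(fitn, "note"), "entry rule")
  }
})

test_that("stratum benefit and interaction behave at planted effects", {
  cfg <- simulation_config(seed = 77, n_target_features = 48,
                           trial_n_per_arm = 150,
                           log_hr_treatment_hypoxic = log(0.3))
  trial <- generate_trial(cfg)
  surv <- trial$survival[trial$survival$endpoint == "OS", ]
  surv$label <- ifelse(trial$ground_truth$latent_hypoxia[surv$sample_id] == 1,
                       "hypoxic", "normoxic")
  hyp <- stratum_benefit(surv, "hypoxic")
  expect_lt(hyp$hr[1], 1)
  norm <- stratum_benefit(surv, "normoxic")
  expect_true(norm$ci_low[1] < 1 && norm$ci_high[1] > 1)
  it <- interaction_test(surv)
  expect_true(is.finite(attr(it, "interaction_p")))
  # constant hypoxia label: inestimable, flagged
  surv2 <- surv; surv2$label <- "hypoxic"
  it2 <- interaction_test(surv2)
  expect_false(attr(it2, "converged"))
  expect_true(is.na(attr(it2, "interaction_p")))
  # stratum with zero events is flagged, no fit
  surv3 <- surv[surv$label == "hypoxic", ]; surv3$event <- 0L
  expect_false(attr(stratum_benefit(surv3, "hypoxic"), "converged"))
})

test_that("Mann-Whitney U matches enumeration and symmetry", {
  r <- marker_association(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)      # 2 of the 20 orderings are as extreme
  expect_match(r$method, "exact")
  # swapping groups maps U to n1*n2 - U with the same p
  r2 <- marker_association(c(1, 2, 3, 4, 5, 6), rep(c("b", "a"), each = 3))
  expect_equal(r2$U, 9 - r$U)
  expect_equal(r2$p, r$p)
  # identical-distribution exact p agrees with wilcox.test (untied data)
  set.seed(44)
  x <- rnorm(5); y <- rnorm(5)
  ours <- marker_association(c(x, y), rep(c("a", "b"), each = 5))
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # large-sample tie-corrected approximation tracks wilcox.test
  xl <- round(rnorm(40), 1); yl <- round(rnorm(35, 0.3), 1)
  ours_l <- marker_association(c(xl, yl), rep(c("a", "b"), c(40, 35)))
  ref_l <- wilcox.test(xl, yl, exact = FALSE, correct = TRUE)
  expect_equal(ours_l$p, ref_l$p.value, tolerance = 1e-9)
  expect_match(ours_l$method, "tie-corrected")
})
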