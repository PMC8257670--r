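new_cox_fit <- function(terms, n, n_events, converged = TRUE, note = NULL) {
  attr(terms, "n") <- n
  attr(terms, "n_events") <- n_events
  attr(terms, "converged") <- converged
  attr(terms, "note") <- note
  class(terms) <- c("cox_fit", "data.frame")
  terms
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (n = ", attr(x, "n"),
      ", events = ", attr(x, "n_events"), ")\n", sep = "")
  if (!attr(x, "converged"))
    cat("  ** not converged / inestimable: ", attr(x, "note"), "\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Administrative censoring at a follow-up horizon
#'
#' Records with follow-up strictly beyond the horizon are censored at
#' the horizon (time set to `horizon`, event to 0); records at or below
#' it are unchanged. Five-year (60-month) censoring is the convention
#' for radiotherapy-trial analyses.
#'
#' @param table survival data frame with `time_months` and `event`
#'   columns.
#' @param horizon censoring horizon in months (default 60).
#' @return the censored table.
#' @examples
#' censor_at(data.frame(time_months = c(72, 60), event = c(1, 1)))
#' @export
censor_at <- function(table, horizon = 60) {
  stopifnot(all(c("time_months", "event") %in% names(table)),
            all(table$time_months >= 0), horizon > 0)
  over <- table$time_months > horizon
  table$time_months[over] <- horizon
  table$event[over] <- 0L
  table
}

cox_one_endpoint <- function(table) {
  stopifnot(all(c("time_months", "event") %in% names(table)))
  if ("endpoint" %in% names(table) &&
      length(unique(table$endpoint)) > 1)
    stop("fit one endpoint at a time; subset the table first")
  table
}

#' Univariable Cox proportional-hazards model
#'
#' Single-term fit by partial-likelihood maximisation with the Efron
#' tie approximation. The reported p-value is the score (log-rank) test
#' — the univariable convention — with the Wald p also included per
#' term. Binary/character terms are fitted as factors.
#'
#' @param table one-endpoint survival data frame (`time_months`,
#'   `event`, plus the term column).
#' @param term name of the covariate column.
#' @return a `cox_fit` data frame (term, coef, hr, ci_low, ci_high,
#'   p, test, wald_p) with n/events/convergence attributes. Degenerate
#'   inputs (no events, constant term, non-convergence) return a
#'   flagged, all-NA fit rather than silent numbers.
#' @export
cox_univariable <- function(table, term) {
  table <- cox_one_endpoint(table)
  stopifnot(term %in% names(table))
  x <- table[[term]]
  n_ev <- sum(table$event)
  na_fit <- function(note) new_cox_fit(
    data.frame(term = term, coef = NA_real_, hr = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               test = "score", wald_p = NA_real_, stringsAsFactors = FALSE),
    n = nrow(table), n_events = n_ev, converged = FALSE, note = note)
  if (n_ev == 0) return(na_fit("no events"))
  if (length(unique(x[!is.na(x)])) < 2) return(na_fit("constant term"))
  if (is.character(x) || is.logical(x)) table[[term]] <- factor(x)
  fit <- tryCatch(
    coxph(stats::as.formula(paste("Surv(time_months, event) ~", paste0("`", term, "`"))),
          data = table, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      f <- suppressWarnings(
        coxph(stats::as.formula(paste("Surv(time_months, event) ~",
                                      paste0("`", term, "`"))),
              data = table, ties = "efron"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  if (is.null(fit)) return(na_fit("fit error"))
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- new_cox_fit(
    data.frame(term = rownames(co), coef = co[, "coef"],
               hr = ci[, "exp(coef)"],
               ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
               p = rep(unname(s$sctest["pvalue"]), nrow(co)),
               test = "score",
               wald_p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE),
    n = s$n, n_events = s$nevent,
    converged = is.null(attr(fit, "fit_warning")),
    note = attr(fit, "fit_warning"))
  rownames(out) <- NULL
  out
}

#' Multivariable Cox model with a univariable entry rule
#'
#' Screens every candidate by its univariable score-test p-value and
#' fits a joint model on the candidates with `p < entry_p` (default
#' 0.1). Per-term p-values from the joint model are Wald tests, the
#' multivariable convention. When no candidate passes the screen an
#' empty-model marker is returned rather than a forced fit.
#'
#' @param table one-endpoint survival data frame.
#' @param candidate_terms covariate column names to screen.
#' @param entry_p univariable entry threshold (default 0.1).
#' @return a `cox_fit`; attribute `"screen"` reports univariable p per
#'   candidate, attribute `"entered"` the terms fitted. An empty screen
#'   gives a zero-row fit with `converged = TRUE` and a note.
#' @export
cox_multivariable <- function(table, candidate_terms, entry_p = 0.1) {
  table <- cox_one_endpoint(table)
  screen <- vapply(candidate_terms, function(tm)
    cox_univariable(table, tm)$p[1], numeric(1))
  entered <- candidate_terms[!is.na(screen) & screen < entry_p]
  if (!length(entered)) {
    out <- new_cox_fit(
      data.frame(term = character(0), coef = numeric(0), hr = numeric(0),
                 ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
                 test = character(0), wald_p = numeric(0),
                 stringsAsFactors = FALSE),
      n = nrow(table), n_events = sum(table$event), converged = TRUE,
      note = "no candidate passed the entry rule; model not fitted")
    attr(out, "screen") <- screen
    attr(out, "entered") <- character(0)
    return(out)
  }
  for (tm in entered)
    if (is.character(table[[tm]]) || is.logical(table[[tm]]))
      table[[tm]] <- factor(table[[tm]])
  fml <- stats::as.formula(paste("Surv(time_months, event) ~",
                                 paste(paste0("`", entered, "`"),
                                       collapse = " + ")))
  fit <- coxph(fml, data = table, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- new_cox_fit(
    data.frame(term = rownames(co), coef = co[, "coef"],
               hr = ci[, "exp(coef)"],
               ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
               p = co[, "Pr(>|z|)"], test = "wald",
               wald_p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE),
    n = s$n, n_events = s$nevent, converged = TRUE)
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  attr(out, "entered") <- entered
  out
}

#' Kaplan-Meier estimate with log-rank comparison
#'
#' Product-limit survival per group with numbers at risk, plus the
#' log-rank test when two or more groups are present.
#'
#' @param table one-endpoint survival data frame.
#' @param groups per-record group labels (vector aligned with `table`,
#'   or the name of a column).
#' @return list with `curves` (group, time, n_risk, n_event, survival)
#'   and `logrank_p` (NA for a single group).
#' @export
km_estimate <- function(table, groups) {
  table <- cox_one_endpoint(table)
  if (length(groups) == 1 && is.character(groups) &&
      groups %in% names(table)) groups <- table[[groups]]
  stopifnot(length(groups) == nrow(table))
  table$.group <- factor(groups)
  fit <- survfit(Surv(time_months, event) ~ .group, data = table)
  strata <- if (is.null(fit$strata)) {
    rep(levels(table$.group)[1], length(fit$time))
  } else {
    rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       survival = fit$surv, stringsAsFactors = FALSE)
  logrank_p <- if (nlevels(table$.group) >= 2) {
    sd_ <- survdiff(Surv(time_months, event) ~ .group, data = table)
    unname(pchisq(sd_$chisq, df = nlevels(table$.group) - 1,
                  lower.tail = FALSE))
  } else NA_real_
  list(curves = curves, logrank_p = logrank_p)
}

#' Treatment benefit within a hypoxia stratum
#'
#' Within the patients labelled `stratum_label`, a univariable Cox fit
#' of the treatment arm (experimental vs control): the within-stratum
#' test of whether hypoxia-modifying treatment helps the patients the
#' signature calls hypoxic. An HR below 1 favours the experimental arm.
#'
#' @param table one-endpoint survival data frame with an `arm` column
#'   and a `label` column (e.g. joined from [classify_by_quantile()]).
#' @param stratum_label which stratum to analyse ("hypoxic" or
#'   "normoxic").
#' @param arm_col,label_col column names (defaults "arm", "label").
#' @param reference_arm control arm level (default "RT").
#' @return a `cox_fit` for the arm term within the stratum; degenerate
#'   strata (zero events, one arm) come back flagged.
#' @export
stratum_benefit <- function(table, stratum_label,
                            arm_col = "arm", label_col = "label",
                            reference_arm = "RT") {
  table <- cox_one_endpoint(table)
  stopifnot(arm_col %in% names(table), label_col %in% names(table))
  sub <- table[table[[label_col]] == stratum_label, ]
  if (!nrow(sub))
    return(new_cox_fit(data.frame(term = arm_col, coef = NA_real_,
                                  hr = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, p = NA_real_,
                                  test = "score", wald_p = NA_real_,
                                  stringsAsFactors = FALSE),
                       n = 0, n_events = 0, converged = FALSE,
                       note = "empty stratum"))
  sub[[arm_col]] <- stats::relevel(factor(sub[[arm_col]]), ref = reference_arm)
  fit <- cox_univariable(sub, arm_col)
  attr(fit, "stratum") <- stratum_label
  fit
}

#' Treatment-by-hypoxia interaction test
#'
#' Cox model `~ arm + hypoxia + arm:hypoxia` on the full two-arm
#' cohort. The interaction p-value is a likelihood-ratio test of the
#' interaction term against the main-effects model (more reliable than
#' Wald at small within-stratum event counts); the Wald p is also
#' reported. A constant hypoxia label or constant arm makes the
#' interaction inestimable and returns a flagged fit.
#'
#' @param table one-endpoint survival data frame.
#' @param arm_col,label_col column names (defaults "arm", "label").
#' @param reference_arm control arm level (default "RT").
#' @return a `cox_fit` of the full model with attributes
#'   `"interaction_p"` (LRT) and `"interaction_wald_p"`.
#' @export
interaction_test <- function(table, arm_col = "arm", label_col = "label",
                             reference_arm = "RT") {
  table <- cox_one_endpoint(table)
  stopifnot(arm_col %in% names(table), label_col %in% names(table))
  flagged <- function(note) {
    out <- new_cox_fit(data.frame(term = paste0(arm_col, ":", label_col),
                                  coef = NA_real_, hr = NA_real_,
                                  ci_low = NA_real_, ci_high = NA_real_,
                                  p = NA_real_, test = "lrt",
                                  wald_p = NA_real_, stringsAsFactors = FALSE),
                       n = nrow(table), n_events = sum(table$event),
                       converged = FALSE, note = note)
    attr(out, "interaction_p") <- NA_real_
    attr(out, "interaction_wald_p") <- NA_real_
    out
  }
  if (length(unique(table[[label_col]])) < 2)
    return(flagged("hypoxia label constant: interaction inestimable"))
  if (length(unique(table[[arm_col]])) < 2)
    return(flagged("treatment arm constant: interaction inestimable"))
  if (sum(table$event) == 0) return(flagged("no events"))
  table$.arm <- stats::relevel(factor(table[[arm_col]]), ref = reference_arm)
  table$.hyp <- factor(table[[label_col]])
  full <- coxph(Surv(time_months, event) ~ .arm * .hyp, data = table,
                ties = "efron")
  main <- coxph(Surv(time_months, event) ~ .arm + .hyp, data = table,
                ties = "efron")
  lrt_p <- pchisq(2 * (full$loglik[2] - main$loglik[2]),
                  df = length(coef(full)) - length(coef(main)),
                  lower.tail = FALSE)
  s <- summary(full)
  co <- s$coefficients
  ci <- s$conf.int
  out <- new_cox_fit(
    data.frame(term = rownames(co), coef = co[, "coef"],
               hr = ci[, "exp(coef)"],
               ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
               p = co[, "Pr(>|z|)"], test = "wald",
               wald_p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE),
    n = s$n, n_events = s$nevent, converged = TRUE)
  rownames(out) <- NULL
  inter_row <- grepl(":", out$term)
  attr(out, "interaction_p") <- unname(lrt_p)
  attr(out, "interaction_wald_p") <- out$wald_p[inter_row][1]
  out
}

#' Mann-Whitney U test for marker association
#'
#' Compares a continuous marker (e.g. CAIX, GLUT1 or HIF-1alpha IHC
#' intensity) between two classification groups. With 10 or fewer
#' values per group the two-sided p-value is computed by exact
#' enumeration of all label assignments (ties included); otherwise the
#' tie-corrected normal approximation with continuity correction is
#' used.
#'
#' @param values continuous per-sample marker values.
#' @param labels two-group labels aligned with `values`.
#' @param exact_max per-group size up to which enumeration is exact
#'   (default 10).
#' @return list with `U` (statistic for the first group level), `p`
#'   (two-sided) and `method`.
#' @examples
#' marker_association(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
marker_association <- function(values, labels, exact_max = 10) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  if (nlevels(labels) != 2) stop("labels must have exactly two groups")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(g1, g2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate every assignment of n1 labels to the pooled values
    idx <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  list(U = unname(U), p = p, method = method, n = c(n1, n2))
}
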