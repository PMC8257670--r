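#' Simulation configuration for synthetic study inputs
#'
#' Builds the single configuration object consumed by
#' [generate_ct_table()], [generate_cohort()] and [generate_trial()].
#' Defaults emulate the design of a typical hypoxia-signature study:
#' four bladder cancer cell lines profiled on 384-feature qPCR array
#' cards with three endogenous controls in biological triplicate under
#' 21%, 1% and 0.2% O2; a ~400-patient development cohort with matched
#' mRNA/miRNA expression and survival; and a two-arm radiotherapy +/-
#' hypoxia-modification trial with ~95 patients per arm.
#'
#' @param seed integer master seed; every generator draws from it via
#'   fixed sub-streams, so identical config + seed gives identical output.
#' @param layout_seed optional separate seed for the feature layout
#'   (which miRNAs are low-expressed, planted as induced, or in the
#'   planted signature). Defaults to `seed`. Fixing it while varying
#'   `seed` replicates new cohorts/trials around one shared ground-truth
#'   signature, as in a power study.
#' @param n_cell_lines number of cell lines (named T24, UMUC3, J82, RT4,
#'   then CL5...).
#' @param n_target_features number of target miRNAs on the array card.
#' @param n_control_features number of endogenous control features
#'   (RNU48, RNU44, U6snRNA, then CTRL4...). Must be >= 1.
#' @param n_replicates biological replicates per condition.
#' @param o2_percent oxygen conditions as percentages; the maximum is
#'   normoxia. The most severe hypoxia is profiled in all lines;
#'   intermediate hypoxic conditions only in the first three lines
#'   (muscle-invasive lines), matching common screen designs.
#' @param n_planted_induced number of miRNAs truly induced by hypoxia in
#'   vitro; each is planted in 2 or more cell lines.
#' @param induction_shift_ct Ct decrease under hypoxia for planted
#'   features (lower Ct = higher expression).
#' @param ct_noise_sd replicate-level Ct measurement noise for target
#'   features (>= 0).
#' @param control_noise_sd replicate-level Ct noise for endogenous
#'   controls. Smaller than `ct_noise_sd` by default: controls are
#'   chosen as reference genes precisely for their stability, and qPCR
#'   technical variance shrinks at high abundance (low Ct). The default
#'   pair (0.25, 0.1) puts the replicate delta-Ct sd at ~0.26.
#' @param sample_offset_sd sd of a per-sample global Ct shift (shared by
#'   targets and controls; exercises normalisation).
#' @param low_expression_fraction fraction of target features emitted
#'   near/above the detection limit (Ct >= 30 in all replicates) to
#'   exercise the exclusion filter.
#' @param cohort_n development-cohort size.
#' @param anchor_gene_count genes in the synthetic mRNA anchor signature.
#' @param filler_gene_count additional non-anchor mRNA genes.
#' @param hypoxia_prevalence latent hypoxia prevalence in the cohort.
#' @param trial_hypoxia_prevalence latent hypoxia prevalence in the trial.
#' @param n_signature_pos,n_signature_neg sizes of the planted signed
#'   miRNA signature (positively/negatively associated with hypoxia in
#'   tumours); both subsets are drawn from the planted induced miRNAs.
#' @param n_seed_low_cohort planted induced miRNAs given no/low cohort
#'   expression (exercises [filter_unexpressed()]).
#' @param mirna_effect_log2 log2 shift of signature miRNAs with latent
#'   hypoxia (+ for positives, - for negatives).
#' @param anchor_effect_log2 log2 shift of anchor mRNAs with hypoxia.
#' @param expression_noise_sd sd of log2 expression noise.
#' @param baseline_hazard event hazard per month for non-hypoxic patients.
#' @param log_hr_hypoxia log hazard ratio of latent hypoxia.
#' @param pfs_hazard_multiplier hazard multiplier for the
#'   progression/relapse endpoint relative to overall survival.
#' @param trial_n_per_arm patients per trial arm (1:1 forced allocation).
#' @param log_hr_treatment_hypoxic log HR of the experimental arm within
#'   hypoxic patients (default log 0.45: strong benefit).
#' @param log_hr_treatment_normoxic log HR of the experimental arm within
#'   normoxic patients (default 0: no benefit).
#' @param admin_censor_months administrative censoring horizon.
#' @param dropout_rate exponential dropout (loss to follow-up) rate per
#'   month.
#' @param marker_shift mean shift of the IHC-like continuous markers
#'   (CAIX, GLUT1, HIF1A) in hypoxic patients, in marker sd units.
#' @return a `sim_config` list with validated fields.
#' @examples
#' cfg <- simulation_config(seed = 1, n_target_features = 48, cohort_n = 60)
#' @export
simulation_config <- function(seed = 1L,
                              layout_seed = NULL,
                              n_cell_lines = 4L,
                              n_target_features = 384L,
                              n_control_features = 3L,
                              n_replicates = 3L,
                              o2_percent = c(21, 0.2, 1),
                              n_planted_induced = 30L,
                              induction_shift_ct = 1.5,
                              ct_noise_sd = 0.25,
                              control_noise_sd = 0.1,
                              sample_offset_sd = 0.5,
                              low_expression_fraction = 0.05,
                              cohort_n = 400L,
                              anchor_gene_count = 99L,
                              filler_gene_count = 100L,
                              hypoxia_prevalence = 0.5,
                              trial_hypoxia_prevalence = 0.25,
                              n_signature_pos = 7L,
                              n_signature_neg = 7L,
                              n_seed_low_cohort = 2L,
                              mirna_effect_log2 = 1.0,
                              anchor_effect_log2 = 1.0,
                              expression_noise_sd = 1.0,
                              baseline_hazard = 0.02,
                              log_hr_hypoxia = log(1.7),
                              pfs_hazard_multiplier = 1.5,
                              trial_n_per_arm = 95L,
                              log_hr_treatment_hypoxic = log(0.45),
                              log_hr_treatment_normoxic = 0,
                              admin_censor_months = 60,
                              dropout_rate = 0.005,
                              marker_shift = 1.0) {
  cfg <- list(
    seed = as.integer(seed),
    layout_seed = if (is.null(layout_seed)) as.integer(seed)
                  else as.integer(layout_seed),
    n_cell_lines = as.integer(n_cell_lines),
    n_target_features = as.integer(n_target_features),
    n_control_features = as.integer(n_control_features),
    n_replicates = as.integer(n_replicates),
    o2_percent = as.numeric(o2_percent),
    n_planted_induced = as.integer(n_planted_induced),
    induction_shift_ct = induction_shift_ct,
    ct_noise_sd = ct_noise_sd,
    control_noise_sd = control_noise_sd,
    sample_offset_sd = sample_offset_sd,
    low_expression_fraction = low_expression_fraction,
    cohort_n = as.integer(cohort_n),
    anchor_gene_count = as.integer(anchor_gene_count),
    filler_gene_count = as.integer(filler_gene_count),
    hypoxia_prevalence = hypoxia_prevalence,
    trial_hypoxia_prevalence = trial_hypoxia_prevalence,
    n_signature_pos = as.integer(n_signature_pos),
    n_signature_neg = as.integer(n_signature_neg),
    n_seed_low_cohort = as.integer(n_seed_low_cohort),
    mirna_effect_log2 = mirna_effect_log2,
    anchor_effect_log2 = anchor_effect_log2,
    expression_noise_sd = expression_noise_sd,
    baseline_hazard = baseline_hazard,
    log_hr_hypoxia = log_hr_hypoxia,
    pfs_hazard_multiplier = pfs_hazard_multiplier,
    trial_n_per_arm = as.integer(trial_n_per_arm),
    log_hr_treatment_hypoxic = log_hr_treatment_hypoxic,
    log_hr_treatment_normoxic = log_hr_treatment_normoxic,
    admin_censor_months = admin_censor_months,
    dropout_rate = dropout_rate,
    marker_shift = marker_shift
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_cell_lines", "n_target_features", "n_replicates",
              "cohort_n", "anchor_gene_count", "trial_n_per_arm")
  for (f in counts)
    if (cfg[[f]] < 1L) stop("config field '", f, "' must be a positive count")
  if (cfg$n_control_features < 1L)
    stop("at least one endogenous control feature is required")
  if (cfg$n_planted_induced > cfg$n_target_features)
    stop("n_planted_induced cannot exceed n_target_features")
  if (cfg$n_planted_induced < 0L || cfg$n_seed_low_cohort < 0L ||
      cfg$filler_gene_count < 0L)
    stop("counts must be non-negative")
  for (f in c("hypoxia_prevalence", "trial_hypoxia_prevalence"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config field '", f, "' must lie in (0, 1)")
  if (cfg$low_expression_fraction < 0 || cfg$low_expression_fraction >= 1)
    stop("low_expression_fraction must lie in [0, 1)")
  for (f in c("ct_noise_sd", "control_noise_sd", "sample_offset_sd",
              "expression_noise_sd"))
    if (cfg[[f]] < 0) stop("config field '", f, "' must be >= 0")
  if (cfg$induction_shift_ct < 0) stop("induction_shift_ct must be >= 0")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$dropout_rate < 0) stop("dropout_rate must be >= 0")
  if (cfg$admin_censor_months <= 0) stop("admin_censor_months must be > 0")
  if (length(cfg$o2_percent) < 2)
    stop("need at least one hypoxic and one normoxic O2 condition")
  if (any(cfg$o2_percent <= 0 | cfg$o2_percent > 100))
    stop("o2_percent values must lie in (0, 100]")
  if (cfg$n_signature_pos + cfg$n_signature_neg + cfg$n_seed_low_cohort >
      cfg$n_planted_induced && cfg$n_planted_induced > 0)
    stop("planted signature plus low-expression features exceed n_planted_induced")
  invisible(cfg)
}

cell_line_names <- function(n) {
  base <- c("T24", "UMUC3", "J82", "RT4")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("CL%d", seq(length(base) + 1L, n)))
}

control_feature_names <- function(n) {
  base <- c("RNU48", "RNU44", "U6snRNA")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("CTRL%d", seq(length(base) + 1L, n)))
}

target_feature_names <- function(n) sprintf("miR-sim-%03d", seq_len(n))

# Feature-level layout shared by the qPCR plate and cohort generators:
# which features are low-expressed, which are truly induced (and where),
# and which form the planted signed signature. Depends only on (config,
# seed) so plate and cohort agree on ground truth.
plant_features <- function(cfg) {
  with_seed(sub_seed(cfg$layout_seed, 1L), {
    features <- target_feature_names(cfg$n_target_features)
    lines <- cell_line_names(cfg$n_cell_lines)
    n_low <- round(cfg$low_expression_fraction * cfg$n_target_features)
    low <- sort(sample(features, n_low))
    eligible <- setdiff(features, low)
    if (cfg$n_planted_induced > length(eligible))
      stop("too few detectable features to plant the induced set")
    planted <- sort(sample(eligible, cfg$n_planted_induced))
    # each planted miRNA is induced in >= 2 lines, most in just 2-3
    induced_in <- matrix(FALSE, nrow = length(planted), ncol = length(lines),
                         dimnames = list(planted, lines))
    if (length(planted)) {
      max_lines <- max(2L, cfg$n_cell_lines)
      for (f in planted) {
        k <- if (cfg$n_cell_lines <= 2L) cfg$n_cell_lines
             else sample(2:cfg$n_cell_lines, 1L,
                         prob = rev(seq_len(cfg$n_cell_lines - 1L))^2)
        induced_in[f, sample(lines, k)] <- TRUE
      }
    }
    # planted signature: subsets of the induced miRNAs, disjoint from the
    # features made unexpressed in the cohort
    pos <- neg <- low_cohort <- character(0)
    if (length(planted)) {
      pool <- sample(planted)
      pos <- sort(pool[seq_len(cfg$n_signature_pos)])
      pool <- setdiff(pool, pos)
      neg <- sort(pool[seq_len(cfg$n_signature_neg)])
      pool <- setdiff(pool, neg)
      if (cfg$n_seed_low_cohort > 0L)
        low_cohort <- sort(pool[seq_len(min(cfg$n_seed_low_cohort, length(pool)))])
    }
    list(features = features, lines = lines, low_ct = low,
         planted = planted, induced_in = induced_in,
         signature_pos = pos, signature_neg = neg,
         low_cohort = low_cohort)
  })
}

new_ground_truth <- function(...) {
  gt <- list(...)
  class(gt) <- "ground_truth"
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  if (!is.null(x$planted_induced))
    cat("  planted induced miRNAs:", nrow(x$induced_in), "\n")
  if (!is.null(x$signature_truth))
    cat("  planted signature:", length(x$signature_truth$positive), "up /",
        length(x$signature_truth$negative), "down\n")
  if (!is.null(x$latent_hypoxia))
    cat("  latent hypoxia: ", sum(x$latent_hypoxia), "/",
        length(x$latent_hypoxia), " samples\n", sep = "")
  invisible(x)
}

#' Simulate a qPCR array-card experiment
#'
#' Generates long-format Ct measurements for every cell line, oxygen
#' condition and replicate: endogenous controls with stable Ct, target
#' miRNAs with per-feature baselines, a planted subset whose Ct drops by
#' `induction_shift_ct` under hypoxia in the cell lines where it is
#' induced, a subset emitted at/above the Ct >= 30 detection limit, and
#' a per-sample global Ct offset shared by targets and controls (so that
#' control normalisation is genuinely needed).
#'
#' @param config a [simulation_config()].
#' @return list with `ct_table` (a `ct_table` data frame with columns
#'   cell_line, o2_percent, replicate, feature_id, feature_class, ct) and
#'   `ground_truth` (planted induced features with per-line flags and the
#'   planted signed signature).
#' @examples
#' sim <- generate_ct_table(simulation_config(seed = 1, n_target_features = 24))
#' head(sim$ct_table)
#' @export
generate_ct_table <- function(config) {
  validate_sim_config(config)
  layout <- plant_features(config)
  with_seed(sub_seed(config$seed, 2L), {
    lines <- layout$lines
    controls <- control_feature_names(config$n_control_features)
    normoxia <- max(config$o2_percent)
    hypoxic <- sort(setdiff(config$o2_percent, normoxia))
    severe <- min(hypoxic)
    # per-feature baselines: controls tight and low, targets mid-range,
    # low-expression subset parked above the detection threshold
    base_ctrl <- setNames(runif(length(controls), 15, 17), controls)
    base_tgt <- setNames(runif(length(layout$features), 22, 29), layout$features)
    base_tgt[layout$low_ct] <- runif(length(layout$low_ct), 31, 34)

    rows <- list()
    for (cl in lines) {
      # intermediate hypoxic conditions only in the first three lines
      conds <- c(normoxia, severe)
      if (match(cl, lines) <= 3L)
        conds <- sort(unique(c(conds, hypoxic)), decreasing = TRUE)
      for (o2 in conds) {
        for (rep_i in seq_len(config$n_replicates)) {
          offset <- rnorm(1, 0, config$sample_offset_sd)
          shift <- rep(0, length(layout$features))
          names(shift) <- layout$features
          if (o2 < normoxia && length(layout$planted)) {
            ind <- rownames(layout$induced_in)[layout$induced_in[, cl]]
            shift[ind] <- -config$induction_shift_ct
          }
          ct_t <- base_tgt + shift + offset +
            rnorm(length(base_tgt), 0, config$ct_noise_sd)
          ct_c <- base_ctrl + offset +
            rnorm(length(base_ctrl), 0, config$control_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, o2_percent = o2, replicate = rep_i,
            feature_id = c(names(ct_t), names(ct_c)),
            feature_class = rep(c("target", "control"),
                                c(length(ct_t), length(ct_c))),
            ct = c(unname(ct_t), unname(ct_c)),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("ct_table", "data.frame")
    gt <- new_ground_truth(
      planted_induced = layout$planted,
      induced_in = layout$induced_in,
      low_ct_features = layout$low_ct,
      signature_truth = list(positive = layout$signature_pos,
                             negative = layout$signature_neg))
    list(ct_table = tab, ground_truth = gt)
  })
}

# log2 expression block: baseline + effect*H + noise, truncated at 0
# (log2(x+1) platforms are non-negative)
expr_block <- function(n, features, H, effect, noise_sd, base_range = c(2, 10)) {
  base <- runif(length(features), base_range[1], base_range[2])
  m <- matrix(rnorm(n * length(features), 0, noise_sd), nrow = n)
  m <- sweep(m, 2, base, "+") + outer(H, effect)
  pmax(m, 0)
}

make_survival_rows <- function(ids, endpoint, rate, cfg) {
  t_event <- rexp(length(ids), rate)
  t_drop <- if (cfg$dropout_rate > 0) rexp(length(ids), cfg$dropout_rate)
            else rep(Inf, length(ids))
  obs <- pmin(t_event, t_drop, cfg$admin_censor_months)
  data.frame(sample_id = ids, endpoint = endpoint,
             time_months = obs,
             event = as.integer(t_event <= pmin(t_drop, cfg$admin_censor_months)),
             stringsAsFactors = FALSE)
}

#' Simulate a signature-development cohort
#'
#' Draws a latent binary hypoxia state per patient and emits (i) an mRNA
#' matrix in which a known anchor gene set shifts up with hypoxia, (ii) a
#' miRNA matrix in which the planted signature positives shift up and
#' negatives shift down with hypoxia while all other miRNAs are noise,
#' and (iii) overall and progression-free survival driven by the latent
#' state through an exponential proportional-hazards model with
#' administrative censoring and exponential dropout. miRNA feature names
#' match [generate_ct_table()], so seed discovery and signature
#' derivation can be chained on one simulation.
#'
#' @param config a [simulation_config()].
#' @return list with `mrna` and `mirna` (samples x features log2
#'   matrices), `anchor_signature` (the unsigned anchor gene set as a
#'   [gene_signature()]), `survival` (long-format survival table),
#'   `clinical` (per-patient covariates) and `ground_truth` (latent
#'   hypoxia, a continuous hypoxia severity score, the planted signed
#'   signature and the true log hazard ratios).
#' @examples
#' cohort <- generate_cohort(simulation_config(seed = 1, cohort_n = 50,
#'                                             n_target_features = 48))
#' dim(cohort$mirna)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  layout <- plant_features(config)
  with_seed(sub_seed(config$seed, 3L), {
    n <- config$cohort_n
    ids <- sprintf("PT-%04d", seq_len(n))
    H <- rbinom(n, 1L, config$hypoxia_prevalence)
    severity <- H + rnorm(n, 0, 0.3)  # graded latent severity, for rank tests

    anchor_genes <- sprintf("HYPOX-GENE-%03d", seq_len(config$anchor_gene_count))
    filler_genes <- if (config$filler_gene_count > 0)
      sprintf("GENE-%04d", seq_len(config$filler_gene_count)) else character(0)
    mrna <- cbind(
      expr_block(n, anchor_genes, H, rep(config$anchor_effect_log2,
                 length(anchor_genes)), config$expression_noise_sd,
                 base_range = c(4, 8)),
      expr_block(n, filler_genes, H, rep(0, length(filler_genes)),
                 config$expression_noise_sd, base_range = c(4, 8)))
    dimnames(mrna) <- list(ids, c(anchor_genes, filler_genes))

    eff <- setNames(rep(0, length(layout$features)), layout$features)
    eff[layout$signature_pos] <- config$mirna_effect_log2
    eff[layout$signature_neg] <- -config$mirna_effect_log2
    mirna <- expr_block(n, layout$features, H, eff, config$expression_noise_sd)
    dimnames(mirna) <- list(ids, layout$features)
    # no/low-expression miRNAs: mostly exact zeros on the log2(x+1) scale
    for (f in c(layout$low_cohort, layout$low_ct)) {
      v <- pmax(rnorm(n, 0.2, 0.3), 0)
      v[runif(n) < 0.8] <- 0
      mirna[, f] <- v
    }

    rate_os <- config$baseline_hazard * exp(config$log_hr_hypoxia * H)
    surv <- rbind(
      make_survival_rows(ids, "OS", rate_os, config),
      make_survival_rows(ids, "PFS", rate_os * config$pfs_hazard_multiplier,
                         config))
    clinical <- data.frame(
      sample_id = ids,
      age = round(rnorm(n, 70, 8), 1),
      stage = sample(c("T2", "T3", "T4"), n, replace = TRUE,
                     prob = c(0.5, 0.35, 0.15)),
      stringsAsFactors = FALSE)

    gt <- new_ground_truth(
      latent_hypoxia = setNames(H, ids),
      hypoxia_severity = setNames(severity, ids),
      signature_truth = list(positive = layout$signature_pos,
                             negative = layout$signature_neg),
      low_cohort_features = c(layout$low_cohort, layout$low_ct),
      true_log_hrs = list(OS = list(hypoxia = config$log_hr_hypoxia),
                          PFS = list(hypoxia = config$log_hr_hypoxia)))
    list(mrna = mrna, mirna = mirna,
         anchor_signature = gene_signature("anchor-mrna", positive = anchor_genes,
                                           provenance = "synthetic"),
         survival = surv, clinical = clinical, ground_truth = gt)
  })
}

#' Simulate a two-arm randomised trial with a treatment-by-hypoxia effect
#'
#' Patients are allocated 1:1 (forced balance) to radiotherapy alone
#' ("RT") or radiotherapy plus hypoxia modification ("RT+CON"). Survival
#' follows an exponential proportional-hazards model whose log hazard is
#' `log(h0) + bH*H + (bT_hyp*H + bT_norm*(1-H))*I(arm = RT+CON)`: by
#' default the experimental arm benefits only the hypoxic stratum. Two
#' endpoints (OS, LRFS) share the latent state, and continuous IHC-like
#' hypoxia markers (CAIX, GLUT1, HIF1A) are emitted for association
#' tests.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna` (samples x features log2 matrix), `survival`
#'   (long-format table including `arm` and marker columns) and
#'   `ground_truth` (latent hypoxia and true log HRs per stratum).
#' @examples
#' trial <- generate_trial(simulation_config(seed = 1, trial_n_per_arm = 30,
#'                                           n_target_features = 48))
#' table(trial$survival$arm) / 2
#' @export
generate_trial <- function(config) {
  validate_sim_config(config)
  layout <- plant_features(config)
  with_seed(sub_seed(config$seed, 4L), {
    n <- 2L * config$trial_n_per_arm
    ids <- sprintf("BC-%04d", seq_len(n))
    arm <- sample(rep(c("RT", "RT+CON"), each = config$trial_n_per_arm))
    H <- rbinom(n, 1L, config$trial_hypoxia_prevalence)
    con <- as.integer(arm == "RT+CON")

    eff <- setNames(rep(0, length(layout$features)), layout$features)
    eff[layout$signature_pos] <- config$mirna_effect_log2
    eff[layout$signature_neg] <- -config$mirna_effect_log2
    mirna <- expr_block(n, layout$features, H, eff, config$expression_noise_sd)
    dimnames(mirna) <- list(ids, layout$features)

    loghaz <- config$log_hr_hypoxia * H +
      (config$log_hr_treatment_hypoxic * H +
         config$log_hr_treatment_normoxic * (1 - H)) * con
    rate_os <- config$baseline_hazard * exp(loghaz)
    surv <- rbind(
      make_survival_rows(ids, "OS", rate_os, config),
      make_survival_rows(ids, "LRFS", rate_os * config$pfs_hazard_multiplier,
                         config))
    surv$arm <- rep(arm, 2L)
    markers <- data.frame(
      sample_id = ids,
      caix = rnorm(n, 5, 1) + config$marker_shift * H,
      glut1 = rnorm(n, 5, 1) + config$marker_shift * H,
      hif1a = rnorm(n, 5, 1) + config$marker_shift * H,
      stringsAsFactors = FALSE)
    surv <- merge(surv, markers, by = "sample_id", sort = FALSE)
    surv <- surv[order(match(surv$endpoint, c("OS", "LRFS")),
                       match(surv$sample_id, ids)), ]
    rownames(surv) <- NULL

    gt <- new_ground_truth(
      latent_hypoxia = setNames(H, ids),
      signature_truth = list(positive = layout$signature_pos,
                             negative = layout$signature_neg),
      true_log_hrs = list(
        OS = list(hypoxia = config$log_hr_hypoxia,
                  treatment_hypoxic = config$log_hr_treatment_hypoxic,
                  treatment_normoxic = config$log_hr_treatment_normoxic),
        LRFS = list(hypoxia = config$log_hr_hypoxia,
                    treatment_hypoxic = config$log_hr_treatment_hypoxic,
                    treatment_normoxic = config$log_hr_treatment_normoxic)))
    list(mirna = mirna, survival = surv, ground_truth = gt)
  })
}
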