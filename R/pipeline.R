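#' Run configuration for the full pipeline
#'
#' Bundles a [simulation_config()] (or file paths to real inputs) with
#' the analysis thresholds and cut-off policies of a full run. Can be
#' read from a YAML file whose keys mirror the argument names
#' (`simulation:` entries are passed to [simulation_config()]).
#'
#' @param simulation a [simulation_config()], or NULL when all inputs
#'   come from files.
#' @param paths named list of input files (`ct_table`, `mrna`, `mirna`,
#'   `survival`, `trial_mirna`, `trial_survival`, `anchor_gmt`), used
#'   where no simulation is supplied.
#' @param hypoxia_o2 hypoxic condition for seed discovery (percent O2).
#' @param min_lines cell-line support needed for a seed miRNA.
#' @param train_fraction training fraction of the development cohort.
#' @param n_trees,max_iter,alpha,q_threshold,include_tentative
#'   derivation parameters (see [derive_signature()]).
#' @param cohort_cutoff,trial_cutoff quantile cut-off policy per cohort.
#' @param endpoints endpoints analysed in the trial.
#' @param censor_horizon months of follow-up retained (default 60).
#' @param seed global seed; per-stage seeds are derived from it and
#'   recorded in the run manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       paths = list(),
                       hypoxia_o2 = 0.2,
                       min_lines = 2L,
                       train_fraction = 0.7,
                       n_trees = 500,
                       max_iter = 1000,
                       alpha = 0.05,
                       q_threshold = 0.05,
                       include_tentative = TRUE,
                       cohort_cutoff = "median",
                       trial_cutoff = "upper_quartile",
                       endpoints = c("OS", "LRFS"),
                       censor_horizon = 60,
                       seed = NULL) {
  if (!is.null(simulation)) validate_sim_config(simulation)
  if (!is.null(seed) && !is.null(simulation)) {
    if (simulation$layout_seed == simulation$seed)
      simulation$layout_seed <- as.integer(seed)
    simulation$seed <- as.integer(seed)
  }
  cfg <- list(simulation = simulation, paths = paths,
              hypoxia_o2 = hypoxia_o2, min_lines = as.integer(min_lines),
              train_fraction = train_fraction, n_trees = n_trees,
              max_iter = max_iter, alpha = alpha,
              q_threshold = q_threshold,
              include_tentative = include_tentative,
              cohort_cutoff = cohort_cutoff, trial_cutoff = trial_cutoff,
              endpoints = endpoints, censor_horizon = censor_horizon,
              seed = if (is.null(seed)) {
                if (is.null(simulation)) 1L else simulation$seed
              } else as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [run_config()]
#'   arguments, with `simulation:` holding [simulation_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown run_config field(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  if (!is.null(y$simulation)) {
    sim_known <- names(formals(simulation_config))
    sim_bad <- setdiff(names(y$simulation), sim_known)
    if (length(sim_bad))
      stop("unknown simulation field(s): ", paste(sim_bad, collapse = ", "))
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  do.call(run_config, y)
}

stage_dir <- function(out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out_dir
}

run_manifest <- function(config, stage, extra = list()) {
  c(list(stage = stage,
         seed = config$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         package_version = as.character(utils::packageVersion("hypomir")),
         thresholds = config[c("hypoxia_o2", "min_lines", "train_fraction",
                               "n_trees", "max_iter", "alpha", "q_threshold",
                               "include_tentative", "cohort_cutoff",
                               "trial_cutoff", "censor_horizon")]),
    extra)
}

#' Derive a hypoxia miRNA signature from simulated or supplied inputs
#'
#' Executes the derivation half of the study flow: qPCR seed discovery
#' (detection-limit exclusion, control-stability selection,
#' delta-delta-Ct with Welch tests, >= `min_lines` cell-line support),
#' then on the development cohort a stratified 70:30 split, anchor
#' scoring with median dichotomisation, Boruta selection and the
#' Spearman/FDR filter into a signed signature.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes the signature
#'   (GMT + JSON), the differential-expression and correlation tables
#'   (TSV), the Boruta plot (PNG) and a machine-readable run manifest.
#' @return list with `signature`, `seeds`, `dge`, `split`, `cohort`
#'   (the generated/loaded inputs), `ground_truth` and `manifest`.
#' @export
run_derivation <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- pipeline_inputs(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("derivation stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dge <- stage("qpcr_dge", qpcr_differential_expression(
    inputs$ct_table, hypoxia_o2 = config$hypoxia_o2))
  seeds <- stage("seed_selection", select_seeds(dge, config$min_lines))
  if (!length(seeds)) stop("derivation stage 'seed_selection' failed: ",
                           "no seed miRNAs at min_lines = ", config$min_lines)
  split <- stage("train_test_split", {
    anchor_scores <- score_mean_expression(inputs$mrna, inputs$anchor)
    labels <- classify_by_quantile(anchor_scores, "median")
    split_train_test(labels$sample_id, labels$label,
                     config$train_fraction, seed = sub_seed(config$seed, 11L))
  })
  sig <- stage("derive_signature", derive_signature(
    seed_features = seeds,
    mrna = inputs$mrna[split$train, , drop = FALSE],
    mirna = inputs$mirna[split$train, , drop = FALSE],
    anchor = inputs$anchor,
    n_trees = config$n_trees, max_iter = config$max_iter,
    alpha = config$alpha, q_threshold = config$q_threshold,
    include_tentative = config$include_tentative,
    seed = sub_seed(config$seed, 12L)))
  manifest <- run_manifest(config, "derivation", list(
    n_seeds = length(seeds),
    n_train = length(split$train), n_test = length(split$test),
    boruta_iterations = attr(sig, "boruta")$iterations_run,
    signature_positive = sig$positive, signature_negative = sig$negative))
  if (!is.null(out_dir)) {
    out_dir <- stage_dir(out_dir)
    if (length(sig))
      write_gmt(sig, file.path(out_dir, "signature.gmt"))
    jsonlite::write_json(
      list(name = sig$name, positive = sig$positive,
           negative = sig$negative, provenance = sig$provenance,
           statistics = sig$statistics),
      file.path(out_dir, "signature.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write.table(as.data.frame(dge), file.path(out_dir, "dge.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(seeds, file.path(out_dir, "seeds.txt"))
    flt <- attr(sig, "correlation_filter")
    if (!is.null(flt))
      write.table(flt, file.path(out_dir, "correlation_filter.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    b <- attr(sig, "boruta")
    if (b$iterations_run > 0) {
      grDevices::png(file.path(out_dir, "boruta.png"), width = 1400,
                     height = 700)
      plot_boruta(b)
      grDevices::dev.off()
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(signature = sig, seeds = seeds, dge = dge, split = split,
       cohort = inputs[c("mrna", "mirna", "survival", "anchor")],
       ground_truth = inputs$ground_truth, manifest = manifest)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim_ct <- generate_ct_table(config$simulation)
    cohort <- generate_cohort(config$simulation)
    list(ct_table = sim_ct$ct_table,
         mrna = cohort$mrna, mirna = cohort$mirna,
         survival = cohort$survival, anchor = cohort$anchor_signature,
         ground_truth = list(ct = sim_ct$ground_truth,
                             cohort = cohort$ground_truth))
  } else {
    p <- config$paths
    need <- c("ct_table", "mrna", "mirna", "survival", "anchor_gmt")
    missing <- setdiff(need, names(p))
    if (length(missing))
      stop("run_config paths missing: ", paste(missing, collapse = ", "))
    for (f in need)
      if (!file.exists(p[[f]])) stop("input file not found: ", p[[f]])
    anchors <- read_gmt(p$anchor_gmt)
    list(ct_table = read_ct_table(p$ct_table),
         mrna = read_expression_matrix(p$mrna),
         mirna = read_expression_matrix(p$mirna),
         survival = read_survival_table(p$survival),
         anchor = anchors[[1]],
         ground_truth = NULL)
  }
}

#' Validate a signature in a two-arm trial
#'
#' Scores the trial cohort with the signed signature, applies the
#' configured quantile cut-off (optionally transferring a reference
#' cohort's cut-off), censors follow-up at the horizon, and per
#' endpoint fits the within-stratum treatment-benefit models and the
#' treatment-by-hypoxia interaction test. Continuous marker columns
#' (e.g. IHC intensities), when present, are compared between the
#' hypoxic and normoxic groups with the Mann-Whitney U test.
#'
#' @param config a [run_config()].
#' @param signature a signed [gene_signature()].
#' @param trial list with `mirna` and `survival` (e.g. from
#'   [generate_trial()]); defaults to simulating one from
#'   `config$simulation`.
#' @param reference_scores optional scores whose quantile defines the
#'   cut-off (cut-off transfer between cohorts).
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return list with `scores` (classified), and per endpoint
#'   `benefit_hypoxic`, `benefit_normoxic`, `interaction`, `km`; plus
#'   `marker_tests` and `manifest`.
#' @export
run_validation <- function(config = run_config(), signature,
                           trial = NULL, reference_scores = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(signature, "gene_signature"))
  if (is.null(trial)) {
    if (is.null(config$simulation))
      stop("validation needs either a trial or a simulation config")
    trial <- generate_trial(config$simulation)
  }
  if (!length(signature))
    stop("validation stage 'scoring' failed: empty signature")
  scores <- score_signed_signature(trial$mirna, signature)
  scores <- classify_by_quantile(scores, config$trial_cutoff,
                                 reference_scores = reference_scores)
  surv <- merge(trial$survival,
                scores[, c("sample_id", "score", "label")],
                by = "sample_id", sort = FALSE)
  surv <- censor_at(surv, config$censor_horizon)
  endpoints <- intersect(config$endpoints, unique(surv$endpoint))
  per_endpoint <- lapply(endpoints, function(ep) {
    tab <- surv[surv$endpoint == ep, ]
    list(endpoint = ep,
         benefit_hypoxic = stratum_benefit(tab, "hypoxic"),
         benefit_normoxic = stratum_benefit(tab, "normoxic"),
         interaction = interaction_test(tab),
         km = km_estimate(tab, interaction(tab$label, tab$arm, drop = TRUE)))
  })
  names(per_endpoint) <- endpoints
  marker_cols <- intersect(c("caix", "glut1", "hif1a"), names(surv))
  one_ep <- surv[surv$endpoint == endpoints[1], ]
  marker_tests <- lapply(setNames(marker_cols, marker_cols), function(mc)
    marker_association(one_ep[[mc]], one_ep$label))
  manifest <- run_manifest(config, "validation", list(
    signature = signature$name,
    cutoff_type = scores$cutoff_type[1],
    cutoff_value = scores$cutoff_value[1],
    n_hypoxic = sum(scores$label == "hypoxic"),
    n = nrow(scores)))
  if (!is.null(out_dir)) {
    out_dir <- stage_dir(out_dir)
    write_score_result(scores, file.path(out_dir, "trial_scores.csv"))
    for (ep in endpoints) {
      write_cox_fit(per_endpoint[[ep]]$benefit_hypoxic,
                    file.path(out_dir, paste0("benefit_hypoxic_", ep, ".tsv")))
      write_cox_fit(per_endpoint[[ep]]$benefit_normoxic,
                    file.path(out_dir, paste0("benefit_normoxic_", ep, ".tsv")))
      write_cox_fit(per_endpoint[[ep]]$interaction,
                    file.path(out_dir, paste0("interaction_", ep, ".tsv")))
      write.csv(per_endpoint[[ep]]$km$curves,
                file.path(out_dir, paste0("km_", ep, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      c(manifest,
        list(interaction_p = lapply(per_endpoint, function(x)
          attr(x$interaction, "interaction_p")))),
      file.path(out_dir, "validation_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(list(scores = scores, marker_tests = marker_tests,
         manifest = manifest), per_endpoint)
}

#' Run the full study flow end to end
#'
#' Simulation (or file input), seed discovery, signature derivation,
#' trial scoring and survival validation in one call, with one global
#' seed fanned out to per-stage sub-seeds recorded in the manifests.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; derivation artifacts go to
#'   `out_dir/derivation`, validation reports to `out_dir/validation`.
#' @return list with `derivation` and `validation` results.
#' @examples
#' \donttest{
#' cfg <- run_config(simulation_config(seed = 7, n_target_features = 96,
#'                                     cohort_n = 120, trial_n_per_arm = 60))
#' res <- run_pipeline(cfg)
#' res$derivation$signature
#' }
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  der <- run_derivation(config,
                        out_dir = if (!is.null(out_dir))
                          file.path(out_dir, "derivation"))
  val <- run_validation(config, der$signature,
                        out_dir = if (!is.null(out_dir))
                          file.path(out_dir, "validation"))
  list(derivation = der, validation = val)
}
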