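#' Load a pipeline run configuration
#'
#' Configurations are YAML (or JSON) with top-level keys: `seed`, `out_dir`,
#' `stages` (any of `simulate`, `sexdiff`, `continuum`, `sensitivity`,
#' `assoc`), `synthetic` (fields of [synthetic_config()]), and numeric knobs
#' (`bootstrap_reps`, `n_perm`, `folds`, `top_fraction`, `band_lower`,
#' `band_upper`, `test_fraction`). Missing keys fall back to defaults.
#'
#' @param path YAML/JSON file path, or a named list already in memory.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(seed = 1L, out_dir = "braingender_run",
                   stages = c("simulate", "sexdiff", "continuum",
                              "sensitivity", "assoc"),
                   synthetic = list(),
                   bootstrap_reps = 1000L, n_perm = 2000L, folds = 5L,
                   top_fraction = 0.05, band_lower = 0.35,
                   band_upper = 0.65, test_fraction = 0.3)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$stages <- match.arg(cfg$stages,
                          c("simulate", "sexdiff", "continuum",
                            "sensitivity", "assoc"),
                          several.ok = TRUE)
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in order on a synthetic cohort: simulate
#' (generate and write the cohort), sexdiff (effect-size maps, gFC
#' trajectories, confound concordance), continuum (train/test split, model
#' fit, cross-validation, scores and bands), sensitivity (network ablation
#' and top-weight enrichment), assoc (U-shape association table and band
#' ANOVA of the strongest-effect network). Later stages re-use earlier
#' results; every random draw descends from the single root `seed`. Outputs
#' are tab-separated tables plus a machine-readable JSON report of all
#' statistics, seeds and package version.
#'
#' @param config a [load_run_config()] result, a path, or a named list.
#' @return the report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version =
                   as.character(utils::packageVersion("braingender")),
                 seed = cfg$seed, stages = cfg$stages)

  syn_args <- cfg$synthetic
  syn_args$seed <- cfg$seed
  scfg <- do.call(synthetic_config, syn_args)
  cohort <- generate_cohort(scfg)
  ds <- cohort$connectomes
  ph <- cohort$phenotypes

  if ("simulate" %in% cfg$stages) {
    write_connectome(ds, file.path(cfg$out_dir, "cohort"))
    utils::write.table(
      data.frame(edge = seq_along(cohort$truth$edge_baseline_d),
                 baseline_d = cohort$truth$edge_baseline_d,
                 slope = cohort$truth$edge_slope),
      file.path(cfg$out_dir, "cohort", "truth_edges.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    report$simulate <- list(n_subjects = nrow(ph),
                            n_edges = ncol(ds$fc),
                            n_male = sum(ph$sex == "M"))
  }

  net <- network_aggregate(ds)
  gfc <- global_fc(ds)
  covars <- ph[, c("FD", "SNR", "TIV")]

  if ("sexdiff" %in% cfg$stages) {
    dmap <- sex_difference_map(net, ph$sex, covars)
    conc <- confound_concordance(dmap$d_raw, dmap$d_adjusted)
    gci <- bootstrap_ci(gfc, ph$sex, n_reps = cfg$bootstrap_reps,
                        seed = cfg$seed + 1L)
    common_lo <- max(tapply(ph$age, ph$sex, min))
    common_hi <- min(tapply(ph$age, ph$sex, max))
    traj <- fit_trajectory(ph$age, gfc, ph$sex,
                           grid_min = common_lo, grid_max = common_hi,
                           covariates = covars)
    tconc <- trajectory_concordance(traj)
    utils::write.table(dmap, file.path(cfg$out_dir, "sexdiff_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$sexdiff <- list(gfc_d = gci$d, gfc_ci = gci$ci,
                           network_concordance_r = conc$r,
                           network_concordance_df = conc$df,
                           trajectory_concordance_r = tconc$F$r,
                           n_grid = length(traj$grid))
  }

  model <- NULL; test_ds <- NULL; scores <- NULL
  if (any(c("continuum", "sensitivity", "assoc") %in% cfg$stages)) {
    set.seed(cfg$seed + 2L)
    n <- nrow(ph)
    te_idx <- sort(sample(n, round(cfg$test_fraction * n)))
    tr_ds <- subset_subjects(ds, setdiff(seq_len(n), te_idx))
    test_ds <- subset_subjects(ds, te_idx)
    model <- fit_continuum(tr_ds, cost = 1)
    scores <- score_continuum(model, test_ds)
  }

  if ("continuum" %in% cfg$stages) {
    cv <- crossval(ds, k = cfg$folds, seed = cfg$seed + 3L)
    acc <- evaluate_accuracy(model, test_ds)
    auc <- roc_auc(scores$score, test_ds$phenotypes$sex)
    utils::write.table(scores, file.path(cfg$out_dir, "continuum_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$continuum <- list(cv_mean_accuracy = cv$mean,
                             cv_sd_accuracy = cv$sd,
                             test_accuracy = acc$accuracy,
                             test_auc = auc,
                             band_counts = as.list(table(scores$band)))
  }

  if ("sensitivity" %in% cfg$stages) {
    tr_ds <- subset_subjects(ds, setdiff(seq_len(nrow(ph)),
                                         match(scores$subject_id,
                                               rownames(ds$fc))))
    signal_net <- names(which.max(abs(
      sapply(split(cohort$truth$edge_baseline_d, ds$edges$category), mean))))
    signal_net <- sub("\\|.*", "", signal_net)
    abl <- ablate_network(tr_ds, test_ds, signal_net,
                          train_n = 2L * floor(0.4 * nrow(tr_ds$fc)),
                          n_repeats = 5L, seed = cfg$seed + 4L)
    enr <- weight_enrichment(model, ds$parcellation,
                             top_fraction = cfg$top_fraction,
                             n_perm = max(100L, cfg$n_perm %/% 4L),
                             seed = cfg$seed + 5L)
    utils::write.table(enr, file.path(cfg$out_dir, "weight_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$sensitivity <- list(ablated_network = abl$network,
                               ablation_delta = abl$delta,
                               ablation_ci = abl$ci,
                               top_category = enr$category[which.min(enr$p)],
                               top_category_p = min(enr$p))
  }

  if ("assoc" %in% cfg$stages) {
    te_ph <- test_ds$phenotypes
    scheme <- build_scheme(te_ph$family_id)
    tab <- association_table(scores$score, te_ph, scheme = scheme,
                             n_perm = cfg$n_perm, seed = cfg$seed + 6L)
    net_te <- network_aggregate(test_ds)
    sig_cat <- names(which.max(abs(cohens_d(net_te, te_ph$sex))))
    ban <- band_anova(net_te[, sig_cat],
                      assign_band(scores$score, cfg$band_lower,
                                  cfg$band_upper))
    utils::write.table(tab, file.path(cfg$out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    quad_all <- tab[tab$group == "all" & tab$term == "quadratic" &
                      tab$outcome == "internalizing", ]
    report$assoc <- list(quadratic_r = quad_all$r,
                         quadratic_p_perm = quad_all$p_perm,
                         quadratic_df = quad_all$df,
                         band_anova_F = ban$F,
                         band_anova_df = as.list(ban$df),
                         band_network = sig_cat)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
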