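#' Experiment configuration
#'
#' Bundles the full experiment: the synthetic cohort specification, the DICE
#' configuration, the classifier presets to run, and evaluation options.
#' Every stage derives its seed from the single `master_seed` through a
#' counter-based scheme ([stage_seed()]), so skipping or reordering stages
#' never changes another stage's random stream.
#'
#' @param cohort a [cohort_spec()]; its own seed is overridden by the
#'   master-seed fan-out.
#' @param master_seed integer master seed.
#' @param dice a [dice_config()]; seed likewise overridden.
#' @param presets character vector of model presets among
#'   `"dice_lr_ffs"`, `"lr_ffs"`, `"xgboost"`, `"dice_gbdt"`,
#'   `"dice_xgboost"`, `"lr"`, `"dice_lr"`, `"gbdt"`,
#'   `"risk_score_modified"`, `"risk_score"` (the last needs
#'   `risk_score_coefficients`).
#' @param ffs_budget forward-feature-search budget. Default 20.
#' @param search_k if TRUE run the cluster-count search over
#'   `dice$k_candidates`; if FALSE fit the first candidate directly.
#' @param eval_B bootstrap resamples in evaluation. Default 2000.
#' @param risk_score_coefficients optional named vector for the unmodified
#'   risk-score preset.
#' @param ratios split ratios. Default `c(0.8, 0.1, 0.1)`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              master_seed = 1L,
                              dice = dice_config(),
                              presets = c("dice_lr_ffs", "lr_ffs", "xgboost",
                                          "dice_gbdt", "dice_xgboost", "lr",
                                          "dice_lr", "gbdt",
                                          "risk_score_modified"),
                              ffs_budget = 20L,
                              search_k = TRUE,
                              eval_B = 2000L,
                              risk_score_coefficients = NULL,
                              ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(dice, "dice_config"))
  known <- c("dice_lr_ffs", "lr_ffs", "xgboost", "dice_gbdt", "dice_xgboost",
             "lr", "dice_lr", "gbdt", "risk_score_modified", "risk_score")
  bad <- setdiff(presets, known)
  if (length(bad)) stopf("unknown preset(s): %s", paste(bad, collapse = ", "))
  if ("risk_score" %in% presets && is.null(risk_score_coefficients))
    stopf("preset 'risk_score' needs risk_score_coefficients")
  structure(list(cohort = cohort, master_seed = as.integer(master_seed),
                 dice = dice, presets = presets,
                 ffs_budget = as.integer(ffs_budget),
                 search_k = isTRUE(search_k), eval_B = as.integer(eval_B),
                 risk_score_coefficients = risk_score_coefficients,
                 ratios = ratios),
            class = "experiment_config")
}

preset_spec <- function(name, cfg, seed) {
  switch(name,
    dice_lr_ffs = classifier_spec("l1_logistic", use_dice = TRUE,
                                  use_ffs = TRUE, ffs_budget = cfg$ffs_budget,
                                  seed = seed),
    lr_ffs = classifier_spec("l1_logistic", use_ffs = TRUE,
                             ffs_budget = cfg$ffs_budget, seed = seed),
    xgboost = classifier_spec("xgboost", seed = seed),
    dice_gbdt = classifier_spec("gbdt", use_dice = TRUE, seed = seed),
    dice_xgboost = classifier_spec("xgboost", use_dice = TRUE, seed = seed),
    lr = classifier_spec("l1_logistic", seed = seed),
    dice_lr = classifier_spec("l1_logistic", use_dice = TRUE, seed = seed),
    gbdt = classifier_spec("gbdt", seed = seed))
}

preset_uses_dice <- function(name) grepl("^dice_", name)

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full synthetic RVA experiment
#'
#' Executes the pipeline end-to-end: cohort generation, monthly 8:1:1
#' split, feature construction (training-row statistics only), DICE fitting
#' (when any preset needs it), preset classifier fitting, and test-set
#' evaluation. Fully deterministic per `cfg$master_seed`.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, the results table (CSV),
#'   a JSON run manifest (config echo, master seed, config hash) and the
#'   serialized models are written there.
#' @return an object of class `experiment`: `results` (one row per preset:
#'   model, auc, ci, sensitivity, specificity, plr), the fitted `models`,
#'   `dice` model (or NULL), cluster `assignment` on test rows with its
#'   risk ratio, plus `cohort`, `fm`, `split` and the config.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  ms <- cfg$master_seed

  cohort <- cfg$cohort
  cohort$seed <- stage_seed(ms, 1L)
  tab <- generate_cohort(cohort)

  split <- monthly_split(list(month = tab$month, y = tab$outcome),
                         ratios = cfg$ratios, seed = stage_seed(ms, 2L))
  fm <- build_matrix(tab, split$train_idx)

  dice_model <- NULL
  memberships <- NULL
  assignment <- NULL
  if (any(preset_uses_dice(cfg$presets))) {
    dcfg <- cfg$dice
    dcfg$seed <- stage_seed(ms, 3L)
    dice_model <- if (cfg$search_k) search_architecture(fm, split, dcfg)
                  else fit_dice(fm, split, dcfg)
    memberships <- assign_clusters(dice_model, fm, seq_len(nrow(fm$X)))$membership
    assignment <- assign_clusters(dice_model, fm, split$test_idx)
  }

  models <- list()
  rows <- list()
  for (i in seq_along(cfg$presets)) {
    p <- cfg$presets[i]
    seed_p <- stage_seed(ms, 10L + i)
    fitted <- if (p == "risk_score_modified") {
      fit_risk_score(risk_score_spec("refit"), fm, split, seed = seed_p)
    } else if (p == "risk_score") {
      fit_risk_score(risk_score_spec("user_coefficients",
                                     coefficients = cfg$risk_score_coefficients),
                     fm, split, seed = seed_p)
    } else {
      fit_classifier(preset_spec(p, cfg, seed_p), fm, split,
                     memberships = memberships)
    }
    rep <- evaluate_model(fitted, fm, split$test_idx,
                          memberships = memberships, B = cfg$eval_B,
                          seed = stage_seed(ms, 50L + i), subgroups = FALSE)
    models[[p]] <- fitted
    rows[[p]] <- data.frame(
      model = p, auc = rep$auc, auc_lo = rep$auc_ci[1], auc_hi = rep$auc_ci[2],
      sensitivity = rep$sensitivity, specificity = rep$specificity,
      plr = rep$plr)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results <- results[order(-results$auc), ]

  out <- structure(list(
    results = results, models = models, dice = dice_model,
    assignment = assignment,
    risk_ratio = if (!is.null(assignment)) assignment$risk_ratio else NA_real_,
    cohort = tab, fm = fm, split = split, config = cfg,
    config_hash = object_hash(cfg)
  ), class = "experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    manifest <- list(master_seed = ms, config_hash = out$config_hash,
                     presets = cfg$presets,
                     n_visits = cohort$n_visits,
                     chosen_k = if (!is.null(dice_model)) dice_model$chosen_k else NA,
                     risk_ratio = out$risk_ratio,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    saveRDS(models, file.path(out_dir, "models.rds"))
    if (!is.null(dice_model))
      saveRDS(dice_model, file.path(out_dir, "dice_model.rds"))
  }
  out
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("experiment (master seed %d, n = %d):\n",
              x$config$master_seed, nrow(x$cohort)))
  print(x$results, row.names = FALSE, digits = 3)
  if (!is.null(x$dice))
    cat(sprintf("  DICE: K = %d, test-set cluster risk ratio %.2f\n",
                x$dice$chosen_k, x$risk_ratio))
  invisible(x)
}

#' Validate frozen models on an external cohort
#'
#' Applies the experiment's frozen preprocessing statistics, DICE model and
#' classifiers to an external visit table without refitting anything, and
#' recomputes the metric panel. Model artifacts are hashed before and after
#' to guarantee nothing was modified; a schema mismatch raises an error
#' naming the missing columns.
#'
#' @param experiment a fitted `experiment`.
#' @param external_table a `visit_table` with the development schema.
#' @return list with the external `results` table, `risk_ratio` on the
#'   external cohort (when DICE was used), and `frozen` = TRUE after the
#'   hash check.
#' @export
validate_external_cohort <- function(experiment, external_table) {
  stopifnot(inherits(experiment, "experiment"))
  h_before <- object_hash(list(experiment$models, experiment$dice))

  fm_ext <- apply_matrix(experiment$fm, external_table)
  rows <- seq_len(nrow(fm_ext$X))
  memberships <- NULL
  rr <- NA_real_
  if (!is.null(experiment$dice)) {
    asg <- assign_clusters(experiment$dice, fm_ext, rows)
    memberships <- asg$membership
    rr <- asg$risk_ratio
  }
  res <- lapply(names(experiment$models), function(p) {
    fitted <- experiment$models[[p]]
    pr <- stats::predict(fitted, fm_ext, rows, memberships = memberships)
    y <- fm_ext$y
    cm <- confusion_metrics(pr$calls, y)
    data.frame(model = p, auc = auc(pr$scores, y),
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               plr = cm$plr)
  })
  results <- do.call(rbind, res)

  h_after <- object_hash(list(experiment$models, experiment$dice))
  if (!identical(h_before, h_after))
    stopf("frozen-model guarantee violated: artifacts changed during validation")
  list(results = results, risk_ratio = rr, frozen = TRUE,
       model_hash = h_after)
}
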