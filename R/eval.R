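#' Confusion-matrix metrics at a decision threshold
#'
#' @param calls binary 0/1 predicted calls.
#' @param labels binary 0/1 outcome labels (both classes required).
#' @return named list: `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `plr` = sensitivity / (1 - specificity) (`Inf` with an
#'   `infinite_plr` flag when specificity is 1).
#' @export
confusion_metrics <- function(calls, labels) {
  calls <- as.integer(calls); labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("labels must contain both classes")
  tp <- sum(calls == 1 & labels == 1); fn <- sum(calls == 0 & labels == 1)
  tn <- sum(calls == 0 & labels == 0); fp <- sum(calls == 1 & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  plr <- if (spec < 1) sens / (1 - spec) else Inf
  list(sensitivity = sens, specificity = spec, plr = plr,
       infinite_plr = !is.finite(plr))
}

#' Stratified bootstrap confidence interval for a score metric
#'
#' Percentile interval over `B` bootstrap resamples drawn within outcome
#' class (stratified), so every resample retains both classes at the
#' original class balance — necessary with a ~0.8% outcome. Deterministic
#' per seed.
#'
#' @param metric function of `(scores, labels)`, e.g. [auc()].
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @param B number of resamples (>= 100). Default 2000.
#' @param level confidence level. Default 0.95.
#' @param seed integer seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 2000L, level = 0.95,
                         seed = 1L) {
  if (B < 100) stopf("B must be >= 100")
  labels <- as.integer(labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (!length(i1) || !length(i0)) stopf("both classes required")
  stat <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- c(i1[sample.int(length(i1), length(i1), replace = TRUE)],
             i0[sample.int(length(i0), length(i0), replace = TRUE)])
    metric(scores[idx], labels[idx])
  }, numeric(1)))
  a <- (1 - level) / 2
  stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
}

#' Subgroup AUCs on held-out rows
#'
#' Per-group AUC with bootstrap CI, computed on the supplied (test) rows
#' only. Groups lacking both outcome classes are skipped with a note;
#' groups with fewer than `small_n` positives are flagged.
#'
#' @param scores scores for `rows`.
#' @param labels labels for `rows`.
#' @param groups named list of per-row group label vectors (factors split
#'   multi-level; 0/1 vectors are treated as membership flags).
#' @param B bootstrap resamples for the CI. Default 500.
#' @param seed integer seed.
#' @param small_n flag threshold on positive count. Default 5.
#' @return data.frame with group, level, n, n_pos, auc, ci_lo, ci_hi,
#'   small_n flag; skipped single-class groups appear with NA AUC.
#' @export
subgroup_aucs <- function(scores, labels, groups, B = 500L, seed = 1L,
                          small_n = 5L) {
  out <- data.frame()
  for (g in names(groups)) {
    gv <- groups[[g]]
    lv <- if (is.numeric(gv)) 1 else unique(gv)
    for (l in lv) {
      sel <- gv == l
      n <- sum(sel); np <- sum(labels[sel] == 1)
      if (length(unique(labels[sel])) < 2) {
        out <- rbind(out, data.frame(group = g, level = as.character(l),
                                     n = n, n_pos = np, auc = NA, ci_lo = NA,
                                     ci_hi = NA, small_n = TRUE,
                                     note = "single-class; skipped"))
        next
      }
      a <- auc(scores[sel], labels[sel])
      ci <- bootstrap_ci(auc, scores[sel], labels[sel], B = B, seed = seed)
      out <- rbind(out, data.frame(group = g, level = as.character(l),
                                   n = n, n_pos = np, auc = a,
                                   ci_lo = ci[1], ci_hi = ci[2],
                                   small_n = np < small_n, note = ""))
    }
  }
  out
}

#' Mean absolute additive feature attributions
#'
#' Ranks features by mean absolute per-visit additive attribution of the
#' model score on the given rows. For linear models (L1 logistic, risk
#' score) the attribution is exact: `coefficient * (x - mean(x over rows))`,
#' which equals the Shapley value under feature independence. For boosted
#' trees it delegates to the xgboost TreeSHAP contributions.
#'
#' @param fitted a `fitted_classifier`.
#' @param fm a `feature_matrix`.
#' @param rows integer row indices (typically the test set).
#' @param memberships membership matrix when the model uses DICE features.
#' @param top_n number of features to return. Default 20.
#' @return data.frame `feature`, `mean_abs_attr`, descending.
#' @export
attribution_ranking <- function(fitted, fm, rows, memberships = NULL,
                                top_n = 20L) {
  D <- model_design(fm, if (length(fitted$base_features)) memberships else NULL)
  cols <- fitted$fit$cols
  X <- D[rows, cols, drop = FALSE]
  phi <- switch(fitted$fit$kind,
    glmnet = {
      co <- as.numeric(stats::coef(fitted$fit$fit))[-1]
      sweep(X, 2, colMeans(X)) %*% diag(co, length(co))
    },
    glm = {
      co <- stats::coef(fitted$fit$fit)[-1]
      co[is.na(co)] <- 0
      sweep(X, 2, colMeans(X)) %*% diag(co, length(co))
    },
    linear = sweep(X, 2, colMeans(X)) %*% diag(fitted$fit$w, length(fitted$fit$w)),
    xgb = {
      ctr <- stats::predict(fitted$fit$fit, xgboost::xgb.DMatrix(X),
                            predcontrib = TRUE)
      ctr[, seq_along(cols), drop = FALSE]
    })
  m <- colMeans(abs(phi))
  names(m) <- cols
  ord <- order(m, decreasing = TRUE)
  utils::head(data.frame(feature = cols[ord], mean_abs_attr = unname(m[ord])),
              top_n)
}

#' Full evaluation panel for a fitted model
#'
#' Computes the metric panel on held-out rows: AUC with bootstrap CI,
#' sensitivity/specificity/positive likelihood ratio at the model's (frozen,
#' validation-derived) Youden threshold, subgroup AUCs (race, age >= 65, and
#' the HF/COPD/UTI/pneumonia disease flags) and the attribution ranking.
#'
#' @param fitted a `fitted_classifier`.
#' @param fm a `feature_matrix`.
#' @param rows held-out row indices (never training rows).
#' @param memberships membership matrix when the model uses DICE features.
#' @param B bootstrap resamples. Default 2000.
#' @param seed integer seed.
#' @param subgroups compute subgroup AUCs. Default TRUE.
#' @return an object of class `eval_report`.
#' @export
evaluate_model <- function(fitted, fm, rows, memberships = NULL, B = 2000L,
                           seed = 1L, subgroups = TRUE) {
  pr <- stats::predict(fitted, fm, rows, memberships = memberships)
  y <- fm$y[rows]
  a <- auc(pr$scores, y)
  ci <- bootstrap_ci(auc, pr$scores, y, B = B, seed = seed)
  cm <- confusion_metrics(pr$calls, y)
  sg <- if (subgroups)
    subgroup_aucs(pr$scores, y,
                  lapply(fm$groups, function(g) g[rows]), seed = seed)
  else NULL
  structure(list(
    auc = a, auc_ci = ci,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    plr = cm$plr,
    subgroup_aucs = sg,
    attribution = attribution_ranking(fitted, fm, rows, memberships),
    n = length(rows), n_pos = sum(y)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (n = %d, %d positives)\n", x$n, x$n_pos))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, PLR %s\n",
              x$sensitivity, x$specificity,
              if (is.finite(x$plr)) sprintf("%.3f", x$plr) else "Inf"))
  invisible(x)
}

#' Discharge-variable ablation
#'
#' Reruns a pipeline closure with the features flagged `discharge_related`
#' (disposition, ED LOS) removed from the design, same hyperparameters and
#' seed, and reports the AUC delta — a sensitivity analysis for how much the
#' model leans on information around the discharge itself.
#'
#' @param fm a `feature_matrix` with `discharge_related` flags.
#' @param run function(fm) -> test AUC; called on the full and the ablated
#'   feature matrix.
#' @return list `auc_full`, `auc_ablated`, `delta` (ablated - full),
#'   `removed` feature names. A no-op with a warning when nothing is
#'   flagged.
#' @export
ablation_discharge_vars <- function(fm, run) {
  flagged <- names(fm$discharge_related)[fm$discharge_related]
  auc_full <- run(fm)
  if (!length(flagged)) {
    warnf("no discharge_related features flagged; ablation is a no-op")
    return(list(auc_full = auc_full, auc_ablated = auc_full, delta = 0,
                removed = character(0)))
  }
  fm2 <- fm
  keep <- !(fm$feature_names %in% flagged)
  fm2$X <- fm$X[, keep, drop = FALSE]
  fm2$feature_names <- fm$feature_names[keep]
  fm2$discharge_related <- fm$discharge_related[keep]
  auc_abl <- run(fm2)
  list(auc_full = auc_full, auc_ablated = auc_abl,
       delta = auc_abl - auc_full, removed = flagged)
}

#' Compare category distributions of model-identified vs model-missed cases
#'
#' Chart-review-style analysis: for each clinical category (index-visit
#' diagnosis class or RVA root cause), tests whether its proportion differs
#' between cases the model identified and cases it missed, by a
#' continuity-corrected 2x2 chi-square test (category membership x
#' identified/missed), switching to Fisher's exact test when an expected
#' cell is below 1. Raw p-values are adjusted for multiple testing.
#'
#' @param identified named integer vector of per-category counts among
#'   model-identified cases.
#' @param missed named counts among model-missed cases, same category
#'   universe.
#' @param correction `"holm"` (default) or `"bonferroni"`.
#' @return an object of class `category_comparison`: per-category counts,
#'   proportions, statistic, df, raw and adjusted p, test used.
#' @export
category_comparison <- function(identified, missed,
                                correction = c("holm", "bonferroni")) {
  correction <- match.arg(correction)
  cats <- union(names(identified), names(missed))
  if (!length(cats)) stopf("empty category universe")
  id <- stats::setNames(rep(0L, length(cats)), cats)
  ms <- id
  id[names(identified)] <- identified
  ms[names(missed)] <- missed
  n_id <- sum(id); n_ms <- sum(ms)
  if (n_id == 0 || n_ms == 0) stopf("both groups need positive totals")

  rows <- lapply(cats, function(cc) {
    tab <- matrix(c(id[[cc]], n_id - id[[cc]], ms[[cc]], n_ms - ms[[cc]]),
                  2, 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expected) < 1) {
      ft <- stats::fisher.test(tab)
      data.frame(category = cc, n_identified = id[[cc]], n_missed = ms[[cc]],
                 prop_identified = id[[cc]] / n_id,
                 prop_missed = ms[[cc]] / n_ms,
                 statistic = NA_real_, df = NA_real_, p_raw = ft$p.value,
                 test = "fisher")
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      data.frame(category = cc, n_identified = id[[cc]], n_missed = ms[[cc]],
                 prop_identified = id[[cc]] / n_id,
                 prop_missed = ms[[cc]] / n_ms,
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_raw = ct$p.value, test = "chi-square")
    }
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_raw, method = correction)
  structure(list(table = res, correction = correction),
            class = "category_comparison")
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("category_comparison (%s-adjusted):\n", x$correction))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
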