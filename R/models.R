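#' Specification of a step-2 classifier
#'
#' @param family one of `"l1_logistic"` (L1-regularized logistic regression
#'   via glmnet), `"gbdt"` or `"xgboost"` (gradient-boosted trees via the
#'   xgboost library with family-specific hyperparameter presets).
#' @param use_dice include DICE cluster-membership probabilities as
#'   always-included input features.
#' @param use_ffs select input variables by greedy forward feature search.
#' @param ffs_budget maximum number of FFS-selected variables (DICE
#'   memberships do not count against it). Default 20.
#' @param hp_grid optional list of hyperparameter-override lists searched by
#'   validation AUC; a family default grid is used when NULL.
#' @param seed integer seed.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("l1_logistic", "gbdt", "xgboost"),
                            use_dice = FALSE, use_ffs = FALSE,
                            ffs_budget = 20L, hp_grid = NULL, seed = 1L) {
  family <- match.arg(family)
  if (use_ffs && ffs_budget < 1) stopf("ffs_budget must be >= 1 when use_ffs")
  structure(list(family = family, use_dice = use_dice, use_ffs = use_ffs,
                 ffs_budget = as.integer(ffs_budget), hp_grid = hp_grid,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

default_hp <- function(family) {
  switch(family,
    l1_logistic = list(lambda = 1e-3),
    xgboost = list(eta = 0.1, max_depth = 3L, nrounds = 120L,
                   subsample = 0.9, colsample = 0.9),
    gbdt = list(eta = 0.05, max_depth = 2L, nrounds = 200L,
                subsample = 0.7, colsample = 1.0))
}

default_hp_grid <- function(family) {
  switch(family,
    l1_logistic = list(list(lambda = 1e-2), list(lambda = 1e-3),
                       list(lambda = 1e-4)),
    xgboost = list(list(max_depth = 3L), list(max_depth = 2L)),
    gbdt = list(list(max_depth = 2L), list(max_depth = 3L)))
}

# ---- family fit/predict dispatch ----

fit_family <- function(family, X, y, hp, seed = 1L) {
  hp <- utils::modifyList(default_hp(family), hp %||% list())
  obj <- with_seed(seed, switch(family,
    l1_logistic = {
      if (ncol(X) >= 2) {
        list(kind = "glmnet",
             fit = glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                                  lambda = hp$lambda, standardize = FALSE))
      } else {
        df <- data.frame(y = y, X)
        list(kind = "glm",
             fit = suppressWarnings(stats::glm(y ~ ., data = df,
                                               family = stats::binomial())),
             cols = colnames(X))
      }
    },
    xgboost = ,
    gbdt = {
      dtr <- xgboost::xgb.DMatrix(X, label = y)
      list(kind = "xgb",
           fit = xgboost::xgb.train(
             params = list(objective = "binary:logistic", eta = hp$eta,
                           max_depth = hp$max_depth, subsample = hp$subsample,
                           colsample_bytree = hp$colsample, nthread = 1),
             data = dtr, nrounds = hp$nrounds, verbose = 0))
    }))
  obj$family <- family
  obj$hp <- hp
  obj$cols <- colnames(X)
  obj
}

predict_family <- function(obj, X) {
  X <- X[, obj$cols, drop = FALSE]
  switch(obj$kind,
    glmnet = as.numeric(stats::predict(obj$fit, X, type = "response")),
    glm = as.numeric(stats::predict(obj$fit, newdata = as.data.frame(X),
                                    type = "response")),
    xgb = as.numeric(stats::predict(obj$fit, xgboost::xgb.DMatrix(X))))
}

# design matrix: engineered features plus (optionally) DICE memberships
model_design <- function(fm, memberships = NULL) {
  if (is.null(memberships)) return(fm$X)
  stopifnot(nrow(memberships) == nrow(fm$X))
  cbind(fm$X, memberships)
}

#' Greedy forward feature search maximizing validation AUC
#'
#' At each step, refits the model with every remaining candidate added and
#' keeps the candidate giving the highest validation AUC; stops at `budget`
#' variables or when no candidate improves the AUC by more than 1e-6.
#' `base_features` (e.g. DICE membership probabilities) are always included
#' and do not count against the budget.
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_bundle`.
#' @param base_features character vector of always-included column names.
#' @param candidates character vector of candidate column names; defaults to
#'   all engineered features.
#' @param budget maximum number of selected candidates. Default 20.
#' @param family classifier family used for the refits.
#' @param memberships optional membership-probability matrix aligned with
#'   `fm` rows (required when `base_features` reference it).
#' @param hp fixed hyperparameters used during the search (family default
#'   when NULL).
#' @param seed integer seed.
#' @return character vector of selected candidates in selection order, with
#'   attribute `trace`: the validation AUC after each step (nondecreasing).
#' @export
forward_feature_search <- function(fm, split, base_features = character(),
                                   candidates = NULL, budget = 20L,
                                   family = "l1_logistic",
                                   memberships = NULL, hp = NULL, seed = 1L) {
  D <- model_design(fm, memberships)
  candidates <- candidates %||% fm$feature_names
  candidates <- setdiff(candidates, base_features)
  if (!length(candidates)) stopf("no candidates to search")
  if (!all(base_features %in% colnames(D)))
    stopf("base_features absent from design")
  if (length(unique(fm$y[split$val_idx])) < 2)
    stopf("validation rows must contain both classes for AUC")

  tr <- oversample_minority(split$train_idx, fm$y, seed = stage_seed(seed, 101L))
  ytr <- fm$y[tr]
  yva <- fm$y[split$val_idx]

  eval_set <- function(cols) {
    f <- fit_family(family, D[tr, cols, drop = FALSE], ytr, hp,
                    seed = stage_seed(seed, 7L))
    auc(predict_family(f, D[split$val_idx, , drop = FALSE]), yva)
  }

  selected <- character(0)
  trace <- numeric(0)
  best_auc <- if (length(base_features)) eval_set(base_features) else -Inf

  while (length(selected) < budget && length(candidates)) {
    aucs <- vapply(candidates, function(cc)
      eval_set(c(base_features, selected, cc)), numeric(1))
    j <- which.max(aucs)
    if (aucs[j] <= best_auc + 1e-6) break
    selected <- c(selected, candidates[j])
    best_auc <- aucs[j]
    trace <- c(trace, best_auc)
    candidates <- candidates[-j]
  }
  attr(selected, "trace") <- trace
  selected
}

#' Youden-index decision threshold
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1, scanning the midpoints of sorted unique scores (calls are
#' `score >= threshold`); ties go to the lowest threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; both classes required.
#' @return the selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes required")
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  j_stat <- vapply(cand, function(t) {
    calls <- scores >= t
    sum(calls & labels == 1) / n1 + sum(!calls & labels == 0) / n0 - 1
  }, numeric(1))
  cand[which.max(j_stat)]  # which.max takes the first (lowest) maximizer
}

#' Fit a step-2 classifier
#'
#' Trains the specified family on the minority-oversampled training rows;
#' optionally includes DICE cluster-membership probabilities as
#' always-included features and selects further variables by
#' [forward_feature_search()]. Hyperparameters are chosen from the family
#' grid by validation AUC, and the decision threshold is the Youden point of
#' the validation ROC — test rows are never touched.
#'
#' @param spec a `classifier_spec`.
#' @param fm a `feature_matrix`.
#' @param split a `split_bundle`.
#' @param memberships membership matrix aligned with `fm` rows; required iff
#'   `spec$use_dice`.
#' @return an object of class `fitted_classifier`: the fitted family object,
#'   `selected_features` (FFS order; all features when FFS off),
#'   `base_features`, `decision_threshold`, `val_auc`, and the FFS `trace`.
#' @export
fit_classifier <- function(spec, fm, split, memberships = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$use_dice && is.null(memberships))
    stopf("use_dice requires a membership matrix")
  if (!spec$use_dice) memberships <- NULL
  D <- model_design(fm, memberships)
  base <- if (spec$use_dice) colnames(memberships) else character(0)

  tr <- oversample_minority(split$train_idx, fm$y,
                            seed = stage_seed(spec$seed, 101L))
  ytr <- fm$y[tr]
  if (length(unique(ytr)) < 2) stopf("degenerate training data")

  if (spec$use_ffs) {
    sel <- forward_feature_search(fm, split, base_features = base,
                                  budget = spec$ffs_budget,
                                  family = spec$family,
                                  memberships = memberships,
                                  seed = spec$seed)
    trace <- attr(sel, "trace")
  } else {
    sel <- fm$feature_names
    trace <- NULL
  }
  cols <- c(base, sel)

  grid <- spec$hp_grid %||% default_hp_grid(spec$family)
  yva <- fm$y[split$val_idx]
  best <- NULL; best_auc <- -Inf
  for (hp in grid) {
    f <- fit_family(spec$family, D[tr, cols, drop = FALSE], ytr, hp,
                    seed = stage_seed(spec$seed, 7L))
    va <- auc(predict_family(f, D[split$val_idx, , drop = FALSE]), yva)
    if (va > best_auc) { best <- f; best_auc <- va }
  }

  val_scores <- predict_family(best, D[split$val_idx, , drop = FALSE])
  thr <- youden_threshold(val_scores, yva)

  structure(list(
    spec = spec, fit = best, selected_features = as.character(sel),
    base_features = base, decision_threshold = thr,
    val_auc = best_auc, trace = trace
  ), class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf("fitted_classifier: %s%s%s, %d feature(s), val AUC %.3f, threshold %.4f\n",
              if (length(x$base_features)) "DICE + " else "",
              toupper(x$spec$family),
              if (x$spec$use_ffs) " + FFS" else "",
              length(x$selected_features) + length(x$base_features),
              x$val_auc, x$decision_threshold))
  invisible(x)
}

#' Score visits with a fitted classifier
#'
#' @param object a `fitted_classifier` (or `fitted_risk_score`).
#' @param fm a `feature_matrix`.
#' @param rows integer row indices to score.
#' @param memberships membership matrix aligned with `fm` rows (needed when
#'   the model uses DICE features).
#' @param ... unused.
#' @return list with `scores` in `[0,1]` and binary `calls`
#'   (`score >= decision_threshold`).
#' @export
predict.fitted_classifier <- function(object, fm, rows, memberships = NULL, ...) {
  if (length(object$base_features) && is.null(memberships))
    stopf("model uses DICE memberships; supply them")
  D <- model_design(fm, if (length(object$base_features)) memberships else NULL)
  miss <- setdiff(c(object$base_features, object$selected_features), colnames(D))
  if (length(miss))
    stopf("schema mismatch, missing feature(s): %s", paste(miss, collapse = ", "))
  if (!length(rows)) return(list(scores = numeric(0), calls = integer(0)))
  scores <- predict_family(object$fit, D[rows, , drop = FALSE])
  list(scores = scores,
       calls = as.integer(scores >= object$decision_threshold))
}

#' Specification of the clinical risk-score baseline
#'
#' A 5-variable ED return-visit-admission risk score over age, systolic
#' blood pressure, pulse, comorbidity-burden score and ED length of stay
#' (the published score's sixth factor, BMI, is omitted for missingness).
#' `refit` mode re-estimates the coefficients on the study data by logistic
#' regression; `user_coefficients` mode evaluates a supplied linear score
#' without any fitting.
#'
#' @param mode `"refit"` or `"user_coefficients"`.
#' @param coefficients named numeric vector over the five variables (plus
#'   optional `"(Intercept)"`), required in `user_coefficients` mode.
#' @param variables feature-name mapping of the five score variables.
#' @return an object of class `risk_score_spec`.
#' @export
risk_score_spec <- function(mode = c("refit", "user_coefficients"),
                            coefficients = NULL,
                            variables = c(age = "age", sbp = "sbp_mean",
                                          pulse = "pulse_mean",
                                          comorbidity = "elixhauser_score",
                                          ed_los = "ed_los")) {
  mode <- match.arg(mode)
  if (mode == "user_coefficients" && is.null(coefficients))
    stopf("user_coefficients mode requires a coefficient vector")
  structure(list(mode = mode, coefficients = coefficients,
                 variables = variables),
            class = "risk_score_spec")
}

#' Fit / evaluate the clinical risk-score baseline
#'
#' @param spec a `risk_score_spec`.
#' @param fm a `feature_matrix`.
#' @param split a `split_bundle`.
#' @param seed integer seed (oversampling stream in refit mode).
#' @return a `fitted_classifier`-compatible object of class
#'   `c("fitted_risk_score", "fitted_classifier")` with exactly the five
#'   score variables as `selected_features` and a Youden validation
#'   threshold.
#' @export
fit_risk_score <- function(spec, fm, split, seed = 1L) {
  stopifnot(inherits(spec, "risk_score_spec"))
  vars <- spec$variables
  miss <- setdiff(vars, fm$feature_names)
  if (length(miss))
    stopf("risk-score variable(s) missing from features: %s",
          paste(miss, collapse = ", "))

  if (spec$mode == "refit") {
    tr <- oversample_minority(split$train_idx, fm$y, seed = stage_seed(seed, 101L))
    df <- data.frame(y = fm$y[tr], fm$X[tr, vars, drop = FALSE])
    glmfit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    fit <- list(kind = "glm", fit = glmfit, cols = vars,
                family = "risk_score")
  } else {
    co <- spec$coefficients
    b0 <- if ("(Intercept)" %in% names(co)) co[["(Intercept)"]] else 0
    co <- co[setdiff(names(co), "(Intercept)")]
    miss <- setdiff(names(co), fm$feature_names)
    if (length(miss))
      stopf("user coefficient variable(s) missing: %s", paste(miss, collapse = ", "))
    fit <- list(kind = "linear", w = co, b = b0, cols = names(co),
                family = "risk_score")
  }

  score_rows <- function(rows) {
    X <- fm$X[rows, fit$cols, drop = FALSE]
    if (fit$kind == "glm")
      as.numeric(stats::predict(fit$fit, newdata = as.data.frame(X),
                                type = "response"))
    else as.numeric(stats::plogis(X %*% fit$w + fit$b))
  }
  val_scores <- score_rows(split$val_idx)
  yva <- fm$y[split$val_idx]
  thr <- if (length(unique(yva)) >= 2 && length(unique(val_scores)) > 1)
    youden_threshold(val_scores, yva) else 0.5

  structure(list(
    spec = spec, fit = fit, selected_features = unname(vars),
    base_features = character(0), decision_threshold = thr,
    val_auc = if (length(unique(yva)) >= 2) auc(val_scores, yva) else NA_real_,
    trace = NULL
  ), class = c("fitted_risk_score", "fitted_classifier"))
}

#' @export
predict.fitted_risk_score <- function(object, fm, rows, ...) {
  if (!length(rows)) return(list(scores = numeric(0), calls = integer(0)))
  X <- fm$X[rows, object$fit$cols, drop = FALSE]
  scores <- if (object$fit$kind == "glm")
    as.numeric(stats::predict(object$fit$fit, newdata = as.data.frame(X),
                              type = "response"))
  else as.numeric(stats::plogis(X %*% object$fit$w + object$fit$b))
  list(scores = scores,
       calls = as.integer(scores >= object$decision_threshold))
}
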