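test_that("Youden threshold matches an exhaustive scan", {
  # perfect separation: any threshold in (0.2, 0.8); midpoint 0.5 returned
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)

  # constant scores: J = 0, the single value is returned
  expect_equal(youden_threshold(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)

  # 10-point hand case vs brute force over a fine threshold grid
  set.seed(5)
  s <- round(runif(10), 3)
  l <- rbinom(10, 1, 0.5)
  if (length(unique(l)) < 2) l[1] <- 1 - l[1]
  thr <- youden_threshold(s, l)
  j_at <- function(t) {
    calls <- s >= t
    sum(calls & l == 1) / sum(l) + sum(!calls & l == 0) / sum(1 - l) - 1
  }
  grid <- seq(min(s) - 0.01, max(s) + 0.01, by = 1e-4)
  expect_equal(j_at(thr), max(vapply(grid, j_at, numeric(1))),
               tolerance = 1e-12)

  expect_error(youden_threshold(1:5, rep(1, 5)), "both classes")
})

test_that("forward feature search finds the brute-force optimum on a toy", {
  # y depends on f1 + f2; f3 is noise, f4 duplicates f1
  set.seed(9)
  n <- 300
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  X <- cbind(X, f4 = X[, "f1"])
  y <- as.integer(X[, "f1"] + X[, "f2"] + rnorm(n, sd = 0.4) > 0)
  fm <- toy_fm(X, y)
  sp <- toy_split(1:180, 181:240, 241:300)

  sel <- forward_feature_search(fm, sp, budget = 2, seed = 1)
  expect_length(sel, 2)

  # brute-force oracle over all subsets of size <= 2 with the same family
  tr <- oversample_minority(sp$train_idx, fm$y,
                            seed = edrva::stage_seed(1, 101L))
  val_auc <- function(cols) {
    df <- data.frame(y = fm$y[tr], fm$X[tr, cols, drop = FALSE])
    f <- suppressWarnings(glm(y ~ ., binomial(), data = df))
    nd <- as.data.frame(fm$X[sp$val_idx, cols, drop = FALSE])
    auc(predict(f, newdata = nd), fm$y[sp$val_idx])
  }
  subsets <- c(as.list(colnames(X)), combn(colnames(X), 2, simplify = FALSE))
  best <- subsets[[which.max(vapply(subsets, val_auc, numeric(1)))]]
  expect_setequal(sel, best)

  # duplicated feature is never selected twice
  expect_false(all(c("f1", "f4") %in% sel))

  # budget 1 returns the single best univariate candidate
  sel1 <- forward_feature_search(fm, sp, budget = 1, seed = 1)
  uni <- vapply(colnames(X), function(cc) val_auc(cc), numeric(1))
  expect_equal(unname(uni[sel1]), max(uni), tolerance = 1e-9)

  # the validation-AUC trace never decreases
  expect_true(all(diff(c(0.5, attr(sel, "trace"))) >= 0))
})

test_that("classifier fits separate linearly separable data and stay honest under permuted labels", {
  set.seed(13)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(X[, 1] > 0)
  fm <- toy_fm(X, y)
  sp <- toy_split(1:240, 241:320, 321:400)
  f <- fit_classifier(classifier_spec("l1_logistic", seed = 1), fm, sp)
  pr_tr <- predict(f, fm, sp$train_idx)
  expect_equal(auc(pr_tr$scores, fm$y[sp$train_idx]), 1.0, tolerance = 1e-9)

  # permuted labels: validation AUC near 1/2 across a few permutations
  aucs <- vapply(1:5, function(s) {
    yp <- edrva:::with_seed(s, sample(y))
    fmp <- toy_fm(X, yp)
    fp <- fit_classifier(classifier_spec("l1_logistic", seed = s), fmp, sp)
    fp$val_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("boosted-tree families train and threshold on validation only", {
  td <- toy_cluster_data(n = 500, rate = c(0.1, 0.6))
  sp <- monthly_split(td$fm, seed = 2)
  for (fam in c("xgboost", "gbdt")) {
    f <- fit_classifier(classifier_spec(fam, seed = 3), td$fm, sp)
    pr <- predict(f, td$fm, sp$test_idx)
    expect_true(all(pr$scores >= 0 & pr$scores <= 1))
    expect_gt(auc(pr$scores, td$fm$y[sp$test_idx]), 0.6)
  }
})

test_that("decision thresholds never see test labels", {
  td <- toy_cluster_data(n = 500, rate = c(0.1, 0.6), seed = 77)
  sp <- monthly_split(td$fm, seed = 4)
  f1 <- fit_classifier(classifier_spec("l1_logistic", seed = 5), td$fm, sp)
  fm2 <- td$fm
  fm2$y[sp$test_idx] <- edrva:::with_seed(1, sample(fm2$y[sp$test_idx]))
  f2 <- fit_classifier(classifier_spec("l1_logistic", seed = 5), fm2, sp)
  expect_identical(f1$decision_threshold, f2$decision_threshold)
})

test_that("score >= threshold is a positive call and empty rows give empty output", {
  td <- toy_cluster_data(n = 300, rate = c(0.1, 0.6))
  sp <- monthly_split(td$fm, seed = 2)
  f <- fit_classifier(classifier_spec("l1_logistic", seed = 1), td$fm, sp)
  pr <- predict(f, td$fm, sp$test_idx)
  expect_identical(pr$calls, as.integer(pr$scores >= f$decision_threshold))
  pr0 <- predict(f, td$fm, integer(0))
  expect_length(pr0$scores, 0)
  expect_length(pr0$calls, 0)
})

test_that("refit risk score equals an independent IRLS logistic fit", {
  cc <- small_cohort()
  rs <- fit_risk_score(risk_score_spec("refit"), cc$fm, cc$sp, seed = 2)
  expect_length(rs$selected_features, 5)  # BMI-omitted 5-variable score

  # independent oracle: Newton-Raphson IRLS written out by hand
  tr <- oversample_minority(cc$sp$train_idx, cc$fm$y,
                            seed = edrva::stage_seed(2, 101L))
  Xd <- cbind(1, cc$fm$X[tr, rs$fit$cols])
  yv <- cc$fm$y[tr]
  beta <- rep(0, ncol(Xd))
  for (i in 1:50) {
    p <- plogis(as.vector(Xd %*% beta))
    W <- p * (1 - p)
    beta_new <- beta + solve(crossprod(Xd, Xd * W), crossprod(Xd, yv - p))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- as.vector(beta_new)
  }
  expect_equal(unname(coef(rs$fit$fit)), unname(as.vector(beta)),
               tolerance = 1e-6)

  # all-zero user coefficients give a constant score
  rs0 <- fit_risk_score(
    risk_score_spec("user_coefficients",
                    coefficients = c(age = 0, sbp_mean = 0, pulse_mean = 0,
                                     elixhauser_score = 0, ed_los = 0)),
    cc$fm, cc$sp)
  pr <- predict(rs0, cc$fm, cc$sp$test_idx)
  expect_equal(length(unique(pr$scores)), 1)

  # missing variable is a named error
  spec_bad <- risk_score_spec("refit", variables = c(age = "age", x = "nope",
                                                     p = "pulse_mean",
                                                     c = "elixhauser_score",
                                                     l = "ed_los"))
  expect_error(fit_risk_score(spec_bad, cc$fm, cc$sp), "nope")
})
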