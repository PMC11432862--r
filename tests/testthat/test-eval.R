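test_that("rank-based AUC equals all-pairs counting with ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0.0)

  set.seed(3)
  s <- sample(round(runif(8), 1))  # duplicates likely -> exercises ties
  l <- c(0, 1, 0, 1, 1, 0, 0, 1)
  pairs <- expand.grid(i = which(l == 1), j = which(l == 0))
  oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                        ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(auc(s, l), oracle, tolerance = 1e-12)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("confusion metrics satisfy the likelihood-ratio identity", {
  calls <- c(1, 1, 0, 0, 1, 0)
  labels <- c(1, 0, 1, 0, 1, 0)
  cm <- confusion_metrics(calls, labels)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 2 / 3)
  expect_equal(cm$plr, cm$sensitivity / (1 - cm$specificity))

  # all calls correct: specificity 1 -> infinite PLR flagged
  cm2 <- confusion_metrics(labels, labels)
  expect_identical(cm2$plr, Inf)
  expect_true(cm2$infinite_plr)
})

test_that("stratified bootstrap CIs behave at the edges and cover", {
  # degenerate identical scores: interval collapses to a point
  ci <- bootstrap_ci(auc, rep(0.3, 40), rep(c(0, 1), 20), B = 200, seed = 1)
  expect_equal(ci[1], ci[2])

  # separable scores: interval hugs 1
  ci2 <- bootstrap_ci(auc, c(rnorm(200), rnorm(50, 10)),
                      rep(c(0, 1), c(200, 50)), B = 200, seed = 1)
  expect_gt(ci2[1], 0.99)

  # nominal coverage on binormal scores (moderate replicate count)
  true_auc <- pnorm(1 / sqrt(2))
  hits <- vapply(1:60, function(r) {
    y <- rep(c(0, 1), c(150, 150))
    s <- c(rnorm(150), rnorm(150, 1))
    ci <- bootstrap_ci(auc, s, y, B = 200, seed = r)
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)  # 95% nominal, binomial noise at 60 reps
  expect_error(bootstrap_ci(auc, 1:10, rep(0:1, 5), B = 50), "B must be")
})

test_that("subgroup AUCs reduce to the overall AUC for the whole cohort", {
  set.seed(8)
  s <- runif(300); y <- rbinom(300, 1, plogis(3 * s - 2))
  res <- subgroup_aucs(s, y, list(all = rep("everyone", 300)), B = 200)
  expect_equal(res$auc[1], auc(s, y), tolerance = 1e-12)

  # single-class group is skipped with a note; tiny group flagged
  g <- rep(c("big", "tiny"), c(295, 5))
  y2 <- y; y2[g == "tiny"] <- 0
  res2 <- subgroup_aucs(s, y2, list(grp = g), B = 200)
  tiny <- res2[res2$level == "tiny", ]
  expect_true(is.na(tiny$auc))
  expect_match(tiny$note, "skipped")
})

test_that("attribution ranking is exact for linear models and matches brute-force Shapley", {
  set.seed(4)
  n <- 200
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- as.integer(2 * X[, 1] + 1 * X[, 2] + rnorm(n, sd = 0.5) > 0)
  fm <- toy_fm(X, y)
  sp <- toy_split(1:120, 121:160, 161:200)
  f <- fit_classifier(classifier_spec("l1_logistic", seed = 1), fm, sp)
  rows <- sp$test_idx
  rank_tab <- attribution_ranking(f, fm, rows, top_n = 3)
  expect_equal(rank_tab$feature[1:2], c("f1", "f2"))

  # exhaustive-coalition Shapley oracle on the model's link score, with the
  # off-coalition features fixed at their row means
  co <- as.numeric(coef(f$fit$fit))
  link <- function(x) co[1] + sum(co[-1] * x)
  mu <- colMeans(fm$X[rows, ])
  shap_row <- function(x) {
    vapply(1:3, function(j) {
      others <- setdiff(1:3, j)
      total <- 0
      for (size in 0:2) for (S in if (size) combn(others, size,
                                                  simplify = FALSE) else list(integer(0))) {
        w <- factorial(size) * factorial(3 - size - 1) / factorial(3)
        base <- mu; base[S] <- x[S]
        with_j <- base; with_j[j] <- x[j]
        total <- total + w * (link(with_j) - link(base))
      }
      total
    }, numeric(1))
  }
  phi_oracle <- t(apply(fm$X[rows, ], 1, shap_row))
  oracle_rank <- colnames(X)[order(colMeans(abs(phi_oracle)),
                                   decreasing = TRUE)]
  expect_equal(rank_tab$feature, oracle_rank)
  oracle_vals <- sort(colMeans(abs(phi_oracle)), decreasing = TRUE)
  expect_equal(rank_tab$mean_abs_attr, unname(oracle_vals), tolerance = 1e-8)
})

test_that("tree-model attribution puts a lone informative feature first", {
  set.seed(6)
  n <- 400
  X <- cbind(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- as.integer(X[, 1] + rnorm(n, sd = 0.3) > 0)
  fm <- toy_fm(X, y)
  sp <- toy_split(1:240, 241:320, 321:400)
  f <- fit_classifier(classifier_spec("xgboost", seed = 2), fm, sp)
  rank_tab <- attribution_ranking(f, fm, sp$test_idx, top_n = 3)
  expect_equal(rank_tab$feature[1], "sig")
})

test_that("chi-square category comparison matches the textbook formula", {
  cmp <- category_comparison(c(infection = 30, other = 50),
                             c(infection = 9, other = 71))
  row <- cmp$table[cmp$table$category == "infection", ]
  # continuity-corrected chi-square on the 2x2 (30,50 / 9,71)
  tab <- matrix(c(30, 50, 9, 71), 2, byrow = TRUE)
  n <- sum(tab)
  num <- n * (abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) - n / 2)^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  expect_equal(row$statistic, num / den, tolerance = 1e-10)
  expect_equal(row$p_raw, pchisq(num / den, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical distributions: corrected statistic 0, p = 1
  same <- category_comparison(c(a = 20, b = 20), c(a = 20, b = 20))
  expect_true(all(same$table$p_raw > 0.999))

  # Holm-adjusted p never below raw p; tiny expected cells fall back to exact
  cmp2 <- category_comparison(c(a = 40, b = 39, c = 1),
                              c(a = 42, b = 38, c = 0))
  expect_true(all(cmp2$table$p_adj >= cmp2$table$p_raw))
  expect_true("fisher" %in% cmp2$table$test)
})

test_that("discharge-variable ablation removes flagged features and reports the delta", {
  cc <- small_cohort()
  seen <- list()
  res <- ablation_discharge_vars(cc$fm, function(fm) {
    seen[[length(seen) + 1]] <<- fm$feature_names
    length(fm$feature_names)  # stand-in metric: feature count
  })
  expect_true(all(!grepl("^disposition_", seen[[2]])))
  expect_false("ed_los" %in% seen[[2]])
  expect_equal(res$delta, res$auc_ablated - res$auc_full)

  fm0 <- cc$fm
  fm0$discharge_related[] <- FALSE
  expect_warning(res0 <- ablation_discharge_vars(fm0, function(fm) 1),
                 "no-op")
  expect_equal(res0$delta, 0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- c(rnorm(80), rnorm(40, 0.8)); s[1:10] <- s[11:20]  # inject ties
  y <- rep(c(0, 1), c(80, 40))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(s, y), ref, tolerance = 1e-12)
})
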