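# hand-built DICE model with an identity (linear) encoder, used to test
# membership geometry without any training
identity_dice_model <- function(centroids, tau = 1) {
  d <- ncol(centroids)
  structure(list(
    encoder = list(list(W = diag(d), b = rep(0, d))),
    decoder = list(list(W = diag(d), b = rep(0, d))),
    centroids = centroids,
    head = list(w = rep(0, nrow(centroids)), b = 0),
    chosen_k = nrow(centroids),
    config = dice_config(latent_dim = d, tau = tau),
    feature_names = paste0("f", seq_len(d))
  ), class = "dice_model")
}

test_that("membership probabilities are simplex-valid softmin weights", {
  C <- rbind(c(0, 0), c(4, 0))
  m <- identity_dice_model(C)
  X <- rbind(c(0, 0), c(2, 0), c(4, 0), c(1, 3))
  fm <- toy_fm(X, y = c(0, 0, 1, 1))
  asg <- assign_clusters(m, fm, 1:4)
  expect_true(all(asg$membership >= 0))
  expect_equal(rowSums(asg$membership), rep(1, 4), tolerance = 1e-9)

  # equidistant row splits exactly 50/50
  expect_equal(unname(asg$membership[2, ]), c(0.5, 0.5), tolerance = 1e-12)

  # at a centroid with tau -> 0 the membership concentrates to 1
  asg0 <- assign_clusters(m, fm, 1:4, tau = 1e-4)
  expect_equal(unname(asg0$membership[1, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(asg0$membership[3, 2]), 1, tolerance = 1e-9)
})

test_that("risk ratio is max over min rate with an infinity flag", {
  expect_equal(risk_ratio(c(0.02, 0.02)), 1.0)
  expect_equal(risk_ratio(c(0.10, 0.01)), 10.0)
  expect_equal(risk_ratio(c(0.0045, 0.0010)), 4.5)
  expect_identical(risk_ratio(c(0, 0.1)), Inf)
  expect_error(risk_ratio(0.1), ">= 2")
})

test_that("Wald record agrees with a closed-form 2x2 logistic fit", {
  # hand-built outcome x cluster table: 30/470 events in cluster 2,
  # 10/490 in cluster 1
  y <- c(rep(c(1L, 0L), c(10, 490)), rep(c(1L, 0L), c(30, 470)))
  cl <- factor(rep(1:2, each = 500))
  w <- edrva:::cluster_wald(y, cl)
  beta <- log((30 / 470) / (10 / 490))
  se <- sqrt(1 / 30 + 1 / 470 + 1 / 10 + 1 / 490)
  p_closed <- 2 * (1 - pnorm(abs(beta / se)))
  expect_equal(w$table$estimate, beta, tolerance = 1e-6)
  expect_equal(w$table$p, p_closed, tolerance = 1e-3)
  expect_equal(w$max_adjacent_p, w$min_p, tolerance = 1e-12)  # K = 2 coincide
})

test_that("joint training gradients match finite differences", {
  set.seed(1)
  n <- 12; d <- 4; k <- 2; latent <- 2; tau <- 1
  X <- matrix(rnorm(n * d), n, d)
  y <- rbinom(n, 1, 0.4)
  enc <- edrva:::mlp_init(c(d, 3, latent))
  dec <- edrva:::mlp_init(c(latent, 3, d))
  C <- matrix(rnorm(k * latent), k, latent)
  w <- rnorm(k); b0 <- 0.1
  lw <- c(recon = 1, cluster = 1, outcome = 1)

  loss_fn <- function(enc) {
    Z <- edrva:::mlp_forward(enc, X)[[3]]
    Xh <- edrva:::mlp_forward(dec, Z)[[3]]
    d2 <- edrva:::latent_dist2(Z, C)
    ca <- apply(d2, 1, which.min)
    m <- edrva:::softmin_membership(d2, tau)
    p <- plogis(as.vector(m %*% w) + b0)
    sum((X - Xh)^2) / n + sum((Z - C[ca, ])^2) / n -
      mean(y * log(p) + (1 - y) * log(1 - p))
  }

  # analytic gradient wrt encoder first-layer weights, assignments frozen
  acts_e <- edrva:::mlp_forward(enc, X)
  Z <- acts_e[[3]]
  acts_d <- edrva:::mlp_forward(dec, Z)
  Xh <- acts_d[[3]]
  d2 <- edrva:::latent_dist2(Z, C)
  ca <- apply(d2, 1, which.min)
  m <- edrva:::softmin_membership(d2, tau)
  p <- plogis(as.vector(m %*% w) + b0)
  gz <- edrva:::mlp_backward(dec, acts_d, 2 * (Xh - X) / n)$grad_input
  gz <- gz + 2 * (Z - C[ca, ]) / n
  resid <- (p - y) / n
  sbar <- as.vector(m %*% w)
  coefm <- (resid * (-1 / tau)) * m * (matrix(w, n, k, byrow = TRUE) - sbar)
  gz <- gz + 2 * (rowSums(coefm) * Z - coefm %*% C)
  g_analytic <- edrva:::mlp_backward(enc, acts_e, gz)$grads[[1]]$W

  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
    ep <- enc; ep[[1]]$W[idx[1], idx[2]] <- ep[[1]]$W[idx[1], idx[2]] + eps
    em <- enc; em[[1]]$W[idx[1], idx[2]] <- em[[1]]$W[idx[1], idx[2]] - eps
    g_num <- (loss_fn(ep) - loss_fn(em)) / (2 * eps)
    expect_equal(g_analytic[idx[1], idx[2]], g_num, tolerance = 1e-5)
  }
})

test_that("DICE recovers a well-separated planted clustering", {
  td <- toy_cluster_data(n = 600, shift = 4, rate = c(0.05, 0.4))
  sp <- monthly_split(td$fm, seed = 1)
  cfg <- dice_config(latent_dim = 2, max_epochs = 60, pretrain_epochs = 60,
                     learning_rate = 0.02, seed = 3)
  dm <- fit_dice(td$fm, sp, cfg, k = 2)
  expect_true(dm$significant)
  asg <- assign_clusters(dm, td$fm, sp$test_idx)
  expect_gte(ari(asg$hard, td$cluster[sp$test_idx]), 0.9)
  # risk-ordering convention: cluster 1 has the lowest training rate
  expect_equal(dm$train_cluster_rates, sort(dm$train_cluster_rates))
  expect_gte(asg$risk_ratio, 1)
})

test_that("fixed seeds reproduce centroids exactly", {
  td <- toy_cluster_data(n = 300)
  sp <- monthly_split(td$fm, seed = 1)
  cfg <- dice_config(latent_dim = 2, max_epochs = 10, pretrain_epochs = 10,
                     seed = 11)
  d1 <- fit_dice(td$fm, sp, cfg, k = 2, enforce_significance = FALSE)
  d2 <- fit_dice(td$fm, sp, cfg, k = 2, enforce_significance = FALSE)
  expect_identical(d1$centroids, d2$centroids)
  expect_identical(d1$wald, d2$wald)
})

test_that("degenerate loss weights reduce to a plain autoencoder near the PCA optimum", {
  set.seed(2)
  X <- matrix(rnorm(500 * 10), 500, 10) %*% matrix(rnorm(100, sd = 0.6), 10, 10)
  X <- scale(X)
  fm <- toy_fm(X, y = rbinom(500, 1, 0.3))
  sp <- toy_split(1:400, 401:450, 451:500)
  cfg <- dice_config(latent_dim = 3, loss_weights = c(1, 0, 0),
                     max_epochs = 150, pretrain_epochs = 150,
                     learning_rate = 0.02, seed = 4,
                     oversample_ratio = 0.01)
  dm <- fit_dice(fm, sp, cfg, k = 2, enforce_significance = FALSE)
  Z <- edrva:::mlp_forward(dm$encoder, X[1:400, ])[[2]]
  Xh <- edrva:::mlp_forward(dm$decoder, Z)[[2]]
  ae_err <- mean(rowSums((X[1:400, ] - Xh)^2))
  pc <- prcomp(X[1:400, ])
  pca_err <- sum(pc$sdev[-(1:3)]^2) * (399 / 400)
  expect_lt(ae_err, 1.25 * pca_err)   # close to the linear optimum
  expect_gt(ae_err, 0.95 * pca_err)   # and not impossibly below it
})

test_that("architecture search prefers the planted K and breaks ties downward", {
  cc <- small_cohort()
  cfg <- dice_config(k_candidates = c(2L, 3L), seed = 21)
  dm <- search_architecture(cc$fm, cc$sp, cfg)
  expect_true(dm$significant)
  expect_true(dm$chosen_k %in% cfg$k_candidates)
  expect_s3_class(dm$search_record, "data.frame")

  # single candidate reduces to fit_dice
  cfg1 <- dice_config(k_candidates = 2L, seed = 21)
  d1 <- search_architecture(cc$fm, cc$sp, cfg1)
  expect_equal(d1$chosen_k, 2L)
})

test_that("a null cohort fails the significance gate", {
  spec <- cohort_spec(2500, seed = 31, cluster_risk_ratio = 1.0)
  tab <- generate_cohort(spec)
  sp <- monthly_split(list(month = tab$month, y = tab$outcome), seed = 32)
  fm <- build_matrix(tab, sp$train_idx)
  expect_error(fit_dice(fm, sp, dice_config(seed = 33), k = 2),
               class = "no_significant_clustering")
})
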