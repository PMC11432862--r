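#' Configuration for deep significance clustering (DICE)
#'
#' DICE jointly learns an autoencoder representation, k-means centroids in
#' the latent space, and a logistic outcome head on soft cluster
#' memberships, minimizing
#' `L = a * reconstruction + b * latent-to-centroid distance + g * outcome
#' cross-entropy`, and only accepts a clustering whose cluster-outcome
#' association is statistically significant by a Wald test.
#'
#' @param latent_dim latent representation width. Default 8.
#' @param encoder_layers integer vector of hidden-layer widths between input
#'   and latent (tanh activations); `integer(0)` gives a linear encoder.
#' @param k_candidates candidate numbers of clusters for the architecture
#'   search. Default `2:5`.
#' @param loss_weights nonnegative weights `(recon, cluster, outcome)`, not
#'   all zero. Default `c(1, 1, 1)`.
#' @param alpha_sig significance level of the Wald gate, in (0,1).
#'   Default 0.05.
#' @param max_epochs joint-objective gradient epochs. Default 40.
#' @param pretrain_epochs reconstruction-only epochs run before the joint
#'   objective engages (and before centroids are first estimated), so
#'   k-means starts from a representation that already reflects the data
#'   geometry rather than the random initialization. Default 40.
#' @param learning_rate Adam step size. Default 0.01.
#' @param batch_size minibatch size; `Inf` (default) trains full-batch.
#' @param tau softmin temperature for membership probabilities. Default 1.
#' @param kmeans_every re-estimate centroids by k-means every this many
#'   epochs. Default 5.
#' @param oversample_ratio minority:majority ratio used to oversample the
#'   training rows the encoder sees. Default 1.0.
#' @param seed integer seed.
#' @return an object of class `dice_config`.
#' @export
dice_config <- function(latent_dim = 8L,
                        encoder_layers = integer(0),
                        k_candidates = 2:5,
                        loss_weights = c(recon = 1, cluster = 1, outcome = 1),
                        alpha_sig = 0.05,
                        max_epochs = 40L,
                        pretrain_epochs = 40L,
                        learning_rate = 0.01,
                        batch_size = Inf,
                        tau = 1,
                        kmeans_every = 5L,
                        oversample_ratio = 0.1,
                        seed = 1L) {
  if (length(loss_weights) != 3 || any(loss_weights < 0) || all(loss_weights == 0))
    stopf("loss_weights must be 3 nonnegative values, not all zero")
  names(loss_weights) <- c("recon", "cluster", "outcome")
  if (!is_prob(alpha_sig)) stopf("alpha_sig must be in (0,1)")
  if (any(k_candidates < 2)) stopf("k_candidates must all be >= 2")
  structure(list(
    latent_dim = as.integer(latent_dim),
    encoder_layers = as.integer(encoder_layers),
    k_candidates = sort(unique(as.integer(k_candidates))),
    loss_weights = loss_weights,
    alpha_sig = alpha_sig,
    max_epochs = as.integer(max_epochs),
    pretrain_epochs = as.integer(pretrain_epochs),
    learning_rate = learning_rate,
    batch_size = batch_size,
    tau = tau,
    kmeans_every = as.integer(kmeans_every),
    oversample_ratio = oversample_ratio,
    seed = as.integer(seed)
  ), class = "dice_config")
}

# ---- small MLP machinery (tanh hidden layers, linear final layer) ----

mlp_init <- function(widths) {
  # widths: input, hidden..., output; Xavier-scaled gaussian init
  L <- length(widths) - 1
  lapply(seq_len(L), function(l) {
    fan_in <- widths[l]
    list(W = matrix(stats::rnorm(widths[l] * widths[l + 1], 0,
                                 sqrt(1 / fan_in)),
                    widths[l], widths[l + 1]),
         b = rep(0, widths[l + 1]))
  })
}

mlp_forward <- function(params, X) {
  L <- length(params)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    a <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
    acts[[l + 1]] <- if (l < L) tanh(a) else a
  }
  acts
}

# grad_out: dL/d(output); returns list(grads, grad_input)
mlp_backward <- function(params, acts, grad_out) {
  L <- length(params)
  grads <- vector("list", L)
  delta <- grad_out
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (1 - acts[[l + 1]]^2)  # through tanh
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(params[[l]]$W)
  }
  list(grads = grads, grad_input = delta)
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    g <- grads[[l]]; s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    params[[l]]$W <- params[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

# squared distances of latent rows to centroids: n x K
latent_dist2 <- function(Z, C) {
  outer(rowSums(Z^2), rep(1, nrow(C))) - 2 * Z %*% t(C) +
    outer(rep(1, nrow(Z)), rowSums(C^2))
}

# softmin memberships over squared distances, numerically stabilized
softmin_membership <- function(d2, tau) {
  e <- -d2 / tau
  e <- e - apply(e, 1, max)
  m <- exp(e)
  m / rowSums(m)
}

#' Fit a DICE model
#'
#' Trains the joint objective on the (minority-oversampled) training rows:
#' Adam gradient epochs on the autoencoder and outcome head, with centroids
#' re-estimated by k-means on the current latent representation every
#' `cfg$kmeans_every` epochs. After training, clusters are relabeled so
#' cluster 1 has the lowest training outcome rate, and a logistic model
#' `outcome ~ cluster` is fitted by [stats::glm()] on the *original*
#' (non-duplicated) training rows; the model is rejected unless some cluster
#' coefficient's Wald p-value is below `cfg$alpha_sig` (oversampling
#' duplicates would otherwise understate the standard errors).
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_bundle`.
#' @param cfg a `dice_config`; `cfg$k_candidates[1]` sets K (use
#'   [search_architecture()] to search over K).
#' @param k number of clusters; defaults to the first candidate in `cfg`.
#' @param enforce_significance if TRUE (default), a clustering failing the
#'   Wald gate raises a condition of class `no_significant_clustering`
#'   reporting the best attained p-value; if FALSE the (rejected) model is
#'   returned with `significant = FALSE`.
#' @return an object of class `dice_model`: encoder/decoder parameters,
#'   `centroids` (K x latent_dim, risk-ordered), logistic `head`
#'   (coefficients and per-cluster Wald estimate/SE/z/p), `chosen_k`,
#'   training `history`, the config and the significance record.
#' @export
fit_dice <- function(fm, split, cfg = dice_config(), k = NULL,
                     enforce_significance = TRUE) {
  k <- as.integer(k %||% cfg$k_candidates[1])
  tr_raw <- split$train_idx
  tr <- oversample_minority(tr_raw, fm$y, cfg$oversample_ratio,
                            seed = stage_seed(cfg$seed, 101L))
  X <- fm$X[tr, , drop = FALSE]
  y <- fm$y[tr]
  if (length(unique(y)) < 2) stopf("training rows must contain both classes")
  n <- nrow(X); d <- ncol(X)
  lw <- cfg$loss_weights
  tau <- cfg$tau

  with_seed(stage_seed(cfg$seed, 1L), {
    widths_enc <- c(d, cfg$encoder_layers, cfg$latent_dim)
    widths_dec <- c(cfg$latent_dim, rev(cfg$encoder_layers), d)
    enc <- mlp_init(widths_enc)
    dec <- mlp_init(widths_dec)
    head_w <- rep(0, k); head_b <- stats::qlogis(max(mean(y), 1e-6))
    st_enc <- adam_init(enc); st_dec <- adam_init(dec)
    head_m <- rep(0, k + 1); head_v <- rep(0, k + 1)

    # reconstruction-only pretraining so the first k-means sees a latent
    # space that reflects the data geometry
    t_pre <- 0
    for (ep in seq_len(cfg$pretrain_epochs)) {
      acts_e <- mlp_forward(enc, X)
      Zp <- acts_e[[length(enc) + 1]]
      acts_d <- mlp_forward(dec, Zp)
      g <- 2 * (acts_d[[length(dec) + 1]] - X) / n
      bw_d <- mlp_backward(dec, acts_d, g)
      bw_e <- mlp_backward(enc, acts_e, bw_d$grad_input)
      t_pre <- t_pre + 1
      up <- adam_step(dec, bw_d$grads, st_dec, cfg$learning_rate, t_pre)
      dec <- up$params; st_dec <- up$state
      up <- adam_step(enc, bw_e$grads, st_enc, cfg$learning_rate, t_pre)
      enc <- up$params; st_enc <- up$state
    }

    Z <- mlp_forward(enc, X)[[length(enc) + 1]]
    km <- kmeans_safe(Z, k)
    C <- km$centers
    assign_hard <- km$cluster

    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          recon = numeric(0), cluster = numeric(0),
                          outcome = numeric(0))
    t_adam <- 0
    bs <- if (is.finite(cfg$batch_size)) as.integer(cfg$batch_size) else n

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep_loss <- c(0, 0, 0)
      for (start in seq(1, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1, n)]
        nb <- length(rows)
        Xb <- X[rows, , drop = FALSE]; yb <- y[rows]
        ca <- assign_hard[rows]

        acts_e <- mlp_forward(enc, Xb)
        Zb <- acts_e[[length(enc) + 1]]
        acts_d <- mlp_forward(dec, Zb)
        Xhat <- acts_d[[length(dec) + 1]]

        d2 <- latent_dist2(Zb, C)
        m <- softmin_membership(d2, tau)
        s <- as.vector(m %*% head_w) + head_b
        p <- stats::plogis(s)

        l_rec <- sum((Xb - Xhat)^2) / nb
        l_clu <- sum((Zb - C[ca, , drop = FALSE])^2) / nb
        l_out <- -mean(yb * log(pmax(p, 1e-12)) +
                       (1 - yb) * log(pmax(1 - p, 1e-12)))
        ep_loss <- ep_loss + nb / n * c(l_rec, l_clu, l_out)

        # backprop: reconstruction through decoder
        g_xhat <- 2 * lw[["recon"]] * (Xhat - Xb) / nb
        bw_d <- mlp_backward(dec, acts_d, g_xhat)
        gz <- bw_d$grad_input
        # centroid-pull term
        gz <- gz + 2 * lw[["cluster"]] * (Zb - C[ca, , drop = FALSE]) / nb
        # outcome term through softmin memberships
        resid <- lw[["outcome"]] * (p - yb) / nb
        sbar <- as.vector(m %*% head_w)
        coef <- (resid * (-1 / tau)) * m *
          (matrix(head_w, nb, k, byrow = TRUE) - sbar)
        gz <- gz + 2 * (rowSums(coef) * Zb - coef %*% C)
        bw_e <- mlp_backward(enc, acts_e, gz)

        g_w <- as.vector(crossprod(m, resid))
        g_b <- sum(resid)

        t_adam <- t_adam + 1
        up <- adam_step(dec, bw_d$grads, st_dec, cfg$learning_rate, t_adam)
        dec <- up$params; st_dec <- up$state
        up <- adam_step(enc, bw_e$grads, st_enc, cfg$learning_rate, t_adam)
        enc <- up$params; st_enc <- up$state
        gh <- c(g_w, g_b)
        head_m <- 0.9 * head_m + 0.1 * gh
        head_v <- 0.999 * head_v + 0.001 * gh^2
        upd <- cfg$learning_rate * (head_m / (1 - 0.9^t_adam)) /
          (sqrt(head_v / (1 - 0.999^t_adam)) + 1e-8)
        head_w <- head_w - upd[seq_len(k)]
        head_b <- head_b - upd[k + 1]
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = sum(ep_loss * lw), recon = ep_loss[1],
        cluster = ep_loss[2], outcome = ep_loss[3]))

      if (epoch %% cfg$kmeans_every == 0 || epoch == cfg$max_epochs) {
        Z <- mlp_forward(enc, X)[[length(enc) + 1]]
        km <- kmeans_safe(Z, k, centers = C)
        C <- km$centers
        assign_hard <- km$cluster
      }
    }

    model <- structure(list(
      encoder = enc, decoder = dec, centroids = C,
      head = list(w = head_w, b = head_b),
      chosen_k = k, config = cfg, history = history,
      feature_names = fm$feature_names
    ), class = "dice_model")

    # risk-order relabeling + Wald gate on the original training rows
    z_raw <- dice_encode(model, fm$X[tr_raw, , drop = FALSE])
    hard_raw <- apply(latent_dist2(z_raw, C), 1, which.min)
    rate <- vapply(seq_len(k), function(cl) {
      r <- fm$y[tr_raw][hard_raw == cl]
      if (length(r)) mean(r) else NA_real_
    }, numeric(1))
    ord_k <- order(rate)  # NA (empty) clusters sort last
    model$centroids <- C[ord_k, , drop = FALSE]
    model$head$w <- head_w[ord_k]
    relabel <- match(seq_len(k), ord_k)
    hard_raw <- relabel[hard_raw]
    model$train_cluster_rates <- sort(rate)

    wald <- cluster_wald(fm$y[tr_raw], factor(hard_raw, levels = seq_len(k)))
    model$wald <- wald
    model$significant <- is.finite(wald$max_adjacent_p) &&
      wald$max_adjacent_p < cfg$alpha_sig
    if (enforce_significance && !model$significant) {
      cond <- structure(
        class = c("no_significant_clustering", "error", "condition"),
        list(message = sprintf(
          "no significant cluster-outcome association at alpha = %.3g (worst adjacent-pair Wald p = %.4g, K = %d)",
          cfg$alpha_sig, wald$max_adjacent_p, k),
          call = NULL, best_p = wald$max_adjacent_p))
      stop(cond)
    }
    model
  })
}

# k-means with fall-back re-initialization when a given-center start
# produces an empty cluster
kmeans_safe <- function(Z, k, centers = NULL) {
  if (!is.null(centers)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Z, centers = centers, iter.max = 50)),
      error = function(e) NULL)
    if (!is.null(km)) return(km)
  }
  suppressWarnings(stats::kmeans(Z, centers = k, nstart = 5, iter.max = 50))
}

# Wald record for the cluster-outcome association. Clusters are assumed
# risk-ordered (1 = lowest rate). Two views are computed from logistic fits:
#   * reference coding: outcome ~ cluster indicators, lowest-risk reference
#   * adjacent pairs: outcome ~ indicator on rows of clusters (j, j+1)
# The gate requires EVERY adjacent pair of risk tiers to differ
# significantly, so a clustering that merely sub-splits one tier (two
# clusters with the same outcome rate) is rejected even though its extreme
# tiers differ. For K = 2 both views coincide.
cluster_wald <- function(y, cluster) {
  present <- droplevels(cluster)
  if (nlevels(present) < 2)
    return(list(table = NULL, adjacent = NULL, min_p = NA_real_,
                max_adjacent_p = NA_real_))
  fit <- stats::glm(y ~ present, family = stats::binomial())
  cf <- summary(fit)$coefficients
  rows <- grep("^present", rownames(cf))
  tab <- data.frame(
    cluster = sub("^present", "", rownames(cf)[rows]),
    estimate = cf[rows, 1], se = cf[rows, 2],
    z = cf[rows, 3], p = cf[rows, 4], row.names = NULL)

  lev <- levels(present)
  adj <- do.call(rbind, lapply(seq_len(length(lev) - 1), function(j) {
    sel <- present %in% lev[c(j, j + 1)]
    pf <- stats::glm(y[sel] ~ (present[sel] == lev[j + 1]),
                     family = stats::binomial())
    pc <- summary(pf)$coefficients
    data.frame(pair = paste(lev[j], lev[j + 1], sep = "-"),
               estimate = pc[2, 1], se = pc[2, 2], z = pc[2, 3],
               p = pc[2, 4], row.names = NULL)
  }))
  list(table = tab, adjacent = adj, min_p = min(tab$p),
       max_adjacent_p = max(adj$p))
}

dice_encode <- function(model, X) {
  mlp_forward(model$encoder, X)[[length(model$encoder) + 1]]
}

#' @export
print.dice_model <- function(x, ...) {
  cat(sprintf("dice_model: K = %d, latent dim %d, %s (min Wald p = %.3g)\n",
              x$chosen_k, ncol(x$centroids),
              if (isTRUE(x$significant)) "significant" else "NOT significant",
              x$wald$min_p))
  cat("  training cluster outcome rates:",
      paste(sprintf("%.4f", x$train_cluster_rates), collapse = ", "), "\n")
  invisible(x)
}

#' Search cluster count and hyperparameters for DICE
#'
#' Deterministic grid search over `cfg$k_candidates` (optionally crossed
#' with a list of config overrides in `grid`). Candidates failing the Wald
#' significance gate are discarded; among the survivors the one maximizing
#' the validation AUC of a step-2 logistic classifier built on its cluster
#' membership probabilities is returned, ties broken toward smaller K.
#'
#' @param fm a `feature_matrix`.
#' @param split a `split_bundle`.
#' @param base_cfg a `dice_config`.
#' @param grid optional list of named config-override lists (e.g.
#'   `list(list(latent_dim = 4), list(latent_dim = 8))`).
#' @return the winning `dice_model`, with a `search_record` data.frame of
#'   candidate K, significance, best p and validation AUC attached.
#' @export
search_architecture <- function(fm, split, base_cfg = dice_config(),
                                grid = list(list())) {
  rec <- data.frame()
  best <- NULL; best_auc <- -Inf; best_p <- Inf
  for (gi in seq_along(grid)) {
    for (k in base_cfg$k_candidates) {
      cfg <- base_cfg
      for (nm in names(grid[[gi]])) cfg[[nm]] <- grid[[gi]][[nm]]
      cfg$seed <- stage_seed(base_cfg$seed, 1000L * gi + k)
      model <- tryCatch(fit_dice(fm, split, cfg, k = k),
                        no_significant_clustering = function(e) e)
      if (inherits(model, "no_significant_clustering")) {
        best_p <- min(best_p, model$best_p)
        rec <- rbind(rec, data.frame(grid = gi, k = k, significant = FALSE,
                                     min_p = model$best_p, val_auc = NA))
        next
      }
      va <- membership_val_auc(model, fm, split)
      rec <- rbind(rec, data.frame(grid = gi, k = k, significant = TRUE,
                                   min_p = model$wald$min_p, val_auc = va))
      if (va > best_auc) { best <- model; best_auc <- va }
    }
  }
  if (is.null(best)) {
    cond <- structure(
      class = c("no_significant_clustering", "error", "condition"),
      list(message = sprintf(
        "no candidate clustering passed the significance gate (best Wald p = %.4g)",
        best_p), call = NULL, best_p = best_p))
    stop(cond)
  }
  best$search_record <- rec
  best
}

# validation AUC of a logistic step-2 classifier on membership probabilities
membership_val_auc <- function(model, fm, split) {
  tr <- oversample_minority(split$train_idx, fm$y,
                            model$config$oversample_ratio,
                            seed = stage_seed(model$config$seed, 101L))
  m_tr <- assign_clusters(model, fm, tr)$membership
  m_va <- assign_clusters(model, fm, split$val_idx)$membership
  k <- ncol(m_tr)
  dat <- as.data.frame(m_tr[, -1, drop = FALSE])
  fit <- suppressWarnings(stats::glm(fm$y[tr] ~ ., data = dat,
                                     family = stats::binomial()))
  newd <- as.data.frame(m_va[, -1, drop = FALSE])
  auc(stats::predict(fit, newdata = newd, type = "link"), fm$y[split$val_idx])
}

#' Assign visits to DICE clusters
#'
#' Encodes the given rows and computes soft membership probabilities
#' `softmin(d^2 / tau)` over the centroids, hard labels (nearest centroid),
#' per-cluster outcome rates on those rows, and the risk ratio between the
#' highest- and lowest-rate clusters.
#'
#' @param model a fitted `dice_model`.
#' @param fm a `feature_matrix`.
#' @param rows integer row indices to assign.
#' @param tau softmin temperature; defaults to the training value.
#' @return an object of class `cluster_assignment`: `membership`
#'   (rows x K, simplex-valid), `hard` labels, `rates` and `risk_ratio`.
#' @export
assign_clusters <- function(model, fm, rows, tau = NULL) {
  tau <- tau %||% model$config$tau
  Z <- dice_encode(model, fm$X[rows, , drop = FALSE])
  d2 <- latent_dist2(Z, model$centroids)
  m <- softmin_membership(d2, tau)
  colnames(m) <- paste0("dice_cluster_p", seq_len(ncol(m)))
  hard <- apply(d2, 1, which.min)
  k <- nrow(model$centroids)
  rates <- vapply(seq_len(k), function(cl) {
    r <- fm$y[rows][hard == cl]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  if (anyNA(rates))
    warnf("empty cluster(s) on the given rows; risk ratio computed over nonempty clusters")
  structure(list(membership = m, hard = hard, rates = rates,
                 risk_ratio = risk_ratio(rates[!is.na(rates)])),
            class = "cluster_assignment")
}

#' Risk ratio between the highest- and lowest-rate clusters
#'
#' @param rates numeric vector of per-cluster outcome rates.
#' @return `max(rates) / min(rates)`; `Inf` when the minimum rate is 0.
#' @export
risk_ratio <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2) stopf("need >= 2 cluster rates")
  if (min(rates) == 0) return(Inf)
  max(rates) / min(rates)
}
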