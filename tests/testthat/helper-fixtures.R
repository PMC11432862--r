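# shared fixtures: small synthetic objects built in code at test time

# adjusted Rand index between two hard partitions (independent of the
# package's clustering code; used as the recovery yardstick)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# minimal feature_matrix for model-level tests, bypassing the generator
toy_fm <- function(X, y, month = NULL, train_frac = 0.6) {
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(
    X = X, feature_names = colnames(X), y = as.integer(y),
    month = month %||% rep(1L, n),
    groups = list(), normalization_stats = list(),
    discharge_related = stats::setNames(rep(FALSE, ncol(X)), colnames(X)),
    dropped = character(0), train_rows = integer(0)
  ), class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split bundle with explicit indices (no randomness)
toy_split <- function(train, val, test) {
  structure(list(train_idx = as.integer(train), val_idx = as.integer(val),
                 test_idx = as.integer(test), month_table = NULL,
                 ratios = c(0.8, 0.1, 0.1), seed = 0L),
            class = "split_bundle")
}

# separable two-cluster gaussian toy with outcome tied to cluster
toy_cluster_data <- function(n = 400, d = 6, shift = 3, rate = c(0.1, 0.5),
                             seed = 42) {
  set.seed(seed)
  cl <- rep(1:2, length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[cl == 2, 1:2] <- X[cl == 2, 1:2] + shift
  y <- rbinom(n, 1, rate[cl])
  month <- sample(1:3, n, TRUE)
  list(fm = toy_fm(X, y, month), cluster = cl)
}

# small generated cohort shared by several test files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(4000, seed = 7)
      tab <- generate_cohort(spec)
      sp <- monthly_split(list(month = tab$month, y = tab$outcome), seed = 8)
      fm <- build_matrix(tab, sp$train_idx)
      cache <<- list(tab = tab, sp = sp, fm = fm, spec = spec)
    }
    cache
  }
})
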