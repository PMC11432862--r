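#' Monthly-stratified train/validation/test split
#'
#' Partitions visits 8:1:1 (by default) within every calendar month, so each
#' partition reflects the seasonal case mix. Within a month, outcome-positive
#' and outcome-negative visits are apportioned separately by the
#' largest-remainder rule, so the rare positives are spread across partitions
#' proportionally where counts permit. Months with fewer than 3 visits go
#' entirely to training, with a warning.
#'
#' @param fm a `feature_matrix` (or any list with `month` and `y` vectors).
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed integer seed; assignment is deterministic given it.
#' @return an object of class `split_bundle`: disjoint, exhaustive
#'   `train_idx`, `val_idx`, `test_idx`, a per-month `month_table` of
#'   partition counts, `ratios` and `seed`.
#' @export
monthly_split <- function(fm, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stopf("ratios must sum to 1")
  month <- fm$month; y <- fm$y
  if (is.null(month) || is.null(y)) stopf("fm must carry month and y vectors")

  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  months <- sort(unique(month))
  mt <- matrix(0L, length(months), 3,
               dimnames = list(as.character(months), c("train", "val", "test")))

  with_seed(seed, {
    for (m in months) {
      rows <- which(month == m)
      if (length(rows) < 3) {
        warnf("month %s has %d visit(s); all assigned to training", m, length(rows))
        idx$train <- c(idx$train, rows)
        mt[as.character(m), "train"] <- length(rows)
        next
      }
      for (cls in c(0L, 1L)) {
        r <- rows[y[rows] == cls]
        if (!length(r)) next
        r <- r[sample.int(length(r))]
        sizes <- largest_remainder(length(r), ratios)
        cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
        idx$train <- c(idx$train, r[seq_len(cut1)])
        if (sizes[2] > 0) idx$val <- c(idx$val, r[(cut1 + 1):cut2])
        if (sizes[3] > 0) idx$test <- c(idx$test, r[(cut2 + 1):length(r)])
        mt[as.character(m), ] <- mt[as.character(m), ] + sizes
      }
    }
  })

  structure(list(
    train_idx = sort(idx$train), val_idx = sort(idx$val),
    test_idx = sort(idx$test),
    month_table = mt, ratios = ratios, seed = as.integer(seed)
  ), class = "split_bundle")
}

#' @export
print.split_bundle <- function(x, ...) {
  cat(sprintf("split_bundle: train %d / val %d / test %d (seed %d)\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx),
              x$seed))
  invisible(x)
}

#' Oversample the minority class of the training partition
#'
#' Resamples minority-class training rows with replacement until the
#' minority:majority ratio reaches `target_ratio`. All original training
#' rows are retained; validation and test rows are never touched. The rare
#' 72-hour RVA outcome (~0.8% prevalence) makes this the class-imbalance
#' handling used before model and cluster fitting.
#'
#' @param train_idx integer training indices.
#' @param y full binary outcome vector (indexed by `train_idx`).
#' @param target_ratio desired minority/majority count ratio; default 1.0.
#' @param seed integer seed.
#' @return integer index multiset: `train_idx` plus resampled minority
#'   indices.
#' @export
oversample_minority <- function(train_idx, y, target_ratio = 1.0, seed = 1L) {
  yt <- y[train_idx]
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  if (n1 == 0 || n0 == 0) stopf("training set must contain both classes")
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  target <- round(target_ratio * n_maj)
  if (target <= n_min) return(train_idx)
  pool <- train_idx[yt == minority]
  extra <- with_seed(seed,
    pool[sample.int(length(pool), target - n_min, replace = TRUE)])
  c(train_idx, extra)
}
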