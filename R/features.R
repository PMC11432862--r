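#' Five-number summary of a vital-sign measurement sequence
#'
#' Collapses the ordered measurements of one vital sign during the ED stay
#' into the (first, last, max, min, mean) summary used as model input.
#'
#' @param values numeric vector of measurements in temporal order.
#' @return named numeric vector `(first, last, max, min, mean)`; all `NA`
#'   when `values` is empty (downstream imputation target).
#' @export
summarize_vitals <- function(values) {
  out <- c(first = NA_real_, last = NA_real_, max = NA_real_,
           min = NA_real_, mean = NA_real_)
  if (length(values) == 0) return(out)
  if (!is.numeric(values) || anyNA(values))
    stopf("non-numeric vital measurement in %s", deparse(substitute(values)))
  c(first = values[1], last = values[length(values)], max = max(values),
    min = min(values), mean = mean(values))
}

#' Average of a lab analyte over the ED stay
#'
#' @param values numeric vector of result values (possibly empty).
#' @return arithmetic mean, or `NA` for an empty list (imputed downstream).
#' @export
summarize_labs <- function(values) {
  if (length(values) == 0) return(NA_real_)
  if (!is.numeric(values)) stopf("non-numeric lab value")
  mean(values)
}

#' Order frequency - inverse patient frequency weights
#'
#' TF-IDF-style weighting of diagnostic/medication orders across a visit
#' corpus: `weight(o, v) = count(o, v) * ln(N / (1 + n_visits_containing(o)))`
#' where `N` is the corpus size. Orders absent from a visit get weight 0.
#' Document frequencies may be fitted on one corpus (training visits) and
#' applied to another via the `df` attribute of the result.
#'
#' @param order_counts list of named count vectors, one per visit to weight.
#' @param corpus list of named count vectors defining the vocabulary and the
#'   visit frequencies (typically the training visits).
#' @param vocabulary optional fixed order vocabulary; defaults to all orders
#'   seen in `corpus`.
#' @return numeric matrix `length(order_counts) x |vocabulary|` of weights,
#'   with attributes `idf` (per-order log inverse visit frequency) and
#'   `n_corpus`.
#' @export
of_ipf <- function(order_counts, corpus, vocabulary = NULL) {
  if (length(corpus) == 0) stopf("corpus must be nonempty")
  if (is.null(vocabulary))
    vocabulary <- sort(unique(unlist(lapply(corpus, names))))
  n_corp <- length(corpus)
  df <- vapply(vocabulary, function(o)
    sum(vapply(corpus, function(v) o %in% names(v), logical(1))), numeric(1))
  idf <- log(n_corp / (1 + df))
  w <- matrix(0, length(order_counts), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(order_counts)) {
    v <- order_counts[[i]]
    hit <- intersect(names(v), vocabulary)
    if (length(hit)) w[i, hit] <- v[hit] * idf[hit]
  }
  attr(w, "idf") <- idf
  attr(w, "n_corpus") <- n_corp
  w
}

#' Operational / utilization features of a visit
#'
#' Emits the summed diagnostic-imaging count (surrogate for the complexity of
#' emergency care received), ED length of stay, prior-year ED visit
#' frequency, triage acuity (ESI) and one-hot disposition.
#'
#' @param row one row of a `visit_table`.
#' @return named numeric vector of operational features.
#' @export
aggregate_utilization <- function(row) {
  if (row$imaging_count < 0 || row$prior_year_visits < 0)
    stopf("negative utilization count for visit %s", row$visit_id)
  disp <- tolower(row$disposition)
  c(imaging_count = as.numeric(row$imaging_count),
    ed_los = as.numeric(row$ed_los),
    prior_year_visits = as.numeric(row$prior_year_visits),
    esi = as.numeric(row$esi),
    disposition_home = as.numeric(disp == "home"),
    disposition_facility = as.numeric(disp == "facility"),
    disposition_ama = as.numeric(disp == "ama"))
}

one_hot <- function(x, prefix, levels_ = sort(unique(x))) {
  m <- sapply(levels_, function(l) as.numeric(x == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, levels_))
  colnames(m) <- paste0(prefix, "_", colnames(m))
  m
}

#' Build the normalized design matrix for modeling
#'
#' Applies the study's variable constructions to a visit table: per-sign
#' five-number vital summaries, per-analyte lab averages, OF-IPF weighted
#' order features, operational variables, one-hot demographics, comorbidity
#' flags and the Elixhauser score. Missing numerics are imputed with the
#' training-row median; every numeric column is then z-normalized (mean 0,
#' sd 1) with statistics fitted on training rows only and applied everywhere.
#' Columns constant on the training rows are dropped and logged. OF-IPF
#' visit frequencies are likewise fitted on training rows only, so no test
#' information leaks into the transform.
#'
#' @param table a `visit_table`.
#' @param train_rows integer indices of training rows (statistics source).
#' @return an object of class `feature_matrix` with elements `X` (numeric
#'   matrix, rows aligned with `table`), `feature_names`, `y`, `month`,
#'   `groups` (race, age >= 65 band, disease flags), `normalization_stats`
#'   (per-feature center/scale/median and OF-IPF idf), `discharge_related`
#'   (logical per feature: disposition and ED-LOS variables, which encode
#'   information around discharge), and `dropped` (constant columns).
#' @export
build_matrix <- function(table, train_rows) {
  if (length(train_rows) == 0) stopf("train_rows must be nonempty")
  if (max(train_rows) > nrow(table)) stopf("train_rows out of range")

  raw <- raw_design(table, idf_source = table$order_counts[train_rows])
  X <- raw$X

  med <- apply(X[train_rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  all_na <- is.na(med)
  if (any(all_na)) {
    warnf("dropping all-missing feature(s): %s",
          paste(colnames(X)[all_na], collapse = ", "))
    X <- X[, !all_na, drop = FALSE]
    med <- med[!all_na]
  }

  ctr <- colMeans(X[train_rows, , drop = FALSE])
  scl <- apply(X[train_rows, , drop = FALSE], 2, stats::sd)
  const <- scl < 1e-12 | !is.finite(scl)
  dropped <- colnames(X)[const]
  if (any(const)) {
    warnf("dropping constant column(s) on training rows: %s",
          paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]; med <- med[!const]
  }
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  discharge <- grepl("^disposition_", colnames(X)) | colnames(X) == "ed_los"

  structure(list(
    X = X,
    feature_names = colnames(X),
    y = as.integer(table$outcome),
    month = as.integer(table$month),
    groups = list(
      race = table$race,
      age65 = ifelse(table$age >= 65, "65plus", "under65"),
      hf = table$flag_hf, copd = table$flag_copd,
      uti = table$flag_uti, pneumonia = table$flag_pneumonia
    ),
    normalization_stats = list(center = ctr, scale = scl, median = med,
                               idf = raw$idf, n_corpus = raw$n_corpus,
                               vocabulary = raw$vocabulary,
                               levels = raw$levels),
    discharge_related = stats::setNames(discharge, colnames(X)),
    dropped = dropped,
    train_rows = as.integer(train_rows)
  ), class = "feature_matrix")
}

# un-normalized design matrix; idf_source sets the OF-IPF corpus
raw_design <- function(table, idf_source, frozen = NULL) {
  n <- nrow(table)
  vit <- t(vapply(table$vitals, function(v) {
    unlist(lapply(v, summarize_vitals))
  }, numeric(5 * length(table$vitals[[1]]))))
  colnames(vit) <- sub("\\.", "_", colnames(vit))

  analytes <- if (is.null(frozen)) sort(unique(unlist(lapply(table$labs, names))))
              else frozen$lab_analytes
  lab <- sapply(analytes, function(a)
    vapply(table$labs, function(l) summarize_labs(l[[a]]), numeric(1)))
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = n, dimnames = list(NULL, analytes))
  colnames(lab) <- paste0("lab_", colnames(lab))

  if (is.null(frozen)) {
    ow <- of_ipf(table$order_counts, corpus = idf_source)
    idf <- attr(ow, "idf"); n_corpus <- attr(ow, "n_corpus")
    vocabulary <- colnames(ow)
  } else {
    idf <- frozen$idf; n_corpus <- frozen$n_corpus; vocabulary <- frozen$vocabulary
    ow <- matrix(0, n, length(vocabulary), dimnames = list(NULL, vocabulary))
    for (i in seq_len(n)) {
      v <- table$order_counts[[i]]
      hit <- intersect(names(v), vocabulary)
      if (length(hit)) ow[i, hit] <- v[hit] * idf[hit]
    }
  }
  colnames(ow) <- paste0("oipf_", colnames(ow))

  util <- t(vapply(seq_len(n), function(i)
    aggregate_utilization(table[i, , drop = FALSE]), numeric(7)))

  lv <- if (is.null(frozen)) NULL else frozen$levels
  demo <- cbind(
    one_hot(table$sex, "sex", lv$sex %||% sort(unique(table$sex))),
    one_hot(table$race, "race", lv$race %||% sort(unique(table$race))),
    one_hot(table$insurance, "insurance",
            lv$insurance %||% sort(unique(table$insurance))),
    one_hot(table$language, "language",
            lv$language %||% sort(unique(table$language)))
  )
  levels <- list(sex = lv$sex %||% sort(unique(table$sex)),
                 race = lv$race %||% sort(unique(table$race)),
                 insurance = lv$insurance %||% sort(unique(table$insurance)),
                 language = lv$language %||% sort(unique(table$language)))

  cmb <- as.matrix(table[, grepl("^cmb_", names(table)), drop = FALSE])
  flg <- as.matrix(table[, grepl("^flag_", names(table)), drop = FALSE])

  X <- cbind(age = table$age, vit, lab, ow, util, demo, cmb,
             elixhauser_score = table$elixhauser_score, flg)
  list(X = X, idf = idf, n_corpus = n_corpus, vocabulary = vocabulary,
       levels = levels,
       lab_analytes = sub("^lab_", "", colnames(lab)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted feature transform to a new visit table
#'
#' Re-applies the stored imputation medians, normalization statistics,
#' OF-IPF document frequencies and categorical level sets of a fitted
#' [build_matrix()] result to new visits, without refitting anything —
#' the external-validation path.
#'
#' @param fm a fitted `feature_matrix`.
#' @param table a new `visit_table` with the same schema.
#' @return a `feature_matrix` for the new rows carrying the frozen stats.
#' @export
apply_matrix <- function(fm, table) {
  stopifnot(inherits(fm, "feature_matrix"))
  need <- c("vitals", "labs", "order_counts", "outcome", "month")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("schema mismatch, missing column(s): %s", paste(miss, collapse = ", "))
  st <- fm$normalization_stats
  st$lab_analytes <- sub("^lab_", "",
                         grep("^lab_", fm$feature_names, value = TRUE))
  # rebuild with frozen idf/levels, then subset to the fitted feature set
  raw <- raw_design(table, idf_source = NULL, frozen = st)
  X <- raw$X
  miss_f <- setdiff(fm$feature_names, colnames(X))
  if (length(miss_f))
    stopf("schema mismatch, missing feature(s): %s", paste(miss_f, collapse = ", "))
  X <- X[, fm$feature_names, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- st$median[[colnames(X)[j]]]
  }
  X <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  out <- fm
  out$X <- X
  out$y <- as.integer(table$outcome)
  out$month <- as.integer(table$month)
  out$groups <- list(
    race = table$race,
    age65 = ifelse(table$age >= 65, "65plus", "under65"),
    hf = table$flag_hf, copd = table$flag_copd,
    uti = table$flag_uti, pneumonia = table$flag_pneumonia
  )
  out$train_rows <- integer(0)
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d visits x %d features, %d positives (%.2f%%)\n",
              nrow(x$X), ncol(x$X), sum(x$y), 100 * mean(x$y)))
  if (length(x$dropped))
    cat("  dropped constant columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
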