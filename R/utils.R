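#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so package functions are deterministic
#' per their own `seed` argument without disturbing the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Counter-based fan-out: each pipeline stage gets a fixed counter so that
#' reordering or skipping stages never changes another stage's stream.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer stage counter.
#' @return an integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(master, counter) {
  m <- as.double(master) %% 2147483647
  # LCG-style mix keeps seeds well below 2^31 and distinct per counter
  as.integer((m * 48271 + as.double(counter) * 16807 + 11) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == floor(x) && x >= 0

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x > 0 && x < 1

#' Rank-based two-class AUC
#'
#' Mann-Whitney AUC with midrank tie correction:
#' `(mean rank of positives - (n1+1)/2) / n0`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC undefined: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# largest-remainder apportionment of n into parts proportional to `ratios`
largest_remainder <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    take <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}
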