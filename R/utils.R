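#' Train/test sizes for a 90/10 split
#'
#' Computes the sizes of a train/hold-out split, rounding half up on the
#' training side, so that e.g. 65,765 sequences give 59,189 train / 6,576
#' test and 6,862 give 6,176 / 686.
#'
#' @param n Total number of sequences.
#' @param train_frac Fraction assigned to training (default 0.9).
#' @return Named integer vector `c(train =, test =)`.
#' @export
#' @examples
#' split_sizes(6862)
split_sizes <- function(n, train_frac = 0.9) {
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  tr <- floor(n * train_frac + 0.5)
  c(train = as.integer(tr), test = as.integer(n - tr))
}

# Stratified hold-out split. The total training size follows split_sizes();
# per-class sizes are the largest-remainder apportionment of that total, so
# class balance is preserved as closely as integers allow. Uses the current
# RNG stream.
stratified_holdout <- function(labels, train_frac = 0.9) {
  n <- length(labels)
  n_train <- split_sizes(n, train_frac)[["train"]]
  classes <- sort(unique(labels))
  raw <- vapply(classes, function(cl) sum(labels == cl) * train_frac, 0)
  base <- floor(raw)
  deficit <- n_train - sum(base)
  if (deficit > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(deficit)]
    base[give] <- base[give] + 1
  }
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    train_idx <- c(train_idx, sample(idx)[seq_len(base[i])])
  }
  train_idx <- sort(train_idx)
  list(train = train_idx, test = setdiff(seq_len(n), train_idx))
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sequence to one of `k` folds, stratified by class. Within
#' each class the (shuffled) members are dealt out in blocks whose sizes
#' differ by at most one; the classes' surplus members rotate over the
#' folds so overall fold sizes also differ by at most one (6,176 sequences
#' in 5 folds give sizes 1236, 1235, 1235, 1235, 1235).
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @return Integer vector of fold ids (1..k), one per sequence.
#' @export
cv_folds <- function(labels, k = 5) {
  if (k < 2) stop("k must be at least 2")
  n <- length(labels)
  fold <- integer(n)
  offset <- 0
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    q <- n_c %/% k
    r <- n_c %% k
    sizes <- rep(q, k)
    if (r > 0) {
      extra <- ((offset + seq_len(r) - 1) %% k) + 1
      sizes[extra] <- sizes[extra] + 1
      offset <- (offset + r) %% k
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

# Map a midpoint-relative position (-l/2 .. l/2-1, midpoint convention: the
# first downstream base is 0) to a 1-based sequence index.
rel_to_index <- function(rel, l) {
  idx <- rel + l / 2 + 1
  if (any(idx < 1 | idx > l)) stop("relative position out of range for l = ", l)
  as.integer(idx)
}

relative_positions <- function(l) seq.int(-l / 2, l / 2 - 1)
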