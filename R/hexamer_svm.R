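#' Hexamer frequency features
#'
#' Encodes each sequence as the frequencies of all 4^6 = 4096 hexamers over
#' sliding windows of stride 1, indexed lexicographically with A < C < G < T.
#' Windows containing `N` are skipped and the frequency denominator reduced
#' accordingly, so for an N-free length-`l` sequence the underlying counts
#' sum to `l - 5` and the frequencies to 1.
#'
#' @param x A [tss_dataset()], `DNAStringSet`, or character vector.
#' @param frequency If `FALSE`, return raw counts instead of frequencies.
#' @return An `n x 4096` matrix with hexamer column names.
#' @export
#' @examples
#' hexamer_features("AAAAAA", frequency = FALSE)[1, "AAAAAA"]
hexamer_features <- function(x, frequency = TRUE) {
  seqs <- as_sequences(x)
  if (any(nchar(seqs) < 6)) {
    stop("sequences must be at least 6 bp for hexamer encoding")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 6, step = 1)
  if (!frequency) return(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("sequence(s) with no countable hexamer window: ",
         paste(which(tot == 0), collapse = ", "))
  }
  counts / tot
}

# Squared Euclidean distances between rows of a and rows of b (BLAS-backed),
# clipped at zero against rounding.
sq_dist <- function(a, b = a) {
  ra <- rowSums(a^2)
  rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

svm_label_factor <- function(labels) factor(labels, levels = c(0, 1))

# Fit a C-SVC on a precomputed RBF kernel; positive decision values
# correspond to the promoter class (second factor level in kernlab's
# convention, verified in the test suite).
ksvm_precomp <- function(K, labels, C) {
  kernlab::ksvm(kernlab::as.kernelMatrix(K), svm_label_factor(labels),
                type = "C-svc", C = C)
}

ksvm_decision <- function(fit, K_cross) {
  sv <- kernlab::SVindex(fit)
  as.numeric(kernlab::predict(fit,
                              kernlab::as.kernelMatrix(K_cross[, sv, drop = FALSE]),
                              type = "decision"))
}

#' Grid-search an RBF-SVM on hexamer features
#'
#' The reference baseline: a radial-basis-kernel support vector classifier
#' on 4096-dimensional hexamer frequencies, tuned by grid search over
#' `C = base^(-3..1)` and `gamma = base^(-13..-1)` (base 2 by default; the
#' exponent ranges are integer grids). Every combination is scored by
#' stratified fivefold cross-validated AU-ROC under the same fold protocol
#' as the CNN, and the highest-AUC combination is refit on the full
#' training set. The RBF kernel `exp(-gamma * ||a - b||^2)` is precomputed
#' once per gamma, so the whole grid reuses one squared-distance matrix.
#'
#' @param features An `n x 4096` matrix from [hexamer_features()].
#' @param labels 0/1 vector (1 = promoter), both classes present.
#' @param exponents_C Integer exponents for `C` (default -3..1).
#' @param exponents_gamma Integer exponents for `gamma` (default -13..-1).
#' @param base Exponent base (default 2).
#' @param k Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class `hexamer_svm`: the full `grid` data.frame
#'   (C, gamma, exponents, cv AUC), `best_C`, `best_gamma`, `best_auc`, and
#'   the refit model. Use [predict.hexamer_svm()] for decision scores.
#' @export
grid_search_train <- function(features, labels,
                              exponents_C = -3:1, exponents_gamma = -13:-1,
                              base = 2, k = 5, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  folds <- cv_folds(labels, k)
  for (f in seq_len(k)) {
    if (length(unique(labels[folds == f])) < 2) {
      stop("fold ", f, " contains a single class; too few sequences for ",
           k, "-fold stratified CV")
    }
  }
  d2 <- sq_dist(features)
  grid <- expand.grid(exponent_C = exponents_C,
                      exponent_gamma = exponents_gamma)
  grid$C <- base^grid$exponent_C
  grid$gamma <- base^grid$exponent_gamma
  grid$auc <- NA_real_
  for (ge in exponents_gamma) {
    K <- exp(-(base^ge) * d2)
    for (ce in exponents_C) {
      aucs <- vapply(seq_len(k), function(f) {
        tr <- which(folds != f)
        va <- which(folds == f)
        fit <- ksvm_precomp(K[tr, tr], labels[tr], C = base^ce)
        compute_auroc(labels[va], ksvm_decision(fit, K[va, tr, drop = FALSE]))
      }, 0)
      row <- grid$exponent_C == ce & grid$exponent_gamma == ge
      grid$auc[row] <- mean(aucs)
    }
  }
  best <- which.max(grid$auc)  # first maximum in enumeration order on ties
  best_gamma <- grid$gamma[best]
  fit <- ksvm_precomp(exp(-best_gamma * d2), labels, C = grid$C[best])
  structure(list(grid = grid, best_C = grid$C[best],
                 best_gamma = best_gamma,
                 best_exponent_C = grid$exponent_C[best],
                 best_exponent_gamma = grid$exponent_gamma[best],
                 best_auc = grid$auc[best], fit = fit,
                 train_features = features),
            class = "hexamer_svm")
}

#' @export
print.hexamer_svm <- function(x, ...) {
  cat(sprintf("hexamer RBF-SVM: best C = %g, gamma = %g (CV AUC %.3f) over %d grid points\n",
              x$best_C, x$best_gamma, x$best_auc, nrow(x$grid)))
  invisible(x)
}

#' Decision scores from a grid-searched hexamer SVM
#'
#' @param object A `hexamer_svm` from [grid_search_train()].
#' @param newdata An `n x 4096` hexamer feature matrix.
#' @param ... Ignored.
#' @return Numeric decision values; positive = promoter-like.
#' @export
predict.hexamer_svm <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == ncol(object$train_features))
  K <- exp(-object$best_gamma * sq_dist(newdata, object$train_features))
  ksvm_decision(object$fit, K)
}
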